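---
title: "Quantifying enrichment effects along the dorso-ventral dentate gyrus axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enrichment effects along the dorso-ventral dentate gyrus axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgquant)
```

## The scientific problem

Adult hippocampal neurogenesis (AHN) and BDNF respond to environmental
enrichment, but the dentate gyrus (DG) is not functionally uniform: its
dorsal pole serves predominantly spatial/cognitive processing while the
ventral pole is tied to affect regulation. A study design that pools the
whole DG can therefore hide opposite responses at the two poles. `dgquant`
implements the complete quantification and inference chain used in this
kind of experiment — doublecortin (DCX) immunohistochemistry scored as a
normalized area fraction, BDNF densitometry, Cavalieri volumetry,
wheel-running distance estimation, and Prox1-normalized molecular
quantification — together with a seeded synthetic-data generator so the
whole chain can be validated against known ground truth.

The core experimental design the generator mirrors: 4 batches of 24 female
mice, 3 mice per cage, cages split equally between an enriched (E)
condition with running wheels and a control (C) condition, for 96 animals
in total. Brains are split across three assay arms — immunohistochemistry
(IHC), quantitative PCR, ELISA — one mouse per cage per arm, giving 16
animals per treatment in each arm.

## Quantification methods

### Adaptive DAB thresholding (`compute_threshold`, `measure_dcx_area`, `aggregate_dcx`)

DAB-stained DCX+ tissue is darker than background, and staining intensity
varies between sections and staining batches. Each section therefore gets
its own threshold from a stain-free region outlined inside the granule cell
layer (GCL):

$$\mathrm{threshold} = \bar g_{\mathrm{clean}} - 2\,s_{g,\mathrm{clean}}$$

A GCL pixel counts as DCX+ when its gray value is *strictly below* the
threshold. Per animal and region, DCX+ and GCL areas are summed over
frames, sections and hemispheres before dividing:

$$\mathrm{DCX~(normalized)} = \frac{\sum \mathrm{DCX~area}~(\mu m^2)}{\sum \mathrm{GCL~area}~(\mu m^2)}$$

a pooled ratio, not a mean of per-section ratios, so sections with more
sampled GCL weigh proportionally more.

Numerical conventions we had to fix (both switchable): the SD is the sample
SD (n − 1), matching common histogram tools; the threshold comparison is
strict (`<`), the natural reading for a dark-object rule; one threshold per
section is applied to all frames of that section's montage
(`per_frame_threshold = TRUE` gives the per-frame alternative).
Intermediate-region frames are accepted but excluded from the dorso-ventral
aggregate by default, since that region's boundaries are the least certain.

A property worth knowing: with Gaussian background noise the mean − 2 SD
rule intrinsically classifies the lower ≈ 2.3% tail of *unstained* GCL
pixels as positive. Estimated fractions are therefore shifted up by
≈ 0.023 × (1 − fraction), which slightly attenuates estimated fold changes
(a configured 1.4-fold arrives at ≈ 1.33–1.37 at the default fractions).
This is a property of the published rule itself, visible here only because
the generator records exact truth; on noise-free frames the estimator is
exact (the tests verify |estimate − truth| < 0.005 at zero pixel noise).

### Relative optical density (`pixel_od`, `roi_rod`, `background_correct`)

BDNF staining is uniform across the DG, so darkness, not area, is the
readout. We use the uncalibrated 8-bit OD convention
$OD = \log_{10}(255/\max(g, 1))$, average it over four rectangular
sampling-site ROIs (suprapyramidal and infrapyramidal blades, hilus, mossy
fibers), and subtract the corpus-callosum OD of the same section as
background. Background subtraction removes global intensity shifts up to
8-bit quantization (≤ 0.01 OD, tested). Negative corrected values are kept
and flagged rather than clipped.

### Cavalieri volumetry (`cavalieri_volume`, `dgca_ratio`)

Volumes come from serial outline areas: dorsal hippocampus outlined every
480 µm, intermediate and ventral every 240 µm, and

$$V = \sum_i A_i\, s_i,$$

where $s_i$ is the distance to the next section and the last section
contributes 240 µm. We apply the 240 µm last-section rule verbatim even for
dorsal stacks sampled at 480 µm — faithful but odd for those stacks —
and provide `last_section_rule = "interval"` to use the sampling interval
instead. Staining method (cresyl violet vs. antibody) is carried as a
categorical covariate into the volume model because antibody-stained
dorsal boundaries read systematically larger.

### Running distance (`allocate_spins`, `total_distance`)

Wheel counters record cage-level daily spin totals; the first 3 minutes of
every recorded hour are scored for which mouse ran. A mouse's proportion of
activity is its observed running seconds over the time at least one mouse
ran; because mice run simultaneously these proportions can sum above 1, so
we renormalize before allocating the spin total — which also makes the
allocation conserve the cage-day total exactly (tested to 1e-9) and makes
the union time cancel algebraically. Spins stay fractional (no rounding) to
keep conservation exact. Distance is spins × wheel circumference; the wheel
circumference is not a quantity the design fixes, so it is a configuration
default (0.38 m).

### Molecular normalization (`fit_standard_curve`, `quantify_cq`, `normalize_expression`)

qPCR quantities come from per-gene standard curves
$C_q = a + b\log_{10}(q)$ fitted to serial dilutions; amplification
efficiency is $10^{-1/b} - 1$ and the generator draws efficiencies in the
98–104% range. Samples run in singlicate, as in the design being
emulated. Dcx and Bdnf are expressed relative to Prox1, which marks all
granule cells and thus plays the same role as the GCL denominator in the
image analysis; normalization is exactly scale-invariant, so absolute
units never matter.

## Inference (`dg_gee` and friends)

Measurements from the two regions of one animal are repeated measures, so
the models are Gaussian generalized estimating equations with animals as
clusters. `dg_gee()` is the package's fitting function: formula + data +
cluster id in, a classed object out, with the usual
`print`/`summary`/`coef`/`vcov`/`residuals`/`fitted`/`predict`/`confint`
methods. The working correlation is exchangeable by default — the natural
structure for two-region repeated measures — with independence available
(under which the fit provably equals OLS, our oracle test). Coefficients
iterate to `max|Δβ| < 1e-8` (cap 100 iterations, non-convergence flagged);
α and the dispersion are moment-estimated from Pearson residuals; inference
uses the sandwich covariance throughout, so it is robust to
misspecification of the working correlation. p-values come from Wald χ²
statistics; post-hoc pairwise cell comparisons use unadjusted Wald z tests
(LSD convention). Data are screened per treatment-by-region cell with the
IQR rule at multiplier 2.2 (type-7 quartiles) before modelling, with
flagged rows excluded and logged.

Small-sample caveats: the sandwich estimator is mildly liberal with few
clusters (the calibration test bounds the type-I rate at ≤ 8% over 100
simulated null cohorts at 32 clusters); the dispersion uses an N − p
denominator, which is why the size-1-cluster identity between sandwich and
model-based covariance holds up to the factor (N − p)/N.

## What the generator emulates — and what it does not

Every modality is generated from one seeded configuration that *is* the
study's ground truth: enrichment multiplies the dorsal DCX+ fraction by
1.4 and divides the ventral one by 1.4; protein ratios change 1.6-fold
(dorsal, up) and 1.2-fold (ventral, down); dorsal volumes are 15% larger
under enrichment; DG/CA volume ratios are 0.63/0.42/0.21
(dorsal/intermediate/ventral); ventral Bdnf/Prox1 of enriched animals is
linear in true running distance with population r² = 0.535 and dorsal
Bdnf is independent of distance. Quantities the design does not pin down
were chosen once as realistic values and are stated in
`generator_config()`: control DCX+ fractions 0.25 (dorsal) / 0.20
(ventral); background gray 180 ± 8 with stain at 60; base CA volumes
2.4/1.7/1.4 mm³; mean running fraction 5% of the day with lognormal
between-mouse spread (σ_log = 0.5) and 2 wheel revolutions per second.
Noise is lognormal for expression quantities and areas (positivity),
Gaussian for pixel values and Cq (SD 0.15 cycles).

Two generator choices deserve explanation. First, stained pixels are
placed as soma disks topped up with single-pixel dendrite fragments to an
*exact* pixel count, so every frame's true fraction is exact rather than
approximate — that is what makes the threshold-rule bias measurable at
all. Second, the residual SD of the ventral Bdnf–distance relation is
calibrated against the cohort's empirical distance variance *minus* the
variance the Cq measurement chain is expected to add, so that the
pipeline-measured r² — not merely the latent one — centres on the
configured 0.535. The distance term is centred, so the coupling adds no
spurious enrichment main effect. At n = 16 the r̂² statistic itself is
biased upward by roughly +0.05 (a small-sample property of r², not of the
generator); cohort averages land around 0.51–0.61 depending on the seed
set, inside the ±0.10 recovery band.

What the synthetic data does *not* contain: real DG geometry (masks are
bands and rectangles — region identity is metadata, not something the
pipeline infers from anatomy); staining artifacts beyond per-frame
intensity shifts; observer bias in the video scoring beyond binomial
window sampling; any difference between hemispheres (frames are generated
pooled). Passing tests therefore validate the estimators and the
inference chain, not the anatomical segmentation steps a real study would
also need.

## Problem sizes and determinism

Recovery checks use full-design cohorts (96 animals; 16 + 16 per arm) and
average over 20 replicate cohorts for fold/volume recoveries and 50 for
the correlation target, sizes at which the Monte-Carlo error is several
times smaller than the recovery tolerances. Every generated artifact is a
pure function of the seed: per-modality and per-animal sub-seeds are
derived deterministically (position-weighted string hashes, double
arithmetic to stay inside 32-bit seed range), so any animal's data can be
regenerated in isolation and two runs with one seed are bit-identical —
the `run_full_study()` manifest records digests to prove it.

## Known limitations

- The GEE implementation covers the Gaussian/identity case this design
  needs; other families/links are out of scope.
- LSD post-hoc means no multiplicity control beyond the omnibus gate, by
  design fidelity rather than statistical preference.
- The 240 µm last-section rule is kept as written; for dorsal stacks the
  "interval" option is arguably the better estimator and both are exposed.
- Ratios are analyzed untransformed (as they are plotted in this
  literature); a log-scale analysis is a one-line change in the model
  formula and is left to the user.
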