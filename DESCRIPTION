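Package: dgquant
Title: Quantification and Repeated-Measures Inference for Dorso-Ventral
    Dentate Gyrus Enrichment Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification and inference pipeline for studies of
    environmental-enrichment effects along the dorso-ventral axis of the
    dentate gyrus. Implements adaptive mean-minus-2SD DAB thresholding and
    normalized DCX area scoring, relative optical density (ROD) densitometry
    with corpus-callosum background correction, Cavalieri serial-section
    volumetry, wheel-running distance allocation from cage-level spin counts
    and sampled video observations, standard-curve qPCR quantification with
    Prox1 normalization, interquartile-range outlier screening, and Gaussian
    generalized estimating equations with robust (sandwich) covariance, Wald
    chi-square tests and LSD post-hoc comparisons. A seeded synthetic-data
    generator emulates every input modality (section images with masks,
    outline tables, activity logs, molecular readouts) with known ground
    truth so each estimator can be scored against what generated it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, png
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
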