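#' Configuration for the synthetic study generator
#'
#' Builds the seeded ground-truth description from which every synthetic
#' modality (cohort design, section images, outline tables, activity logs,
#' molecular readouts) is drawn. The defaults encode the study design the
#' pipeline is meant to recover: 4 batches of 24 mice (3 per cage), one third
#' of the cohort per assay arm, a 1.4-fold dorsal increase (and 1.4-fold
#' ventral decrease) in DCX-stained GCL fraction under enrichment, 1.6-fold
#' dorsal / 1.2-fold ventral protein effects, a 15% dorsal volume excess,
#' DG/CA volume ratios of 0.63/0.42/0.21 (dorsal/intermediate/ventral), and a
#' ventral Bdnf-expression vs. running-distance squared correlation of 0.535.
#'
#' @param seed integer seed; fixing it makes every generated artifact
#'   reproducible bit-for-bit.
#' @param n_batches number of experimental batches.
#' @param animals_per_batch animals per batch (must be divisible by 3: cages
#'   hold 3 mice).
#' @param dcx_fraction_control named vector, true DCX+ fraction of GCL pixels
#'   in control animals per region. Not reported by the study; defaults are
#'   realistic assumptions (dorsal richer than ventral).
#' @param dcx_fold_enriched multiplicative enrichment effect on the stained
#'   fraction per region (dorsal 1.4, ventral 1/1.4). Also applied to
#'   Dcx/Prox1 mRNA ratios.
#' @param protein_fold enrichment effect on DCX/PROX1 protein per region
#'   (dorsal 1.6, ventral 1/1.2).
#' @param volume_effect relative volume difference (enriched vs control) per
#'   region; dorsal +15%, intermediate -15%, ventral -5%.
#' @param dgca_ratio true DG/CA volume ratio per region.
#' @param base_volume_ca_mm3 control CA volume per region, mm^3 (both
#'   hemispheres pooled); DG volumes follow from \code{dgca_ratio}.
#' @param bdnf_site_od true background-corrected optical density per BDNF
#'   sampling site (dorsal values; hilus lowest).
#' @param bdnf_rod_ventral_excess additive OD by which ventral sites are
#'   darker than their dorsal counterparts.
#' @param bdnf_background_od corpus-callosum (background) optical density.
#' @param bdnf_distance_r2_ventral target squared correlation between ventral
#'   Bdnf/Prox1 and running distance among enriched animals.
#' @param bdnf_distance_slope slope (ratio units per km) of that coupling.
#' @param bdnf_ratio_base baseline Bdnf/Prox1 per region (ventral > dorsal).
#' @param dcx_ratio_base baseline Dcx/Prox1 mRNA ratio per region in controls
#'   (ventral > dorsal).
#' @param dcx_protein_base baseline DCX/PROX1 protein ratio per region in
#'   controls (no regional main effect).
#' @param pixel_sd Gaussian SD of tissue gray values (8-bit units).
#' @param gray_bg,gray_pos mean background / DCX+ gray levels; the stain is
#'   darker than tissue by more than 2 pixel SDs.
#' @param area_cv lognormal CV of per-section outline areas.
#' @param animal_volume_cv lognormal CV of per-animal volume scale.
#' @param animal_fraction_cv lognormal CV of per-animal DCX fraction.
#' @param cq_sd Gaussian SD of Cq values (cycles).
#' @param elisa_cv lognormal CV of ELISA quantities.
#' @param expression_cv lognormal CV of per-animal expression baselines.
#' @param wheel_circumference_m wheel circumference in metres (not reported
#'   by the study; configurable).
#' @param spin_rate_hz wheel revolutions per second while a mouse runs.
#' @param running_fraction_mean,running_fraction_sdlog lognormal parameters of
#'   the per-mouse latent fraction of time spent running.
#' @param n_days days of enrichment (wheel access).
#' @param windows_per_day sampled 3-minute video windows per cage-day.
#' @param pixel_size_um image calibration, microns per pixel.
#' @param frame_px frame side length in pixels.
#' @param n_sections_range range of serial sections per region.
#'
#' @return an object of class \code{generator_config} (a validated list).
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$dcx_fold_enriched
#' @export
generator_config <- function(seed = 1L,
                             n_batches = 4L,
                             animals_per_batch = 24L,
                             dcx_fraction_control = c(dorsal = 0.25, ventral = 0.20),
                             dcx_fold_enriched = c(dorsal = 1.4, ventral = 1 / 1.4),
                             protein_fold = c(dorsal = 1.6, ventral = 1 / 1.2),
                             volume_effect = c(dorsal = 0.15, intermediate = -0.15,
                                               ventral = -0.05),
                             dgca_ratio = c(dorsal = 0.63, intermediate = 0.42,
                                            ventral = 0.21),
                             base_volume_ca_mm3 = c(dorsal = 2.4, intermediate = 1.7,
                                                    ventral = 1.4),
                             bdnf_site_od = c(suprapyramidal = 0.40,
                                              infrapyramidal = 0.33,
                                              hilus = 0.22,
                                              mossy_fibers = 0.40),
                             bdnf_rod_ventral_excess = 0.08,
                             bdnf_background_od = 0.10,
                             bdnf_distance_r2_ventral = 0.535,
                             bdnf_distance_slope = 0.02,
                             bdnf_ratio_base = c(dorsal = 1.0, ventral = 1.3),
                             dcx_ratio_base = c(dorsal = 0.8, ventral = 1.2),
                             dcx_protein_base = c(dorsal = 1.0, ventral = 1.0),
                             pixel_sd = 8,
                             gray_bg = 180,
                             gray_pos = 60,
                             area_cv = 0.05,
                             animal_volume_cv = 0.08,
                             animal_fraction_cv = 0.10,
                             cq_sd = 0.15,
                             elisa_cv = 0.12,
                             expression_cv = 0.15,
                             wheel_circumference_m = 0.38,
                             spin_rate_hz = 2,
                             running_fraction_mean = 0.05,
                             running_fraction_sdlog = 0.5,
                             n_days = 8L,
                             windows_per_day = 24L,
                             pixel_size_um = 0.5,
                             frame_px = 96L,
                             n_sections_range = c(4L, 6L)) {
  cfg <- list(seed = as.integer(seed),
              n_batches = as.integer(n_batches),
              animals_per_batch = as.integer(animals_per_batch),
              dcx_fraction_control = dcx_fraction_control,
              dcx_fold_enriched = dcx_fold_enriched,
              protein_fold = protein_fold,
              volume_effect = volume_effect,
              dgca_ratio = dgca_ratio,
              base_volume_ca_mm3 = base_volume_ca_mm3,
              bdnf_site_od = bdnf_site_od,
              bdnf_rod_ventral_excess = bdnf_rod_ventral_excess,
              bdnf_background_od = bdnf_background_od,
              bdnf_distance_r2_ventral = bdnf_distance_r2_ventral,
              bdnf_distance_slope = bdnf_distance_slope,
              bdnf_ratio_base = bdnf_ratio_base,
              dcx_ratio_base = dcx_ratio_base,
              dcx_protein_base = dcx_protein_base,
              pixel_sd = pixel_sd,
              gray_bg = gray_bg,
              gray_pos = gray_pos,
              area_cv = area_cv,
              animal_volume_cv = animal_volume_cv,
              animal_fraction_cv = animal_fraction_cv,
              cq_sd = cq_sd,
              elisa_cv = elisa_cv,
              expression_cv = expression_cv,
              wheel_circumference_m = wheel_circumference_m,
              spin_rate_hz = spin_rate_hz,
              running_fraction_mean = running_fraction_mean,
              running_fraction_sdlog = running_fraction_sdlog,
              n_days = as.integer(n_days),
              windows_per_day = as.integer(windows_per_day),
              pixel_size_um = pixel_size_um,
              frame_px = as.integer(frame_px),
              n_sections_range = as.integer(n_sections_range))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$animals_per_batch %% 3L != 0L)
    stop("invalid design: animals_per_batch must be divisible by 3 (3 mice per cage)")
  if ((cfg$animals_per_batch / 3L) %% 2L != 0L)
    stop("invalid design: cages per batch must split equally between treatments")
  frac <- cfg$dcx_fraction_control
  if (any(frac < 0) || any(frac >= 1))
    stop("invalid config: dcx_fraction_control must lie in [0, 1)")
  if (any(cfg$dcx_fold_enriched <= 0) || any(cfg$protein_fold <= 0))
    stop("invalid config: fold changes must be positive")
  enriched_frac <- frac * cfg$dcx_fold_enriched[names(frac)]
  if (any(enriched_frac >= 1))
    stop("invalid config: enriched stained fraction would reach or exceed 1")
  if (any(cfg$base_volume_ca_mm3 <= 0) || any(1 + cfg$volume_effect <= 0))
    stop("invalid config: target volumes must be positive")
  if (any(cfg$dgca_ratio <= 0))
    stop("invalid config: DG/CA ratios must be positive")
  if (cfg$wheel_circumference_m <= 0)
    stop("invalid config: wheel circumference must be positive")
  if (cfg$pixel_size_um <= 0)
    stop("invalid config: pixel size must be positive")
  if (cfg$gray_pos >= cfg$gray_bg - 2 * cfg$pixel_sd)
    stop("invalid config: stain gray level must lie below background mean - 2 SD")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic study generator configuration\n")
  cat(sprintf("  seed: %d; %d batches x %d animals (%d cages of 3)\n",
              x$seed, x$n_batches, x$animals_per_batch,
              x$animals_per_batch / 3L))
  cat(sprintf("  DCX stained fraction (control): dorsal %.2f, ventral %.2f\n",
              x$dcx_fraction_control[["dorsal"]], x$dcx_fraction_control[["ventral"]]))
  cat(sprintf("  enrichment folds: DCX area %.3g / %.3g, protein %.3g / %.3g (dorsal/ventral)\n",
              x$dcx_fold_enriched[["dorsal"]], x$dcx_fold_enriched[["ventral"]],
              x$protein_fold[["dorsal"]], x$protein_fold[["ventral"]]))
  cat(sprintf("  dorsal volume effect: %+.0f%%; DG/CA ratios %.2f/%.2f/%.2f\n",
              100 * x$volume_effect[["dorsal"]], x$dgca_ratio[["dorsal"]],
              x$dgca_ratio[["intermediate"]], x$dgca_ratio[["ventral"]]))
  cat(sprintf("  ventral Bdnf~distance target r2: %.3f; wheel circumference %.2f m\n",
              x$bdnf_distance_r2_ventral, x$wheel_circumference_m))
  invisible(x)
}

# deterministic per-purpose sub-seed so modalities don't share streams
# (double arithmetic: products can exceed .Machine$integer.max)
sub_seed <- function(cfg, tag) {
  as.integer((as.numeric(cfg$seed) * 1009 + sum(utf8ToInt(tag)) * 131) %%
               2147483587)
}

# uniform draw from an inclusive integer range (safe for degenerate ranges)
sample_range <- function(r) if (r[1] >= r[2]) r[1] else sample(seq(r[1], r[2]), 1)

# per-animal sub-seed; position-weighted so distinct ids rarely collide
animal_seed <- function(cfg, tag, id) {
  v <- utf8ToInt(id)
  as.integer((as.numeric(sub_seed(cfg, tag)) +
                sum(v * seq_along(v) * 131) %% 1000003) %% 2147483587)
}
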