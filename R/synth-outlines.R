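#' Generate synthetic serial-section outline areas for one animal
#'
#' Emits per-region (dorsal, intermediate, ventral), per-subfield (DG, CA)
#' outline-area series whose Cavalieri sum — area times distance to the next
#' section, 240 um for the last — equals a target volume drawn from the
#' configuration: control CA volumes per region, DG as the configured DG/CA
#' ratio of CA, dorsal volumes scaled by \code{1 + volume_effect["dorsal"]}
#' for enriched animals (intermediate and ventral likewise by their own
#' effects). Dorsal series are spaced 480 um apart, intermediate and ventral
#' 240 um. A smooth unimodal area profile is scaled to hit the target
#' exactly; multiplicative lognormal noise (CV \code{area_cv}) is then
#' applied per section, and a shared per-animal lognormal factor (CV
#' \code{animal_volume_cv}) models between-animal size variation (it cancels
#' in DG/CA ratios). A staining-method label (cresyl violet or antibody) is
#' assigned per animal and carried as a covariate.
#'
#' @param animal one row of [generate_cohort()] output.
#' @param config a [generator_config()].
#' @return a data.frame of outlines (\code{animal_id}, \code{region},
#'   \code{subfield}, \code{section_position_um}, \code{area_um2},
#'   \code{spacing_to_next_um}, \code{staining_method}) with a \code{truth}
#'   attribute giving the noise-free target volume (mm^3) per
#'   region/subfield.
#' @export
generate_outlines <- function(animal, config) {
  validate_generator_config(config)
  set.seed(animal_seed(config, "outlines", animal$animal_id))
  sdl_a <- sqrt(log(1 + config$animal_volume_cv^2))
  animal_factor <- rlnorm(1, -sdl_a^2 / 2, sdl_a)
  staining <- sample(c("cresyl", "antibody"), 1)
  sdl_s <- sqrt(log(1 + config$area_cv^2))
  rows <- list(); truth <- list()
  for (region in c("dorsal", "intermediate", "ventral")) {
    spacing <- if (region == "dorsal") 480 else 240
    k <- sample_range(config$n_sections_range)
    v_ca <- config$base_volume_ca_mm3[[region]]
    if (identical(animal$treatment, "E"))
      v_ca <- v_ca * (1 + config$volume_effect[[region]])
    v_ca <- v_ca * animal_factor
    targets <- c(DG = v_ca * config$dgca_ratio[[region]], CA = v_ca)
    for (subfield in c("DG", "CA")) {
      if (targets[[subfield]] <= 0) stop("invalid config: nonpositive target volume")
      s <- rep(spacing, k); s[k] <- 240       # estimator's last-section rule
      profile <- sin(pi * (seq_len(k) - 0.5) / k) + 0.3
      areas <- profile * (targets[[subfield]] * 1e9) / sum(profile * s)
      areas <- areas * rlnorm(k, -sdl_s^2 / 2, sdl_s)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = animal$animal_id, region = region, subfield = subfield,
        section_position_um = spacing * (seq_len(k) - 1L),
        area_um2 = areas, spacing_to_next_um = c(rep(spacing, k - 1L), 240),
        staining_method = staining, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        animal_id = animal$animal_id, region = region, subfield = subfield,
        true_volume_mm3 = targets[[subfield]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
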