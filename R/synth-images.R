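# Synthetic 8-bit section frames with label masks and exact pixel-level truth.
#
# Mask label convention (shared with the quantification modules):
#   0 background tissue outside any ROI
#   1 granule cell layer (GCL)
#   2 stain-free "clean" ROI inside the GCL (used for the adaptive threshold)
#   10..13 BDNF sampling sites (suprapyramidal, infrapyramidal, hilus, mossy fibers)
#   20 corpus callosum (densitometry background)

MASK_GCL <- 1L
MASK_CLEAN <- 2L
MASK_SITES <- c(suprapyramidal = 10L, infrapyramidal = 11L,
                hilus = 12L, mossy_fibers = 13L)
MASK_CC <- 20L

#' Construct a section image
#'
#' A single 8-bit grayscale frame with a congruent label mask and spatial
#' calibration. Frames carry their generating ground truth (when synthetic)
#' so estimators can be scored against it.
#'
#' @param pixels integer matrix of gray values in [0, 255].
#' @param masks integer label matrix of the same dimension.
#' @param pixel_size_um microns per pixel (> 0).
#' @param region one of "dorsal", "intermediate", "ventral".
#' @param section_index integer position of the section in its series.
#' @param animal_id animal identifier.
#' @param hemisphere "left", "right" or "pooled".
#' @param truth optional list of generator ground truth.
#' @return an object of class \code{section_image}.
#' @export
section_image <- function(pixels, masks, pixel_size_um, region,
                          section_index = 1L, animal_id = NA_character_,
                          hemisphere = "pooled", truth = NULL) {
  pixels <- as.matrix(pixels)
  masks <- as.matrix(masks)
  if (!identical(dim(pixels), dim(masks)))
    stop("geometry error: mask dimensions must match the pixel grid")
  if (any(pixels < 0 | pixels > 255))
    stop("format error: gray values must lie in [0, 255]")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  region <- match.arg(region, c("dorsal", "intermediate", "ventral"))
  structure(list(pixels = pixels, masks = masks,
                 pixel_size_um = pixel_size_um, region = region,
                 section_index = as.integer(section_index),
                 animal_id = animal_id, hemisphere = hemisphere,
                 truth = truth),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("section_image %dx%d px (%.3g um/px), %s region, section %d, animal %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$region,
              x$section_index, x$animal_id))
  if (!is.null(x$truth$true_fraction))
    cat(sprintf("  true DCX+ fraction of GCL: %.4f\n", x$truth$true_fraction))
  invisible(x)
}

# fixed frame geometry: a GCL band with a clean sub-rectangle
dcx_frame_masks <- function(n) {
  m <- matrix(0L, n, n)
  band <- seq.int(round(n * 0.32), round(n * 0.64))
  m[band, ] <- MASK_GCL
  clean_rows <- seq.int(round(n * 0.42), round(n * 0.55))
  clean_cols <- seq.int(round(n * 0.07), round(n * 0.22))
  m[clean_rows, clean_cols] <- MASK_CLEAN
  m
}

# choose exactly k stained pixels among candidates: soma disks (radius 2)
# first, then single-pixel dendrite fragments to reach the exact count
place_stain <- function(candidates, k, nrow_px, ncol_px) {
  if (k <= 0L) return(integer(0))
  if (k > length(candidates))
    stop("invalid config: requested stained fraction exceeds available GCL area")
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 4, ]
  n_disks <- max(1L, floor(k / nrow(offs) * 0.8))
  centers <- sample(candidates, min(n_disks, length(candidates)))
  cr <- (centers - 1L) %% nrow_px + 1L
  cc <- (centers - 1L) %/% nrow_px + 1L
  rr <- rep(cr, each = nrow(offs)) + offs$dr
  ccx <- rep(cc, each = nrow(offs)) + offs$dc
  ok <- rr >= 1L & rr <= nrow_px & ccx >= 1L & ccx <= ncol_px
  disk_px <- unique((ccx[ok] - 1L) * nrow_px + rr[ok])
  disk_px <- intersect(disk_px, candidates)
  if (length(disk_px) >= k) return(sample(disk_px, k))
  extra <- sample(setdiff(candidates, disk_px), k - length(disk_px))
  c(disk_px, extra)
}

render_dcx_frame <- function(frac, config, region, section_index, animal_id) {
  n <- config$frame_px
  masks <- dcx_frame_masks(n)
  gcl_idx <- which(masks == MASK_GCL | masks == MASK_CLEAN)
  candidates <- which(masks == MASK_GCL)   # clean ROI stays stain-free
  k <- round(frac * length(gcl_idx))
  pos <- place_stain(candidates, k, n, n)
  mu_bg <- config$gray_bg + rnorm(1, 0, 3)   # per-frame staining-batch shift
  px <- matrix(rnorm(n * n, mu_bg, config$pixel_sd), n, n)
  if (length(pos)) px[pos] <- rnorm(length(pos), config$gray_pos, config$pixel_sd)
  px <- matrix(as.integer(pmin(255, pmax(0, floor(px + 0.5)))), n, n)
  section_image(px, masks, config$pixel_size_um, region, section_index,
                animal_id = animal_id,
                truth = list(true_fraction = k / length(gcl_idx),
                             positive_px = length(pos),
                             gcl_px = length(gcl_idx)))
}

#' Generate synthetic DCX-stained section frames for one animal
#'
#' Emits 4-6 serial frames per region (dorsal and ventral). Each frame holds
#' a Gaussian tissue background, a GCL band mask containing a stain-free
#' clean ROI, and dark DCX+ stain (soma disks plus single-pixel dendrite
#' fragments) covering an exactly recorded fraction of GCL pixels. The
#' animal's true stained fraction is the configured control fraction times
#' the enrichment fold (for E animals) times a per-animal lognormal factor.
#'
#' @param animal one row of [generate_cohort()] output (must be IHC arm).
#' @param config a [generator_config()].
#' @return list of \code{section_image} frames, each carrying its truth.
#' @export
generate_section_images <- function(animal, config) {
  validate_generator_config(config)
  if (!identical(animal$arm, "IHC"))
    stop("section images are generated for IHC-arm animals only")
  set.seed(animal_seed(config, "dcx", animal$animal_id))
  frames <- list()
  for (region in c("dorsal", "ventral")) {
    frac <- config$dcx_fraction_control[[region]]
    if (identical(animal$treatment, "E"))
      frac <- frac * config$dcx_fold_enriched[[region]]
    sdl <- sqrt(log(1 + config$animal_fraction_cv^2))
    frac <- frac * rlnorm(1, -sdl^2 / 2, sdl)   # mean-one animal factor
    if (frac >= 1) stop("invalid config: stained fraction reached 1 after fold")
    n_sec <- sample_range(config$n_sections_range)
    for (s in seq_len(n_sec))
      frames[[length(frames) + 1L]] <-
        render_dcx_frame(frac, config, region, s, animal$animal_id)
  }
  frames
}

bdnf_frame_masks <- function(n) {
  m <- matrix(0L, n, n)
  put <- function(m, label, r0, c0, h, w) {
    m[r0:min(n, r0 + h - 1L), c0:min(n, c0 + w - 1L)] <- label
    m
  }
  h <- max(4L, round(n * 0.12)); w <- max(6L, round(n * 0.16))
  m <- put(m, MASK_SITES[["suprapyramidal"]], round(n * 0.15), round(n * 0.10), h, w)
  m <- put(m, MASK_SITES[["infrapyramidal"]], round(n * 0.60), round(n * 0.10), h, w)
  m <- put(m, MASK_SITES[["hilus"]], round(n * 0.38), round(n * 0.40), h, w)
  m <- put(m, MASK_SITES[["mossy_fibers"]], round(n * 0.38), round(n * 0.70), h, w)
  m <- put(m, MASK_CC, round(n * 0.80), round(n * 0.55),
           max(4L, round(n * 0.10)), max(8L, round(n * 0.25)))
  m
}

#' Generate synthetic BDNF densitometry frames for one animal
#'
#' Emits one frame per serial section per region (dorsal and ventral), each
#' carrying four rectangular sampling-site ROIs (suprapyramidal and
#' infrapyramidal blades, hilus, mossy fibers) and a corpus-callosum ROI.
#' Pixel gray values encode a configured true optical density per site on
#' top of the corpus-callosum background density; ventral sites are darker
#' by \code{bdnf_rod_ventral_excess}. Per-ROI true ODs are stored as truth.
#'
#' @inheritParams generate_section_images
#' @return list of \code{section_image} frames.
#' @export
generate_bdnf_images <- function(animal, config) {
  validate_generator_config(config)
  if (!identical(animal$arm, "IHC"))
    stop("BDNF frames are generated for IHC-arm animals only")
  set.seed(animal_seed(config, "bdnf", animal$animal_id))
  n <- config$frame_px
  masks <- bdnf_frame_masks(n)
  gray_noise <- config$pixel_sd / 4
  # biological between-animal variation in BDNF level (sites only, recorded
  # in the per-frame truth); scaled off the pixel noise so a noise-free
  # config is fully deterministic
  animal_offset <- rnorm(1, 0, 0.0015 * config$pixel_sd)
  frames <- list()
  for (region in c("dorsal", "ventral")) {
    excess <- (if (region == "ventral") config$bdnf_rod_ventral_excess else 0) +
      animal_offset
    for (s in 1:4) {
      od <- matrix(config$bdnf_background_od, n, n)
      for (site in names(MASK_SITES))
        od[masks == MASK_SITES[[site]]] <-
          config$bdnf_background_od + config$bdnf_site_od[[site]] + excess
      gray <- 255 * 10^(-od) + matrix(rnorm(n * n, 0, gray_noise), n, n)
      if (any(gray < 1))
        warning("optical density produced gray < 1; values clipped")
      gray <- matrix(as.integer(pmin(255, pmax(1, floor(gray + 0.5)))), n, n)
      frames[[length(frames) + 1L]] <-
        section_image(gray, masks, 2 * config$pixel_size_um, region, s,
                      animal_id = animal$animal_id,
                      truth = list(site_od = config$bdnf_site_od + excess,
                                   background_od = config$bdnf_background_od))
    }
  }
  frames
}
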