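#' Optical density of an 8-bit gray value
#'
#' Uncalibrated optical density \code{log10(255 / gray)} with gray clamped to
#' at least 1, monotone decreasing in gray (darker pixels have higher OD). A
#' step-tablet calibration curve is out of scope; only relative (background
#' corrected) densities are interpreted.
#'
#' @param gray integer gray values in [0, 255].
#' @return numeric OD values.
#' @examples
#' pixel_od(255)  # 0
#' pixel_od(25)   # 1.0086
#' @export
pixel_od <- function(gray) {
  if (any(gray < 0 | gray > 255))
    stop("format error: gray values must lie in [0, 255]")
  log10(255 / pmax(gray, 1))
}

#' Mean optical density of a sampling-site ROI
#'
#' Averages per-pixel OD over the pixels carrying the requested mask label.
#'
#' @param image a \code{section_image}.
#' @param site_label integer mask label (10-13 for sampling sites, 20 for
#'   corpus callosum) or a site name
#'   ("suprapyramidal", "infrapyramidal", "hilus", "mossy_fibers",
#'   "corpus_callosum").
#' @return mean OD of the ROI (\code{rod_raw}).
#' @export
roi_rod <- function(image, site_label) {
  if (is.character(site_label)) {
    site_label <- if (site_label == "corpus_callosum") MASK_CC
    else MASK_SITES[[match.arg(site_label, names(MASK_SITES))]]
  }
  px <- image$pixels[image$masks == site_label]
  if (!length(px))
    stop(sprintf("missing site: no pixels carry mask label %d", site_label))
  mean(pixel_od(px))
}

#' Background-corrected relative optical density per site
#'
#' For every frame of one animal, measures the raw ROD of the four sampling
#' sites and the corpus-callosum background, subtracts the background per
#' section, and averages the corrected values per region and site over the
#' animal's sections. Negative corrected values are permitted and flagged.
#'
#' @param frames list of \code{section_image} BDNF frames for one animal.
#' @return a data.frame (\code{animal_id}, \code{region}, \code{site},
#'   \code{rod_raw}, \code{rod_background}, \code{rod_corrected},
#'   \code{negative_flag}), one row per region x site, averaged over
#'   sections.
#' @export
background_correct <- function(frames) {
  stopifnot(length(frames) >= 1L)
  rows <- list()
  for (f in frames) {
    bg <- roi_rod(f, MASK_CC)
    for (site in names(MASK_SITES)) {
      raw <- roi_rod(f, MASK_SITES[[site]])
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = f$animal_id, region = f$region,
        section = f$section_index, site = site, rod_raw = raw,
        rod_background = bg, rod_corrected = raw - bg,
        stringsAsFactors = FALSE)
    }
  }
  per_sec <- do.call(rbind, rows)
  agg <- stats::aggregate(
    per_sec[c("rod_raw", "rod_background", "rod_corrected")],
    by = per_sec[c("animal_id", "region", "site")], FUN = mean)
  agg$negative_flag <- agg$rod_corrected < 0
  agg <- agg[order(agg$region, agg$site), ]
  rownames(agg) <- NULL
  agg
}
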