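#' Convert an RGB image to 8-bit grayscale
#'
#' Applies the standard luminance weights (0.299 R + 0.587 G + 0.114 B),
#' rounding half-up and clipping to [0, 255]. Synthetic frames are generated
#' directly in grayscale; this step exists for real RGB captures.
#'
#' @param rgb a 3-dimensional array (rows x cols x 3) of channel values in
#'   [0, 255].
#' @return an integer matrix of gray values.
#' @examples
#' px <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' to_grayscale(px)  # 141
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("format error: expected a rows x cols x 3 RGB array")
  if (any(rgb < 0 | rgb > 255))
    stop("format error: channel values must lie in [0, 255]")
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(as.integer(pmin(255, pmax(0, floor(g + 0.5)))),
         nrow = dim(rgb)[1], ncol = dim(rgb)[2])
}

#' Per-section adaptive DAB threshold
#'
#' Computes the mean and sample standard deviation of gray values over the
#' stain-free clean ROI of a section and returns the threshold
#' \code{mean - 2 * sd}. DAB-stained (DCX+) pixels are darker than tissue, so
#' pixels strictly below this threshold count as positive. One threshold is
#' computed per section and applied to every frame of that section's montage.
#'
#' @param image a \code{section_image} whose mask contains a clean ROI
#'   (label 2), or an integer/numeric vector of clean-ROI gray values.
#' @return a list (\code{threshold_result}) with \code{mean_gray},
#'   \code{sd_gray} and \code{threshold}.
#' @examples
#' compute_threshold(c(90, 110))  # mean 100, sd 14.14, threshold 71.72
#' @export
compute_threshold <- function(image) {
  vals <- if (inherits(image, "section_image"))
    image$pixels[image$masks == MASK_CLEAN]
  else as.numeric(image)
  if (length(vals) < 2L)
    stop("insufficient ROI: the clean ROI must contain at least 2 pixels")
  m <- mean(vals)
  s <- stats::sd(vals)          # sample SD, n - 1 denominator
  structure(list(mean_gray = m, sd_gray = s, threshold = m - 2 * s),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("clean-ROI mean %.2f, SD %.2f -> threshold %.2f (mean - 2 SD)\n",
              x$mean_gray, x$sd_gray, x$threshold))
  invisible(x)
}

#' Measure DCX-positive and GCL areas of one frame
#'
#' Counts GCL pixels (labels 1 and 2) whose gray value lies strictly below
#' the threshold and converts pixel counts to areas using the frame's
#' calibration.
#'
#' @param image a \code{section_image}.
#' @param threshold a gray-value threshold or a \code{threshold_result}.
#' @return named numeric: \code{dcx_area_um2}, \code{gcl_area_um2}.
#' @export
measure_dcx_area <- function(image, threshold) {
  if (inherits(threshold, "threshold_result")) threshold <- threshold$threshold
  gcl <- image$masks == MASK_GCL | image$masks == MASK_CLEAN
  if (!any(gcl)) stop("GCL mask is empty")
  if (threshold <= 0)
    warning("threshold <= 0: no pixel can be positive")
  px2 <- image$pixel_size_um^2
  c(dcx_area_um2 = sum(image$pixels[gcl] < threshold) * px2,
    gcl_area_um2 = sum(gcl) * px2)
}

#' Aggregate DCX measurements to per-animal, per-region normalized values
#'
#' Sums DCX-positive and GCL areas over frames, sections and hemispheres and
#' returns the ratio of the summed totals (a pooled ratio, not a mean of
#' per-section ratios), separately per region. One threshold is computed per
#' section from its clean ROI and applied to all frames of that section.
#' Intermediate-region frames are excluded by default, matching a design in
#' which that region is left out of the dorso-ventral contrast.
#'
#' @param frames list of \code{section_image} frames for one animal.
#' @param regions regions to aggregate (default dorsal and ventral).
#' @param per_frame_threshold if TRUE, compute a threshold per frame instead
#'   of one per section.
#' @return a data.frame with one row per region: \code{animal_id},
#'   \code{region}, \code{dcx_area_um2}, \code{gcl_area_um2},
#'   \code{normalized}.
#' @export
aggregate_dcx <- function(frames, regions = c("dorsal", "ventral"),
                          per_frame_threshold = FALSE) {
  stopifnot(length(frames) >= 1L)
  meta <- data.frame(
    region = vapply(frames, function(f) f$region, ""),
    section = vapply(frames, function(f) f$section_index, 1L),
    stringsAsFactors = FALSE)
  animal_id <- frames[[1]]$animal_id
  out <- list()
  for (rg in regions) {
    idx <- which(meta$region == rg)
    if (!length(idx)) next
    dcx <- 0; gcl <- 0
    for (sec in unique(meta$section[idx])) {
      sidx <- idx[meta$section[idx] == sec]
      if (!per_frame_threshold) {
        # one clean ROI per section: pool clean pixels over its frames
        vals <- unlist(lapply(frames[sidx],
                              function(f) f$pixels[f$masks == MASK_CLEAN]))
        thr <- compute_threshold(vals)
      }
      for (j in sidx) {
        if (per_frame_threshold) thr <- compute_threshold(frames[[j]])
        a <- measure_dcx_area(frames[[j]], thr)
        dcx <- dcx + a[["dcx_area_um2"]]
        gcl <- gcl + a[["gcl_area_um2"]]
      }
    }
    if (gcl == 0) stop("undefined ratio: GCL area is zero")
    out[[rg]] <- data.frame(animal_id = animal_id, region = rg,
                            dcx_area_um2 = dcx, gcl_area_um2 = gcl,
                            normalized = dcx / gcl, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
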