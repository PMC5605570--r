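#' Cavalieri volume from serial-section outline areas
#'
#' Estimates volume as the sum of outline area times the distance to the next
#' section, with 240 um used for the last section of every series (the
#' as-written rule; set \code{last_section_rule = "interval"} to use the
#' series' own sampling interval instead). Input rows are one series for a
#' single animal/region/subfield; unordered rows are reordered with a
#' warning, duplicate positions are an error. Volumes are returned in mm^3.
#'
#' @param outlines data.frame with columns \code{section_position_um},
#'   \code{area_um2} and optionally \code{spacing_to_next_um} (required for
#'   the "interval" rule), plus identifying columns \code{animal_id},
#'   \code{region}, \code{subfield}, \code{staining_method}.
#' @param last_section_rule "paper" (240 um for the last section) or
#'   "interval" (the series' sampling interval).
#' @return a one-row data.frame: \code{animal_id}, \code{region},
#'   \code{subfield}, \code{volume_mm3}, \code{staining_method}.
#' @examples
#' o <- data.frame(animal_id = "a", region = "dorsal", subfield = "DG",
#'                 section_position_um = c(0, 480), area_um2 = c(1e6, 1e6),
#'                 spacing_to_next_um = c(480, 240), staining_method = "cresyl")
#' cavalieri_volume(o)$volume_mm3  # (480 + 240) * 1e6 / 1e9 = 0.72
#' @export
cavalieri_volume <- function(outlines, last_section_rule = c("paper", "interval")) {
  last_section_rule <- match.arg(last_section_rule)
  stopifnot(nrow(outlines) >= 1L)
  if (any(outlines$area_um2 < 0)) stop("outline areas must be nonnegative")
  pos <- outlines$section_position_um
  if (anyDuplicated(pos)) stop("duplicate section positions")
  if (is.unsorted(pos)) {
    warning("sections were not ordered by position; reordering")
    outlines <- outlines[order(pos), ]
    pos <- outlines$section_position_um
  }
  k <- nrow(outlines)
  spacing <- if (k > 1L) diff(pos) else numeric(0)
  last <- if (last_section_rule == "paper") 240
  else if (k > 1L) spacing[k - 1L]
  else if (!is.null(outlines$spacing_to_next_um)) outlines$spacing_to_next_um[k]
  else 240
  s <- c(spacing, last)
  if (any(s <= 0)) stop("section spacings must be positive")
  data.frame(animal_id = outlines$animal_id[1],
             region = outlines$region[1],
             subfield = outlines$subfield[1],
             volume_mm3 = sum(outlines$area_um2 * s) / 1e9,
             staining_method = if (!is.null(outlines$staining_method))
               outlines$staining_method[1] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Cavalieri volumes for a whole outline table
#'
#' Applies [cavalieri_volume()] to every animal x region x subfield series.
#'
#' @inheritParams cavalieri_volume
#' @return a data.frame of volume estimates, one row per series.
#' @export
cavalieri_volumes <- function(outlines, last_section_rule = c("paper", "interval")) {
  last_section_rule <- match.arg(last_section_rule)
  split_by <- interaction(outlines$animal_id, outlines$region,
                          outlines$subfield, drop = TRUE)
  res <- do.call(rbind, lapply(split(outlines, split_by), cavalieri_volume,
                               last_section_rule = last_section_rule))
  rownames(res) <- NULL
  res
}

#' DG/CA volume ratios per animal and region
#'
#' @param volumes output of [cavalieri_volumes()] with DG and CA rows per
#'   animal/region.
#' @return list with \code{per_animal} (animal_id, region, ratio) and
#'   \code{cohort_mean} (region, mean_ratio).
#' @export
dgca_ratio <- function(volumes) {
  wide <- merge(volumes[volumes$subfield == "DG",
                        c("animal_id", "region", "volume_mm3")],
                volumes[volumes$subfield == "CA",
                        c("animal_id", "region", "volume_mm3")],
                by = c("animal_id", "region"), suffixes = c("_dg", "_ca"))
  if (any(wide$volume_mm3_ca == 0))
    stop("undefined ratio: CA volume is zero")
  wide$ratio <- wide$volume_mm3_dg / wide$volume_mm3_ca
  per_animal <- wide[c("animal_id", "region", "ratio")]
  cohort <- stats::aggregate(list(mean_ratio = per_animal$ratio),
                             by = per_animal["region"], FUN = mean)
  list(per_animal = per_animal, cohort_mean = cohort)
}
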