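#' Write a section image and its mask as 8-bit PNG files
#'
#' The gray frame goes to \code{<prefix>.png} and the label mask to
#' \code{<prefix>_mask.png} (labels stored as raw 8-bit values). Spatial
#' calibration and metadata are not stored in the PNG; supply them again
#' when reading.
#'
#' @param image a \code{section_image}.
#' @param prefix file path prefix (no extension).
#' @return invisibly, the two paths written.
#' @export
write_section_image <- function(image, prefix) {
  stopifnot(inherits(image, "section_image"))
  p_img <- paste0(prefix, ".png")
  p_mask <- paste0(prefix, "_mask.png")
  png::writePNG(image$pixels / 255, p_img)
  png::writePNG(image$masks / 255, p_mask)
  invisible(c(p_img, p_mask))
}

#' Read a section image and its mask from PNG files
#'
#' @param prefix file path prefix used by [write_section_image()].
#' @param pixel_size_um microns per pixel.
#' @param region region label.
#' @param section_index section position in its series.
#' @param animal_id animal identifier.
#' @return a \code{section_image}.
#' @export
read_section_image <- function(prefix, pixel_size_um, region,
                               section_index = 1L,
                               animal_id = NA_character_) {
  px <- png::readPNG(paste0(prefix, ".png"))
  mk <- png::readPNG(paste0(prefix, "_mask.png"))
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (length(dim(mk)) == 3L) mk <- mk[, , 1]
  section_image(round(px * 255), round(mk * 255), pixel_size_um, region,
                section_index, animal_id)
}
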