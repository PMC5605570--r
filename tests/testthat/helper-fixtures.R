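# shared fixtures: a small fast generator config and hand-built frames

tiny_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_batches = 1L, animals_per_batch = 6L,
                   frame_px = 48L, n_sections_range = c(2L, 2L),
                   n_days = 2L, windows_per_day = 6L, ...)
}

# frame with an explicit positive-pixel set: background at bg_gray, k stained
# pixels at pos_gray inside the GCL band, clean ROI left unstained
make_dcx_frame <- function(k = 50, bg_gray = 180, pos_gray = 40,
                           pixel_size_um = 1, n = 48, region = "dorsal",
                           section_index = 1L, animal_id = "a1") {
  masks <- dgquant:::dcx_frame_masks(n)
  px <- matrix(bg_gray, n, n)
  candidates <- which(masks == 1L)
  pos <- if (k > 0) candidates[seq_len(k)] else integer(0)
  px[pos] <- pos_gray
  section_image(px, masks, pixel_size_um, region, section_index,
                animal_id = animal_id,
                truth = list(positive_px = k,
                             gcl_px = sum(masks %in% 1:2),
                             true_fraction = k / sum(masks %in% 1:2)))
}

first_animal <- function(cohort, arm = "IHC", treatment = NULL) {
  sel <- cohort$arm == arm
  if (!is.null(treatment)) sel <- sel & cohort$treatment == treatment
  cohort[which(sel)[1], ]
}
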