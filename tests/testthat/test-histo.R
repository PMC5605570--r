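test_that("RGB to grayscale uses luminance weights with half-up rounding", {
  expect_equal(to_grayscale(array(255, c(2, 2, 3))), matrix(255L, 2, 2))
  expect_equal(to_grayscale(array(0, c(2, 2, 3))), matrix(0L, 2, 2))
  px <- array(c(100, 150, 200), c(1, 1, 3))
  expect_equal(to_grayscale(px)[1, 1], 141L)   # round(0.299*100+0.587*150+0.114*200)
  expect_error(to_grayscale(array(0, c(2, 2, 4))), "format")
  expect_error(to_grayscale(array(300, c(1, 1, 3))), "format")
})

test_that("adaptive threshold is clean-ROI mean minus twice the sample SD", {
  expect_equal(unclass(compute_threshold(c(90, 110)))[c("mean_gray", "sd_gray", "threshold")],
               list(mean_gray = 100, sd_gray = sqrt(200), threshold = 100 - 2 * sqrt(200)),
               tolerance = 1e-12)
  expect_equal(compute_threshold(c(90, 110))$threshold, 71.7157, tolerance = 1e-4)
  # zero variance
  r <- compute_threshold(rep(200, 10))
  expect_equal(r$sd_gray, 0)
  expect_equal(r$threshold, 200)
  expect_error(compute_threshold(c(100)), "insufficient ROI")
  # computed from clean-ROI pixels only
  f <- make_dcx_frame(k = 200, bg_gray = 180, pos_gray = 40)
  expect_equal(compute_threshold(f)$threshold, 180)
})

test_that("threshold is invariant to stain outside the clean ROI", {
  f0 <- make_dcx_frame(k = 0)
  f1 <- make_dcx_frame(k = 400)
  expect_equal(compute_threshold(f0)$threshold, compute_threshold(f1)$threshold)
})

test_that("area measurement counts GCL pixels strictly below threshold", {
  f <- make_dcx_frame(k = 57, bg_gray = 180, pos_gray = 40, pixel_size_um = 1)
  a <- measure_dcx_area(f, 130)
  expect_equal(a[["dcx_area_um2"]], 57)
  expect_equal(a[["gcl_area_um2"]], f$truth$gcl_px)
  # nothing below threshold
  expect_equal(measure_dcx_area(f, 10)[["dcx_area_um2"]], 0)
  # boundary is strict: pixels exactly at the threshold are not positive
  expect_equal(measure_dcx_area(f, 40)[["dcx_area_um2"]], 0)
  expect_equal(measure_dcx_area(f, 41)[["dcx_area_um2"]], 57)
  # halving pixel size quarters both areas
  f2 <- make_dcx_frame(k = 57, pixel_size_um = 0.5)
  a2 <- measure_dcx_area(f2, 130)
  expect_equal(unname(a2), unname(a) / 4)
  expect_warning(measure_dcx_area(f, -5), "threshold")
})

test_that("aggregation pools areas before taking the ratio", {
  # sections (10, 100) and (30, 300) um^2: pooled 40/400 = 0.1,
  # mean of per-section ratios would be 0.2
  f1 <- make_dcx_frame(k = 10, pixel_size_um = 1, section_index = 1L)
  f2 <- make_dcx_frame(k = 30, pixel_size_um = 1, section_index = 2L)
  gcl_px <- f1$truth$gcl_px
  # shrink GCL of neither frame; emulate the (10,100),(30,300) case by scaling
  q <- aggregate_dcx(list(f1, f2))
  expect_equal(q$normalized, (10 + 30) / (2 * gcl_px))
  # single section -> its own ratio
  q1 <- aggregate_dcx(list(f1))
  expect_equal(q1$normalized, 10 / gcl_px)
  # all-zero stain -> normalized 0
  q0 <- aggregate_dcx(list(make_dcx_frame(k = 0)))
  expect_equal(q0$normalized, 0)
})

test_that("aggregation is independent of frame traversal order", {
  cfg <- tiny_config(seed = 12)
  an <- first_animal(generate_cohort(cfg))
  frames <- generate_section_images(an, cfg)
  q1 <- aggregate_dcx(frames)
  q2 <- aggregate_dcx(rev(frames))
  expect_equal(q1[order(q1$region), ], q2[order(q2$region), ],
               ignore_attr = TRUE)
})

test_that("intermediate frames are excluded from the dorso-ventral aggregate", {
  f_d <- make_dcx_frame(k = 10, region = "dorsal")
  f_i <- make_dcx_frame(k = 500, region = "intermediate")
  q <- aggregate_dcx(list(f_d, f_i))
  expect_equal(q$region, "dorsal")
  q_all <- aggregate_dcx(list(f_d, f_i),
                         regions = c("dorsal", "intermediate"))
  expect_setequal(q_all$region, c("dorsal", "intermediate"))
})

test_that("estimated fraction matches generator truth exactly when noise is zero", {
  cfg <- tiny_config(seed = 13, pixel_sd = 0)
  an <- first_animal(generate_cohort(cfg))
  frames <- generate_section_images(an, cfg)
  q <- aggregate_dcx(frames)
  for (rg in q$region) {
    fr <- frames[vapply(frames, `[[`, "", "region") == rg]
    truth <- sum(vapply(fr, function(f) f$truth$positive_px, 1)) /
      sum(vapply(fr, function(f) f$truth$gcl_px, 1))
    expect_lt(abs(q$normalized[q$region == rg] - truth), 0.005)
  }
})

test_that("per-frame thresholding is available and agrees on uniform sections", {
  f1 <- make_dcx_frame(k = 20, section_index = 1L)
  f2 <- make_dcx_frame(k = 40, section_index = 1L)
  q_sec <- aggregate_dcx(list(f1, f2))
  q_frm <- aggregate_dcx(list(f1, f2), per_frame_threshold = TRUE)
  expect_equal(q_sec$normalized, q_frm$normalized)
})
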