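test_that("cohort design satisfies its counting invariants", {
  cohort <- generate_cohort(generator_config(seed = 11))
  expect_equal(nrow(cohort), 96L)
  expect_equal(sum(cohort$arm == "IHC" & cohort$treatment == "E"), 16L)
  expect_equal(sum(cohort$arm == "IHC" & cohort$treatment == "C"), 16L)
  # 3 animals per cage, exactly one per arm in each cage
  per_cage <- table(cohort$cage_id)
  expect_true(all(per_cage == 3L))
  arm_by_cage <- table(cohort$cage_id, cohort$arm)
  expect_true(all(arm_by_cage == 1L))
  # cages within each batch split equally between E and C
  cage_trt <- unique(cohort[c("batch", "cage_id", "treatment")])
  split_tab <- table(cage_trt$batch, cage_trt$treatment)
  expect_true(all(split_tab == 4L))
  # only enriched mice carry distinguishing marks
  expect_true(all(cohort$mark_pattern[cohort$treatment == "C"] == "none"))
  expect_true(all(table(cohort$cage_id[cohort$treatment == "E"],
                        cohort$mark_pattern[cohort$treatment == "E"]) == 1L))
})

test_that("smallest balanced design and invalid designs behave", {
  cohort <- generate_cohort(generator_config(seed = 2, n_batches = 1,
                                             animals_per_batch = 6))
  expect_equal(nrow(cohort), 6L)
  expect_equal(length(unique(cohort$cage_id)), 2L)
  expect_setequal(unique(cohort$treatment), c("E", "C"))
  expect_error(generator_config(animals_per_batch = 10),
               "divisible by 3|split equally")
  expect_error(generator_config(dcx_fraction_control = c(dorsal = 0.9,
                                                         ventral = 0.2)),
               "exceed 1")
  expect_error(generator_config(wheel_circumference_m = -1), "circumference")
})

test_that("fixed seed reproduces every modality bit-for-bit", {
  cfg <- tiny_config(seed = 5)
  c1 <- generate_cohort(cfg); c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  an <- first_animal(c1)
  f1 <- generate_section_images(an, cfg)
  f2 <- generate_section_images(an, cfg)
  expect_identical(lapply(f1, `[[`, "pixels"), lapply(f2, `[[`, "pixels"))
  expect_identical(generate_outlines(an, cfg), generate_outlines(an, cfg))
  g1 <- generate_activity_and_expression(c1, cfg)
  g2 <- generate_activity_and_expression(c1, cfg)
  expect_identical(g1, g2)
})

test_that("DCX frames carry exact ground truth at the configured fraction", {
  cfg <- tiny_config(seed = 3)
  an <- first_animal(generate_cohort(cfg), treatment = "C")
  frames <- generate_section_images(an, cfg)
  expect_true(length(frames) >= 4L)
  for (f in frames) {
    pos_true <- f$truth$positive_px
    # stained pixels are exactly those rendered dark: count below midpoint
    gcl <- f$masks %in% 1:2
    expect_equal(sum(f$pixels[gcl] < 120), pos_true, tolerance = 0)
    expect_equal(f$truth$true_fraction, pos_true / f$truth$gcl_px)
    # clean ROI is never stained
    expect_true(all(f$pixels[f$masks == 2L] > 120))
  }
})

test_that("zero stained fraction yields empty positive-pixel truth", {
  cfg <- tiny_config(seed = 4,
                     dcx_fraction_control = c(dorsal = 0, ventral = 0),
                     animal_fraction_cv = 0)
  an <- first_animal(generate_cohort(cfg))
  frames <- generate_section_images(an, cfg)
  expect_true(all(vapply(frames, function(f) f$truth$positive_px, 1) == 0))
})

test_that("generated true DCX fractions hit their configured targets in expectation", {
  cfg <- tiny_config(seed = 9)
  cohort <- generate_cohort(generator_config(seed = 9))
  ihc_e <- cohort[cohort$arm == "IHC" & cohort$treatment == "E", ]
  ihc_c <- cohort[cohort$arm == "IHC" & cohort$treatment == "C", ]
  frac_of <- function(animals, region, n = 100) {
    vapply(seq_len(n), function(i) {
      an <- animals[(i - 1) %% nrow(animals) + 1, ]
      an$animal_id <- paste0(an$animal_id, "_rep", i)  # fresh noise draw
      fr <- generate_section_images(an, cfg)
      fr <- fr[vapply(fr, `[[`, "", "region") == region]
      sum(vapply(fr, function(f) f$truth$positive_px, 1)) /
        sum(vapply(fr, function(f) f$truth$gcl_px, 1))
    }, numeric(1))
  }
  fe <- frac_of(ihc_e, "dorsal"); fc <- frac_of(ihc_c, "dorsal")
  target_e <- cfg$dcx_fraction_control[["dorsal"]] * 1.4
  target_c <- cfg$dcx_fraction_control[["dorsal"]]
  expect_lt(abs(mean(fe) - target_e), 3 * sd(fe) / sqrt(length(fe)) + 0.002)
  expect_lt(abs(mean(fc) - target_c), 3 * sd(fc) / sqrt(length(fc)) + 0.002)
  expect_equal(mean(fe) / mean(fc), 1.4, tolerance = 0.05)
})

test_that("BDNF frames encode the configured site ordering and ventral excess", {
  cfg <- tiny_config(seed = 6, pixel_sd = 0)   # noise-free
  an <- first_animal(generate_cohort(cfg))
  frames <- generate_bdnf_images(an, cfg)
  dorsal <- frames[[1]]$truth$site_od
  ventral <- frames[[5]]$truth$site_od
  expect_equal(unname(ventral - dorsal),
               rep(cfg$bdnf_rod_ventral_excess, 4))
  expect_lt(dorsal[["hilus"]], dorsal[["infrapyramidal"]])
  expect_lt(dorsal[["infrapyramidal"]], dorsal[["suprapyramidal"]])
  expect_equal(dorsal[["suprapyramidal"]], dorsal[["mossy_fibers"]],
               tolerance = 0.08)
})

test_that("outline series Cavalieri-sum to their target volumes", {
  cfg <- tiny_config(seed = 7, area_cv = 0, animal_volume_cv = 0)
  an <- first_animal(generate_cohort(cfg), treatment = "C")
  o <- generate_outlines(an, cfg)
  truth <- attr(o, "truth")
  vols <- cavalieri_volumes(o)
  m <- merge(vols, truth, by = c("animal_id", "region", "subfield"))
  expect_equal(m$volume_mm3, m$true_volume_mm3, tolerance = 1e-12)
  # configured geometry: DG/CA ratios and the enriched dorsal excess
  r <- dgca_ratio(vols)$cohort_mean
  expect_equal(r$mean_ratio[r$region == "ventral"], 0.21, tolerance = 1e-10)
  expect_equal(r$mean_ratio[r$region == "dorsal"], 0.63, tolerance = 1e-10)
  an_e <- first_animal(generate_cohort(cfg), treatment = "E")
  ve <- cavalieri_volumes(generate_outlines(an_e, cfg))
  dors <- function(v) sum(v$volume_mm3[v$region == "dorsal"])
  expect_equal(dors(ve) / dors(vols), 1.15, tolerance = 1e-10)
})

test_that("activity logs exist only for enriched cages and stay in range", {
  cfg <- tiny_config(seed = 8)
  cohort <- generate_cohort(cfg)
  gen <- generate_activity_and_expression(cohort, cfg)
  e_cages <- unique(cohort$cage_id[cohort$treatment == "E"])
  expect_setequal(unique(gen$activity$cage_id), e_cages)
  expect_true(all(gen$activity$run_seconds >= 0 &
                    gen$activity$run_seconds <= 180))
  expect_true(all(gen$activity$total_spins >= 0))
  # truth rides alongside every modality
  expect_true(all(c("distance", "expression", "curves") %in%
                    names(gen$truth)))
  expect_setequal(gen$truth$distance$animal_id,
                  cohort$animal_id[cohort$treatment == "E"])
})

test_that("generator standard-curve efficiencies lie in the reported 98-104% range", {
  for (s in 1:5) {
    gen <- generate_activity_and_expression(
      generate_cohort(tiny_config(seed = s)), tiny_config(seed = s))
    expect_true(all(gen$truth$curves$efficiency >= 0.98 &
                      gen$truth$curves$efficiency <= 1.04))
  }
})
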