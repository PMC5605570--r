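#' Generate synthetic activity logs and molecular readouts
#'
#' Simulates, for every enriched cage-day, per-mouse latent running
#' propensities, the observed per-mouse running seconds in each sampled
#' 3-minute video window (binomial sampling of the latent running fraction),
#' and a daily spin total for the cage's three wheels consistent with the
#' latent distances. Control cages have no wheels and contribute no rows.
#'
#' Molecular readouts follow the cohort's assay arms: PCR-arm animals get Cq
#' values for Dcx, Bdnf and Prox1 in dorsal and ventral DG (generated from
#' per-gene standard curves with efficiencies drawn in 98-104%), plus the
#' serial-dilution standards needed to quantify them; ELISA-arm animals get
#' DCX and PROX1 protein quantities (pg). Dcx/Prox1 ratios follow the
#' configured region-by-treatment folds. Ventral Bdnf/Prox1 of enriched
#' animals is linear in the animal's true running distance with a residual SD
#' calibrated — net of the variance the Cq measurement chain adds — so the
#' squared correlation recovered by the full pipeline centres on
#' \code{bdnf_distance_r2_ventral}; the distance term is centred so coupling
#' adds no enrichment main effect. Dorsal Bdnf/Prox1 is independent of
#' distance.
#'
#' @param cohort the data.frame from [generate_cohort()].
#' @param config a [generator_config()].
#' @return a list with elements \code{activity} (long table: cage_id, day,
#'   window, animal_id, run_seconds, total_spins repeated per cage-day),
#'   \code{expression} (Cq table for PCR-arm animals), \code{standards}
#'   (per-gene dilution series), \code{protein} (pg table for ELISA-arm
#'   animals), and \code{truth} (per-animal true distances and true
#'   expression ratios).
#' @export
generate_activity_and_expression <- function(cohort, config) {
  validate_generator_config(config)
  set.seed(sub_seed(config, "activity"))
  e_cages <- unique(cohort$cage_id[cohort$treatment == "E"])
  W <- config$windows_per_day
  act_rows <- list()
  true_dist <- numeric(0)
  for (cg in e_cages) {
    mice <- cohort$animal_id[cohort$cage_id == cg]
    f <- pmin(0.4, config$running_fraction_mean *
                rlnorm(3, -config$running_fraction_sdlog^2 / 2,
                       config$running_fraction_sdlog))
    spins_total_mouse <- numeric(3)
    for (day in seq_len(config$n_days)) {
      f_day <- pmin(0.6, f * rlnorm(3, -0.3^2 / 2, 0.3))
      spins_day <- f_day * 86400 * config$spin_rate_hz
      secs <- matrix(rbinom(3L * W, 180L, rep(f_day, each = W)), nrow = W)
      act_rows[[length(act_rows) + 1L]] <- data.frame(
        cage_id = cg, day = day, window = rep(seq_len(W), 3L),
        animal_id = rep(mice, each = W), run_seconds = as.vector(secs),
        total_spins = round(sum(spins_day)), stringsAsFactors = FALSE)
      spins_total_mouse <- spins_total_mouse + spins_day
    }
    d <- spins_total_mouse * config$wheel_circumference_m / 1000
    names(d) <- mice
    true_dist <- c(true_dist, d)
  }
  activity <- do.call(rbind, act_rows)
  rownames(activity) <- NULL
  dist_truth <- data.frame(animal_id = names(true_dist),
                           true_distance_km = unname(true_dist),
                           stringsAsFactors = FALSE)

  # --- per-gene standard curves (efficiency 98-104%) -----------------------
  genes <- c("Dcx", "Bdnf", "Prox1")
  eff <- runif(3, 0.98, 1.04)
  curve_a <- rnorm(3, 35, 1)
  curve_b <- -1 / log10(1 + eff)
  names(eff) <- names(curve_a) <- names(curve_b) <- genes
  std_q <- 10^(6:1)
  standards <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, quantity = std_q,
               cq = curve_a[[g]] + curve_b[[g]] * log10(std_q) +
                 rnorm(length(std_q), 0, config$cq_sd),
               stringsAsFactors = FALSE)
  }))

  sdl_e <- sqrt(log(1 + config$expression_cv^2))
  pcr <- cohort[cohort$arm == "PCR", ]
  pcr_e <- pcr[pcr$treatment == "E", ]
  d_e <- dist_truth$true_distance_km[match(pcr_e$animal_id, dist_truth$animal_id)]
  # residual SD so the measured ventral r2 centres on the target after the
  # Cq chain adds lognormal measurement noise to the recovered ratio
  slope <- config$bdnf_distance_slope
  sig_ln <- sqrt(2) * log(10) * config$cq_sd / 3.3219
  meas_var <- (config$bdnf_ratio_base[["ventral"]])^2 * (exp(sig_ln^2) - 1)
  signal_var <- slope^2 * (if (length(d_e) >= 2L) stats::var(d_e) else 0)
  resid_var <- max(signal_var * (1 / config$bdnf_distance_r2_ventral - 1) -
                     meas_var, (0.02 * config$bdnf_ratio_base[["ventral"]])^2)
  sig_eps <- sqrt(resid_var)

  expr_rows <- list(); truth_rows <- list()
  for (i in seq_len(nrow(pcr))) {
    an <- pcr[i, ]
    di <- dist_truth$true_distance_km[match(an$animal_id, dist_truth$animal_id)]
    for (region in c("dorsal", "ventral")) {
      prox1 <- rlnorm(1, log(1e4), 0.3)
      r_dcx <- config$dcx_ratio_base[[region]]
      if (an$treatment == "E") r_dcx <- r_dcx * config$dcx_fold_enriched[[region]]
      r_dcx <- r_dcx * rlnorm(1, -sdl_e^2 / 2, sdl_e)
      base_b <- config$bdnf_ratio_base[[region]]
      d_center <- if (length(d_e)) mean(d_e) else 0
      if (region == "ventral") {
        dev <- if (an$treatment == "E") slope * (di - d_center) else 0
        r_bdnf <- max(0.05, base_b + dev + rnorm(1, 0, sig_eps))
      } else {
        r_bdnf <- base_b * rlnorm(1, -sdl_e^2 / 2, sdl_e)
      }
      q <- c(Dcx = r_dcx * prox1, Bdnf = r_bdnf * prox1, Prox1 = prox1)
      for (g in genes)
        expr_rows[[length(expr_rows) + 1L]] <- data.frame(
          animal_id = an$animal_id, region = region, gene = g,
          cq = curve_a[[g]] + curve_b[[g]] * log10(q[[g]]) +
            rnorm(1, 0, config$cq_sd),
          stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        animal_id = an$animal_id, region = region, modality = "mRNA",
        true_dcx_ratio = r_dcx, true_bdnf_ratio = r_bdnf,
        stringsAsFactors = FALSE)
    }
  }
  expression <- do.call(rbind, expr_rows)

  sdl_p <- sqrt(log(1 + config$elisa_cv^2))
  elisa <- cohort[cohort$arm == "ELISA", ]
  prot_rows <- list()
  for (i in seq_len(nrow(elisa))) {
    an <- elisa[i, ]
    for (region in c("dorsal", "ventral")) {
      prox1 <- rlnorm(1, log(50), 0.3)
      r <- config$dcx_protein_base[[region]]
      if (an$treatment == "E") r <- r * config$protein_fold[[region]]
      r <- r * rlnorm(1, -sdl_p^2 / 2, sdl_p)
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        animal_id = an$animal_id, region = region,
        protein = c("DCX", "PROX1"),
        pg = c(r * prox1 * rlnorm(1, -sdl_p^2 / 2, sdl_p), prox1),
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        animal_id = an$animal_id, region = region, modality = "protein",
        true_dcx_ratio = r, true_bdnf_ratio = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  protein <- do.call(rbind, prot_rows)
  rownames(expression) <- rownames(protein) <- NULL

  list(activity = activity, expression = expression, standards = standards,
       protein = protein,
       truth = list(distance = dist_truth,
                    expression = do.call(rbind, truth_rows),
                    curves = data.frame(gene = genes, intercept_a = curve_a,
                                        slope_b = curve_b, efficiency = eff,
                                        stringsAsFactors = FALSE)))
}
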