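test_that("IQR(2.2) rule flags by interpolated-quartile fences", {
  expect_false(any(iqr_outliers(1:5)))
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4, upper fence 4 + 2.2*2 = 8.4
  expect_equal(iqr_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # affine invariance (positive scale)
  set.seed(71)
  x <- c(rnorm(20), 50)
  expect_equal(iqr_outliers(3.7 * x + 11), iqr_outliers(x))
  # zero IQR: only exact equality passes
  expect_equal(iqr_outliers(c(5, 5, 5, 5, 7)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outliers(rep(4, 6))))
  expect_error(iqr_outliers(1:3), "at least 4")
})

test_that("outlier screen works per treatment-by-region cell with an audit trail", {
  d <- expand.grid(treatment = c("E", "C"), region = c("dorsal", "ventral"),
                   rep = 1:6, stringsAsFactors = FALSE)
  d$value <- seq_len(nrow(d)) / nrow(d)   # tight within-cell spread
  d$value[1] <- 100                       # extreme only within its cell
  scr <- screen_outliers(d)
  expect_true(scr$outlier[1])
  expect_equal(sum(scr$outlier), 1L)
  expect_equal(nrow(attr(scr, "audit")), 1L)
})

sim_exchangeable <- function(n_clusters, beta = c(1, 2), alpha = 0.5,
                             sigma = 1, seed = 73) {
  set.seed(seed)
  id <- rep(seq_len(n_clusters), each = 2)
  x <- rnorm(2 * n_clusters)
  u <- rep(rnorm(n_clusters, 0, sigma * sqrt(alpha)), each = 2)
  e <- u + rnorm(2 * n_clusters, 0, sigma * sqrt(1 - alpha))
  data.frame(y = beta[1] + beta[2] * x + e, x = x, id = id)
}

test_that("GEE under independence equals OLS on the stacked data", {
  d <- sim_exchangeable(30)
  # unbalance the clusters
  d <- d[-c(3, 10, 11), ]
  fit <- dg_gee(y ~ x, d, id = "id", corstr = "independence")
  ols <- lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$alpha, 0)
})

test_that("single-observation clusters give alpha 0 and the OLS fit", {
  d <- sim_exchangeable(40)
  d <- d[seq(1, nrow(d), by = 2), ]    # one obs per cluster
  fit <- dg_gee(y ~ x, d, id = "id", corstr = "exchangeable")
  expect_equal(fit$alpha, 0)
  expect_equal(unname(coef(fit)), unname(coef(lm(y ~ x, d))),
               tolerance = 1e-8)
})

test_that("exchangeable GEE recovers coefficients and working correlation", {
  d <- sim_exchangeable(200, beta = c(1, 2), alpha = 0.5)
  fit <- dg_gee(y ~ x, d, id = "id", corstr = "exchangeable")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$robust_cov))
  expect_lt(abs(coef(fit)[["x"]] - 2), 3 * se[2])
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 1), 3 * se[1])
  expect_lt(abs(fit$alpha - 0.5), 0.1)
})

test_that("sandwich covariance matches the model-based one for homoscedastic size-1 clusters", {
  # residuals of equal magnitude: sandwich = naive * (N - p) / N exactly,
  # the df convention being the only difference
  d <- data.frame(y = c(1, -1, 1, -1, 1, -1), id = 1:6)
  fit <- dg_gee(y ~ 1, d, id = "id", corstr = "independence")
  n <- nrow(d); p <- 1
  expect_equal(fit$robust_cov, fit$naive_cov * (n - p) / n,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Wald tests follow the quadratic form and its invariances", {
  d <- sim_exchangeable(60)
  fit <- dg_gee(y ~ x, d, id = "id")
  w <- wald_test(fit, matrix(c(0, 1), 1))
  expect_equal(w[["chisq"]],
               coef(fit)[["x"]]^2 / fit$robust_cov["x", "x"],
               tolerance = 1e-12)
  expect_equal(w[["df"]], 1)
  # invariant to invertible reparameterization of the same row space
  L2 <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  L3 <- matrix(c(2, 2, 0, -1), 2, byrow = TRUE)   # same span
  expect_equal(wald_test(fit, L2)[["chisq"]], wald_test(fit, L3)[["chisq"]],
               tolerance = 1e-8)
  expect_error(wald_test(fit, matrix(0, 1, 2)), "contrast error")
  # a zero coefficient with positive variance gives chisq 0, p 1
  fit0 <- fit; fit0$coefficients[["x"]] <- 0
  w0 <- wald_test(fit0, matrix(c(0, 1), 1))
  expect_equal(w0[["chisq"]], 0)
  expect_equal(w0[["p"]], 1)
})

test_that("Wald type-I error is near nominal under a true null", {
  set.seed(74)
  n_rep <- 500
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    id <- rep(1:60, each = 2)
    g <- factor(rep(rep(c("A", "B"), each = 2), 30))
    u <- rep(rnorm(60, 0, 0.5), each = 2)
    d <- data.frame(y = u + rnorm(120), g = g, id = id)
    fit <- dg_gee(y ~ g, d, id = "id")
    rej[r] <- fit$wald_table$p[1] < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})

test_that("aliased columns are dropped and missing rows handled per cluster", {
  d <- sim_exchangeable(30)
  d$x2 <- 2 * d$x            # aliased
  d$y[5] <- NA               # unbalanced cluster
  fit <- dg_gee(y ~ x + x2, d, id = "id")
  expect_equal(fit$aliased, "x2")
  expect_true(fit$converged)
  expect_equal(length(coef(fit)), 2L)
})

test_that("LSD post-hoc enumerates cell pairs and detects equality", {
  set.seed(75)
  d <- expand.grid(treatment = c("E", "C"), region = c("dorsal", "ventral"),
                   rep = 1:10, stringsAsFactors = FALSE)
  d$id <- paste0(d$treatment, seq_len(nrow(d)) %% 20)
  d$y <- rnorm(nrow(d)) + ifelse(d$treatment == "E" & d$region == "dorsal", 3, 0)
  fit <- dg_gee(y ~ treatment * region, d, id = "id")
  ph <- lsd_posthoc(fit, c("treatment", "region"))
  expect_equal(nrow(ph$cell_means), 4L)
  expect_equal(nrow(ph$pairwise), 6L)   # choose(4, 2)
  # identical cell means -> p = 1
  fit_eq <- fit
  fit_eq$coefficients[] <- c(1, 0, 0, 0)  # all cells equal
  ph_eq <- lsd_posthoc(fit_eq, c("treatment", "region"))
  expect_true(all(abs(ph_eq$pairwise$diff) < 1e-12))
  expect_true(all(ph_eq$pairwise$p > 1 - 1e-9))
})

test_that("per-region r2 matches exact and null relationships", {
  d <- data.frame(region = rep(c("dorsal", "ventral"), each = 50),
                  dist = rep(seq_len(50), 2))
  set.seed(76)
  d$y <- ifelse(d$region == "ventral", 2 + 0.3 * d$dist, rnorm(100))
  r2 <- covariate_r2(d, "y", "dist")
  expect_equal(r2[["ventral"]], 1, tolerance = 1e-12)
  expect_lt(r2[["dorsal"]], 0.15)
  # fewer than 3 animals -> omitted
  d3 <- d[c(1, 2, 51:100), ]
  expect_true(is.na(covariate_r2(d3, "y", "dist")[["dorsal"]]))
})
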