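#' LSD pairwise comparisons of factorial cell means
#'
#' Recovers the cell means of a factorial structure from a fitted GEE and
#' tests every pairwise difference with an unadjusted Wald z test on the
#' robust covariance — least-significant-difference style, i.e. no
#' multiplicity adjustment beyond the omnibus interaction gate. Numeric
#' covariates are held at their observed mean; factors not in \code{factors}
#' at their reference level.
#'
#' @param fit a [dg_gee()] fit.
#' @param factors character vector of factor names whose crossing defines
#'   the cells (e.g. \code{c("treatment", "region")}).
#' @return list with \code{cell_means} (one row per cell: estimate, robust
#'   SE) and \code{pairwise} (one row per cell pair: difference, SE, z, p).
#' @export
lsd_posthoc <- function(fit, factors = c("treatment", "region")) {
  stopifnot(inherits(fit, "dg_gee"))
  mf <- fit$model
  vars <- attr(stats::delete.response(fit$terms), "term.labels")
  all_vars <- all.vars(stats::delete.response(fit$terms))
  levs <- lapply(factors, function(f) {
    if (!is.null(fit$xlevels[[f]])) fit$xlevels[[f]]
    else sort(unique(mf[[f]]))
  })
  names(levs) <- factors
  grid <- expand.grid(levs, stringsAsFactors = FALSE)
  newdata <- grid
  for (v in setdiff(all_vars, factors)) {
    col <- mf[[v]]
    newdata[[v]] <- if (is.numeric(col)) mean(col)
    else if (!is.null(fit$xlevels[[v]])) fit$xlevels[[v]][1]
    else sort(unique(col))[1]
  }
  X <- stats::model.matrix(stats::delete.response(fit$terms), newdata,
                           xlev = fit$xlevels)
  X <- X[, names(fit$coefficients), drop = FALSE]
  est <- as.numeric(X %*% fit$coefficients)
  se <- sqrt(rowSums((X %*% fit$robust_cov) * X))
  cell_means <- cbind(grid, estimate = est, robust_se = se)
  labels <- do.call(paste, c(grid, sep = ":"))
  pairs <- utils::combn(nrow(grid), 2)
  pw <- apply(pairs, 2, function(ij) {
    l <- X[ij[1], ] - X[ij[2], ]
    d <- sum(l * fit$coefficients)
    s <- sqrt(as.numeric(t(l) %*% fit$robust_cov %*% l))
    z <- if (s > 0) d / s else 0
    c(diff = d, se = s, z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- data.frame(cell_a = labels[pairs[1, ]],
                         cell_b = labels[pairs[2, ]],
                         t(pw), stringsAsFactors = FALSE)
  list(cell_means = cell_means, pairwise = pairwise)
}

#' Per-region squared correlation with a covariate
#'
#' Squared Pearson correlation between a response and a covariate (running
#' distance), computed separately within each region; the companion GEE
#' distance-by-region interaction test is reported by the pipeline. Regions
#' with fewer than 3 complete pairs are omitted (NA).
#'
#' @param data data.frame.
#' @param response name of the response column.
#' @param covariate name of the covariate column.
#' @param region_col name of the region column.
#' @return named numeric vector of r-squared per region.
#' @export
covariate_r2 <- function(data, response, covariate, region_col = "region") {
  regions <- unique(data[[region_col]])
  out <- vapply(regions, function(rg) {
    sub <- data[data[[region_col]] == rg, ]
    ok <- stats::complete.cases(sub[[response]], sub[[covariate]])
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(sub[[response]][ok], sub[[covariate]][ok])^2
  }, numeric(1))
  stats::setNames(out, regions)
}
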