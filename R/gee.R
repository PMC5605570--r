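#' Gaussian generalized estimating equations with robust covariance
#'
#' Fits a marginal linear model to clustered (repeated-measures) data by
#' generalized estimating equations with an identity link: measurements from
#' the two (or more) regions of the same animal form a cluster, and a
#' working correlation — exchangeable by default, or independence — captures
#' their within-animal association. Coefficients solve the weighted
#' estimating equations iteratively; the exchangeable correlation parameter
#' alpha and the dispersion are re-estimated from Pearson residuals at each
#' step until the coefficient change falls below \code{tol}. Inference uses
#' the robust (sandwich) covariance, which is consistent even when the
#' working correlation is wrong. Under the independence structure the
#' coefficients coincide with ordinary least squares on the stacked data;
#' clusters of size one contribute no correlation information and alpha is 0
#' by convention.
#'
#' @param formula model formula for the marginal mean.
#' @param data data.frame with one row per observation.
#' @param id cluster identifier: a column name (character) or a vector.
#' @param corstr working correlation structure.
#' @param tol convergence tolerance on \code{max(abs(delta beta))}.
#' @param maxit maximum iterations.
#' @return an object of class \code{dg_gee} with components
#'   \code{coefficients}, \code{robust_cov}, \code{naive_cov}, \code{alpha},
#'   \code{dispersion}, \code{wald_table} (per-term Wald chi-square tests on
#'   the robust covariance), \code{n_clusters}, \code{converged},
#'   \code{fitted.values}, \code{residuals}.
#' @examples
#' d <- data.frame(y = rnorm(20), x = rnorm(20), id = rep(1:10, each = 2))
#' fit <- dg_gee(y ~ x, d, id = "id")
#' coef(fit)
#' @export
dg_gee <- function(formula, data, id,
                   corstr = c("exchangeable", "independence"),
                   tol = 1e-8, maxit = 100) {
  corstr <- match.arg(corstr)
  cl <- match.call()
  if (is.character(id) && length(id) == 1L) id <- data[[id]]
  if (length(id) != nrow(data)) stop("id must have one entry per row of data")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  keep <- stats::complete.cases(cbind(y, X)) & !is.na(id)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; id <- id[keep]
  # drop aliased columns so the design is full rank
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    if (qrX$rank == 0L) stop("aliasing error: design has rank 0")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  } else aliased <- character(0)
  n <- length(y); p <- ncol(X)
  clusters <- split(seq_len(n), factor(id, levels = unique(id)))
  n_clusters <- length(clusters)
  if (n_clusters < 2L) stop("need at least 2 clusters")

  beta <- qr.coef(qr(X), y)                       # OLS start
  alpha <- 0
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    e <- as.numeric(y - X %*% beta)
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in clusters) {
        ni <- length(ix)
        if (ni > 1L) {
          s <- sum(e[ix])
          num <- num + (s^2 - sum(e[ix]^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (npairs > p) num / phi / (npairs - p) else 0
      max_n <- max(lengths(clusters))
      alpha <- min(max(alpha, -1 / (max_n - 1) + 1e-6), 1 - 1e-6)
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in clusters) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      Rinv <- if (ni == 1L || alpha == 0) diag(1, ni)
      else solve((1 - alpha) * diag(ni) + alpha)
      A <- A + crossprod(Xi, Rinv %*% Xi)
      b <- b + crossprod(Xi, Rinv %*% y[ix])
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (corstr == "independence" && iter >= 1L) { converged <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) { warning("GEE did not converge"); break }
  }

  e <- as.numeric(y - X %*% beta)
  phi <- sum(e^2) / (n - p)
  A <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in clusters) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    Rinv <- if (ni == 1L || alpha == 0) diag(1, ni)
    else solve((1 - alpha) * diag(ni) + alpha)
    Vinv <- Rinv / phi
    XtVi <- crossprod(Xi, Vinv)
    A <- A + XtVi %*% Xi
    ui <- XtVi %*% e[ix]
    M <- M + tcrossprod(ui)
  }
  Ainv <- solve(A)
  robust <- Ainv %*% M %*% Ainv
  robust <- (robust + t(robust)) / 2
  dimnames(robust) <- dimnames(Ainv) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(as.numeric(beta), colnames(X))

  fit <- structure(list(coefficients = beta, robust_cov = robust,
                        naive_cov = Ainv, alpha = alpha, dispersion = phi,
                        corstr = corstr, n_clusters = n_clusters,
                        cluster_sizes = lengths(clusters),
                        converged = converged, iterations = iter,
                        aliased = aliased, call = cl,
                        terms = attr(mf, "terms"),
                        assign = attr(stats::model.matrix(attr(mf, "terms"), mf),
                                      "assign")[match(colnames(X),
                                                      colnames(stats::model.matrix(attr(mf, "terms"), mf)))],
                        xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                        model = mf[keep, , drop = FALSE],
                        X = X, y = y,
                        fitted.values = as.numeric(X %*% beta),
                        residuals = e),
                   class = "dg_gee")
  fit$wald_table <- wald_terms(fit)
  fit
}

# per-term Wald chi-square table on the robust covariance
wald_terms <- function(fit) {
  labels <- attr(fit$terms, "term.labels")
  rows <- lapply(seq_along(labels), function(t) {
    idx <- which(fit$assign == t)
    if (!length(idx)) return(NULL)
    L <- matrix(0, length(idx), length(fit$coefficients))
    L[cbind(seq_along(idx), idx)] <- 1
    w <- wald_test(fit, L)
    data.frame(effect = labels[t], chisq = w[["chisq"]], df = w[["df"]],
               p = w[["p"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wald chi-square test of a linear contrast
#'
#' Tests \code{L beta = 0} using the robust covariance:
#' \code{chisq = (L beta)' (L V L')^{-1} (L beta)} on \code{rank(L)} degrees
#' of freedom. A rank-deficient \code{L V L'} is inverted by generalized
#' inverse with a warning.
#'
#' @param fit a \code{dg_gee} fit.
#' @param L contrast matrix (rows are contrasts over the coefficients).
#' @return named numeric: \code{chisq}, \code{df}, \code{p}.
#' @export
wald_test <- function(fit, L) {
  stopifnot(inherits(fit, "dg_gee"))
  L <- rbind(L)
  if (ncol(L) != length(fit$coefficients))
    stop("contrast error: L must have one column per coefficient")
  if (any(apply(L, 1, function(r) all(r == 0))))
    stop("contrast error: zero row in L")
  df <- qr(L)$rank
  Lb <- L %*% fit$coefficients
  V <- L %*% fit$robust_cov %*% t(L)
  Vi <- tryCatch(solve(V), error = function(e) {
    warning("singular contrast covariance: using generalized inverse")
    ginv_sym(V)
  })
  chisq <- as.numeric(t(Lb) %*% Vi %*% Lb)
  c(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

ginv_sym <- function(V, tol = 1e-10) {
  ev <- eigen(V, symmetric = TRUE)
  pos <- ev$values > tol * max(abs(ev$values))
  ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
}

#' @export
print.dg_gee <- function(x, digits = 4, ...) {
  cat("Generalized estimating equations (Gaussian, identity link)\n")
  cat(sprintf("  working correlation: %s (alpha = %.4f), dispersion = %.4g\n",
              x$corstr, x$alpha, x$dispersion))
  cat(sprintf("  %d clusters (sizes %s), %s after %d iteration(s)\n",
              x$n_clusters,
              paste(range(x$cluster_sizes), collapse = "-"),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.dg_gee <- function(object, ...) {
  se <- sqrt(diag(object$robust_cov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, wald_table = object$wald_table,
                 alpha = object$alpha, corstr = object$corstr,
                 dispersion = object$dispersion,
                 n_clusters = object$n_clusters, call = object$call,
                 converged = object$converged),
            class = "summary.dg_gee")
}

#' @export
print.summary.dg_gee <- function(x, digits = 4, ...) {
  cat("GEE fit:", deparse(x$call), "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nWorking correlation: %s, alpha = %.4f; dispersion %.4g; %d clusters\n",
              x$corstr, x$alpha, x$dispersion, x$n_clusters))
  if (!is.null(x$wald_table)) {
    cat("\nWald chi-square tests (robust covariance):\n")
    print(x$wald_table, row.names = FALSE, digits = digits)
  }
  invisible(x)
}

#' @export
coef.dg_gee <- function(object, ...) object$coefficients

#' Robust or model-based covariance of a GEE fit
#' @param object a \code{dg_gee} fit.
#' @param type "robust" (sandwich, default) or "naive" (model-based).
#' @param ... unused.
#' @export
vcov.dg_gee <- function(object, type = c("robust", "naive"), ...) {
  switch(match.arg(type), robust = object$robust_cov,
         naive = object$naive_cov)
}

#' @export
residuals.dg_gee <- function(object, ...) object$residuals

#' @export
fitted.dg_gee <- function(object, ...) object$fitted.values

#' @export
predict.dg_gee <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata,
                           xlev = object$xlevels)
  X <- X[, names(object$coefficients), drop = FALSE]
  as.numeric(X %*% object$coefficients)
}

#' @export
confint.dg_gee <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$robust_cov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
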