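#' Fit a qPCR standard curve
#'
#' Least-squares fit of \code{Cq = a + b * log10(quantity)} over a serial
#' dilution series. Amplification efficiency follows from the slope as
#' \code{10^(-1/b) - 1} (a slope of -3.3219 is 100% efficiency, i.e. perfect
#' doubling each cycle).
#'
#' @param quantity known standard quantities (> 0, at least 3 distinct).
#' @param cq measured quantification cycles.
#' @return an object of class \code{standard_curve}: \code{intercept_a},
#'   \code{slope_b}, \code{efficiency}, \code{r2}.
#' @examples
#' q <- 10^(5:1)
#' fit_standard_curve(q, 35 - 3.45 * log10(q))$efficiency  # 0.9492
#' @export
fit_standard_curve <- function(quantity, cq) {
  if (length(unique(quantity)) < 3L)
    stop("need at least 3 distinct standard quantities")
  if (any(quantity <= 0)) stop("standard quantities must be positive")
  fit <- stats::lm(cq ~ log10(quantity))
  b <- unname(stats::coef(fit)[2])
  if (b >= 0)
    stop("invalid curve: slope must be negative (Cq decreases with quantity)")
  structure(list(intercept_a = unname(stats::coef(fit)[1]), slope_b = b,
                 efficiency = 10^(-1 / b) - 1,
                 r2 = suppressWarnings(summary(fit)$r.squared)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: Cq = %.3f %+.4f log10(q); efficiency %.1f%%, r2 %.4f\n",
              x$intercept_a, x$slope_b, 100 * x$efficiency, x$r2))
  invisible(x)
}

#' Quantity from a Cq value via a standard curve
#'
#' Inverts the fitted curve: \code{quantity = 10^((Cq - a) / b)}.
#'
#' @param cq measured Cq value(s).
#' @param curve a \code{standard_curve}.
#' @return starting quantities (same arbitrary units as the standards).
#' @export
quantify_cq <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept_a) / curve$slope_b)
}

#' Prox1-normalized expression table
#'
#' Divides each sample's Dcx (and, for mRNA, Bdnf) quantity by its Prox1
#' quantity, the granule-cell normalizer, giving per-animal per-region
#' expression ratios. Quantities are in arbitrary units; only ratios are
#' interpreted.
#'
#' @param samples data.frame with columns \code{animal_id}, \code{region},
#'   a gene/protein name column (\code{gene} or \code{protein}) and a
#'   quantity column (\code{quantity} or \code{pg}).
#' @param modality "mRNA" or "protein" (sets which ratio columns appear).
#' @return a data.frame with one row per animal x region:
#'   \code{normalized_dcx} and, for mRNA, \code{normalized_bdnf}.
#' @export
normalize_expression <- function(samples, modality = c("mRNA", "protein")) {
  modality <- match.arg(modality)
  namecol <- if ("gene" %in% names(samples)) "gene" else "protein"
  qtycol <- if ("quantity" %in% names(samples)) "quantity" else "pg"
  getq <- function(q, nm) {
    hit <- grep(paste0("^", nm, "$"), names(q), ignore.case = TRUE)
    if (!length(hit)) NA_real_ else q[[hit[1]]]
  }
  key <- interaction(samples$animal_id, samples$region, drop = TRUE)
  rows <- lapply(split(samples, key), function(s) {
    q <- stats::setNames(s[[qtycol]], s[[namecol]])
    prox1 <- getq(q, "prox1")
    if (is.na(prox1) || prox1 <= 0)
      stop("undefined ratio: Prox1 quantity missing or nonpositive")
    out <- data.frame(animal_id = s$animal_id[1], region = s$region[1],
                      modality = modality,
                      normalized_dcx = getq(q, "dcx") / prox1,
                      stringsAsFactors = FALSE)
    if (modality == "mRNA")
      out$normalized_bdnf <- getq(q, "bdnf") / prox1
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$animal_id, res$region), , drop = FALSE]
}

#' Quantify a Cq table against per-gene standard curves
#'
#' Fits one standard curve per gene from the dilution series and inverts
#' every sample Cq to a quantity.
#'
#' @param expression Cq table (\code{animal_id}, \code{region}, \code{gene},
#'   \code{cq}).
#' @param standards dilution series (\code{gene}, \code{quantity}, \code{cq}).
#' @return the expression table with a \code{quantity} column added; fitted
#'   curves are attached as the \code{curves} attribute.
#' @export
quantify_expression <- function(expression, standards) {
  curves <- lapply(split(standards, standards$gene),
                   function(s) fit_standard_curve(s$quantity, s$cq))
  expression$quantity <- vapply(seq_len(nrow(expression)), function(i)
    quantify_cq(expression$cq[i], curves[[expression$gene[i]]]), numeric(1))
  attr(expression, "curves") <- curves
  expression
}
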