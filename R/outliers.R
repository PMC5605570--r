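#' Interquartile-range outlier flags
#'
#' Flags values outside \code{[Q1 - m*IQR, Q3 + m*IQR]} with quartiles by
#' linear interpolation (R's type-7 convention) and the conservative
#' multiplier m = 2.2 recommended for screening before modelling. With zero
#' IQR (ties) only values differing from the common quartile value are
#' flagged.
#'
#' @param values numeric vector (at least 4 values).
#' @param multiplier fence multiplier (default 2.2).
#' @param quartile_type quantile algorithm type (default 7, linear
#'   interpolation).
#' @return logical vector, TRUE where the value is an outlier.
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))  # only 100 flagged
#' @export
iqr_outliers <- function(values, multiplier = 2.2, quartile_type = 7) {
  if (length(values) < 4L) stop("need at least 4 values")
  if (multiplier <= 0) stop("multiplier must be positive")
  qs <- stats::quantile(values, c(0.25, 0.75), type = quartile_type,
                        names = FALSE, na.rm = TRUE)
  iqr <- qs[2] - qs[1]
  values < qs[1] - multiplier * iqr | values > qs[2] + multiplier * iqr
}

#' Screen a long table for outliers within treatment-by-region cells
#'
#' Applies [iqr_outliers()] to each cell of the crossing of the given
#' grouping columns and returns the table with an \code{outlier} flag and an
#' audit attribute listing flagged rows. Cells with fewer than 4 values are
#' left unflagged.
#'
#' @param data long data.frame.
#' @param value_col name of the response column.
#' @param by character vector of grouping column names.
#' @param multiplier fence multiplier.
#' @return \code{data} with a logical \code{outlier} column; flagged rows in
#'   the \code{audit} attribute.
#' @export
screen_outliers <- function(data, value_col = "value",
                            by = c("treatment", "region"), multiplier = 2.2) {
  flag <- logical(nrow(data))
  key <- interaction(data[by], drop = TRUE)
  for (lev in levels(key)) {
    idx <- which(key == lev)
    if (length(idx) >= 4L)
      flag[idx] <- iqr_outliers(data[[value_col]][idx], multiplier)
  }
  data$outlier <- flag
  attr(data, "audit") <- data[flag, , drop = FALSE]
  data
}
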