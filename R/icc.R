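#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measures absolute-agreement ICC from the two-way random-effects
#' ANOVA decomposition, the reliability model for a set of targets each
#' rated by the same raters (e.g. lesion volumes delineated by two raters):
#'
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`
#'
#' where `MS_R`, `MS_C`, `MS_E` are the row (target), column (rater) and
#' residual mean squares, `n` targets and `k` raters. Absolute agreement
#' penalises systematic rater offsets. The F statistic is `MS_R / MS_E`
#' with `(n-1, (n-1)(k-1))` degrees of freedom. Values above 0.75 are
#' conventionally read as excellent reliability.
#'
#' @param ratings numeric matrix or data.frame, `n` targets x `k` raters,
#'   no missing cells; `n >= 2`, `k >= 2`.
#' @return Object of class `icc_result`: list with `icc`, `f_statistic`,
#'   `df1`, `df2`, `model = "two-way random, absolute agreement, single
#'   measures"`, and the mean squares.
#' @export
#' @examples
#' r <- cbind(rater1 = c(10, 20, 30, 40, 50),
#'            rater2 = c(11, 19, 32, 38, 51))
#' icc_two_way_random(r)
icc_two_way_random <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m)) stop_invalid("`ratings` must be numeric")
  if (anyNA(m)) stop_invalid("`ratings` must have no missing cells")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop_invalid("need at least 2 targets and 2 raters")
  if (stats::var(as.vector(m)) == 0) {
    stop_invalid("constant ratings across all cells: ICC undefined (degenerate variance)")
  }
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  f <- if (mse > 0) msr / mse else Inf
  structure(list(icc = icc, f_statistic = f,
                 df1 = n - 1, df2 = (n - 1) * (k - 1),
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n_targets = n, k_raters = k,
                 model = "two-way random, absolute agreement, single measures"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (%s)\n", x$icc, x$model))
  cat(sprintf("  F(%d, %d) = %.4g\n", x$df1, x$df2, x$f_statistic))
  invisible(x)
}
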