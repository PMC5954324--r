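# Cohort-level statistics: TUG change, normality gate, paired tests,
# correlation screen, and the MWF-ratio regression.

#' Change in Timed Up and Go time
#'
#' Day 10 minus Day 1, in seconds; negative values are improvement. Rows
#' with a missing Day 10 time return `NA` and are excluded pairwise by the
#' downstream tests (never imputed).
#'
#' @param record a data.frame with `tug_day1_s` and `tug_day10_s` columns
#'   (a full cohort table works; the function is vectorised).
#' @return Numeric vector of signed changes in s.
#' @export
tug_change <- function(record) {
  if (!all(c("tug_day1_s", "tug_day10_s") %in% names(record))) {
    stop_invalid("record needs `tug_day1_s` and `tug_day10_s` columns")
  }
  record$tug_day10_s - record$tug_day1_s
}

#' Paired t-test with Cohen's d
#'
#' Standard paired t on the within-subject differences with a two-sided p,
#' plus `d = mean(diff) / sd(diff)`.
#'
#' @param pre,post equal-length numeric vectors; pairs with any `NA` are
#'   dropped.
#' @return Object of class `paired_test`: `n_pairs`, `mean_diff`,
#'   `sd_diff`, `t_statistic`, `df`, `p_value`, `cohens_d`.
#' @export
#' @examples
#' paired_ttest(c(21, 13.5, 13), c(14, 10, 13.5))
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) stop_invalid("`pre` and `post` lengths differ")
  keep <- stats::complete.cases(pre, post)
  d <- (post - pre)[keep]
  n <- length(d)
  if (n < 2) stop_invalid("need at least 2 complete pairs")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    stop_invalid("zero-variance differences: paired t undefined (degenerate variance)")
  }
  tt <- stats::t.test(post[keep], pre[keep], paired = TRUE)
  structure(list(n_pairs = n, mean_diff = mean(d), sd_diff = sdd,
                 t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, cohens_d = mean(d) / sdd),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired t: n = %d, mean diff = %.3f (SD %.3f)\n",
              x$n_pairs, x$mean_diff, x$sd_diff))
  cat(sprintf("  t(%d) = %.3f, p = %.4g, d = %.3f\n",
              x$df, x$t_statistic, x$p_value, x$cohens_d))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] returning the W statistic and
#' p-value. The analysis pipeline treats `p <= 0.05` as a normality
#' violation and would switch to non-parametric branches (Wilcoxon
#' signed-rank, Spearman).
#'
#' @param x numeric vector, 3 to 5000 non-missing values.
#' @return Object of class `normality_result`: `statistic`, `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop_invalid("Shapiro-Wilk requires between 3 and 5000 values")
  }
  if (stats::sd(x) == 0) {
    stop_invalid("constant input: normality test undefined (degenerate variance)")
  }
  sw <- stats::shapiro.test(x)
  structure(list(statistic = unname(sw$statistic), p_value = sw$p.value),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors; incomplete pairs dropped; both must be
#'   non-constant with at least 3 complete pairs.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_invalid("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("constant input: correlation undefined (degenerate variance)")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with R-squared, the overall F on
#' `(1, n-2)` degrees of freedom (equal to the squared slope t), and a
#' two-sided p. The fitted [stats::lm] object is kept for the standard
#' methods (`predict`, `residuals`, `plot`).
#'
#' @param x,y numeric vectors; incomplete pairs dropped; `x` non-constant,
#'   `n >= 3`.
#' @return Object of class `mwf_association`: `r`, `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `df_num`, `df_den`, `p_value`, `n`, `fit`.
#' @export
#' @examples
#' simple_regression(1:10, 2 * (1:10) + rnorm(10))
simple_regression <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_invalid("need at least 3 complete pairs")
  if (stats::sd(x) == 0) {
    stop_invalid("constant predictor: regression undefined (degenerate design)")
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip lm's rank warning
  r <- stats::cor(x, y)
  structure(list(r = r,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 f_statistic = unname(sm$fstatistic[1]),
                 df_num = 1L, df_den = n - 2L,
                 p_value = unname(stats::pf(sm$fstatistic[1], 1, n - 2,
                                            lower.tail = FALSE)),
                 n = n, fit = fit),
            class = "mwf_association")
}

#' @export
print.mwf_association <- function(x, ...) {
  cat(sprintf("Simple regression (n = %d): y = %.4g + %.4g x\n",
              x$n, x$intercept, x$slope))
  cat(sprintf("  r = %.3f, R^2 = %.3f, F(%d,%d) = %.3f, p = %.4g\n",
              x$r, x$r_squared, x$df_num, x$df_den, x$f_statistic,
              x$p_value))
  invisible(x)
}

#' @export
coef.mwf_association <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.mwf_association <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(x = newdata)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.mwf_association <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.mwf_association <- function(x, xlab = "predictor", ylab = "response",
                                 ...) {
  mf <- stats::model.frame(x$fit)
  plot(mf$x, mf$y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$fit, col = "red3")
  invisible(x)
}

#' Cohort summary
#'
#' Column means of age, baseline TUG (all subjects), Day 10 TUG (subjects
#' with a value) and lesion volume; the median EDSS; sex counts; and the
#' responder count (subjects whose TUG time decreased).
#'
#' @param table cohort data.frame (see [read_cohort()] for the schema).
#' @return Object of class `cohort_summary`.
#' @export
summarize_cohort <- function(table) {
  if (nrow(table) == 0L) stop_invalid("empty cohort table")
  ch <- tug_change(table)
  structure(list(
    n = nrow(table),
    mean_age = mean(table$age),
    median_edss = stats::median(table$edss),
    mean_tug_day1 = mean(table$tug_day1_s),
    mean_tug_day10 = mean(table$tug_day10_s, na.rm = TRUE),
    mean_lesion_volume = mean(table$lesion_volume_mm3),
    sex_counts = if ("sex" %in% names(table)) table(table$sex) else NULL,
    n_complete_pairs = sum(!is.na(ch)),
    n_responders = sum(ch < 0, na.rm = TRUE)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d participants\n", x$n))
  cat(sprintf("  mean age %.1f y, median EDSS %.1f\n",
              x$mean_age, x$median_edss))
  cat(sprintf("  TUG day 1 %.1f s, day 10 %.1f s (%d complete pairs)\n",
              x$mean_tug_day1, x$mean_tug_day10, x$n_complete_pairs))
  cat(sprintf("  mean lesion volume %.1f mm^3\n", x$mean_lesion_volume))
  cat(sprintf("  responders (TUG decreased): %d\n", x$n_responders))
  invisible(x)
}

#' Exploratory association screen
#'
#' Pearson-correlates each candidate neurobiological predictor
#' (`lesion_volume_mm3`, `lesion_mwf`, `nawm_mwf`, `mwf_ratio`) with the
#' TUG change, pairwise complete cases per predictor. All screen results
#' are reported; the predictor with the smallest p advances to
#' [simple_regression()]. Predictors with missing columns or fewer than 3
#' complete cases are reported as skipped.
#'
#' @param table cohort data.frame.
#' @return Object of class `association_screen`: `screen` (data.frame of
#'   predictor, n, r, p or skip reason), `selected`, `regression` (an
#'   `mwf_association`).
#' @export
run_association_screen <- function(table) {
  ch <- tug_change(table)
  predictors <- c("lesion_volume_mm3", "lesion_mwf", "nawm_mwf", "mwf_ratio")
  rows <- lapply(predictors, function(p) {
    if (!p %in% names(table) || all(is.na(table[[p]]))) {
      return(data.frame(predictor = p, n = 0L, r = NA_real_,
                        p_value = NA_real_, status = "skipped: missing",
                        stringsAsFactors = FALSE))
    }
    keep <- stats::complete.cases(table[[p]], ch)
    if (sum(keep) < 3) {
      return(data.frame(predictor = p, n = sum(keep), r = NA_real_,
                        p_value = NA_real_,
                        status = "skipped: < 3 complete cases",
                        stringsAsFactors = FALSE))
    }
    pc <- pearson_cor(table[[p]], ch)
    data.frame(predictor = p, n = pc$n, r = pc$r, p_value = pc$p_value,
               status = "ok", stringsAsFactors = FALSE)
  })
  screen <- do.call(rbind, rows)
  ok <- screen$status == "ok"
  if (!any(ok)) {
    stop_invalid("no predictor with at least 3 complete cases (insufficient data)")
  }
  sel <- screen$predictor[ok][which.min(screen$p_value[ok])]
  reg <- simple_regression(table[[sel]], ch)
  structure(list(screen = screen, selected = sel, regression = reg),
            class = "association_screen")
}

#' @export
print.association_screen <- function(x, ...) {
  cat("Association screen (predictor vs TUG change):\n")
  print(x$screen, row.names = FALSE, digits = 3)
  cat(sprintf("Selected predictor: %s\n", x$selected))
  print(x$regression)
  invisible(x)
}

#' Full cohort analysis
#'
#' Runs the complete statistical stage on a cohort table: summary,
#' Shapiro-Wilk normality on each dependent measure, the paired t on TUG
#' Day 1 vs Day 10, and the association screen with follow-up regression.
#'
#' @param table cohort data.frame.
#' @return Object of class `cohort_analysis`: `summary`, `normality`
#'   (named list of [shapiro_wilk()] results), `tug_test`
#'   (a `paired_test`), `screen` (an `association_screen`, or `NULL` when
#'   no predictor is available).
#' @export
cohort_analysis <- function(table) {
  ch <- tug_change(table)
  measures <- list(tug_change = ch,
                   lesion_volume = table$lesion_volume_mm3)
  for (m in c("lesion_mwf", "nawm_mwf", "mwf_ratio")) {
    if (m %in% names(table) && !all(is.na(table[[m]]))) {
      measures[[m]] <- table[[m]]
    }
  }
  normality <- lapply(measures, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 3 && stats::sd(v) > 0) shapiro_wilk(v) else NULL
  })
  tug_test <- paired_ttest(table$tug_day1_s, table$tug_day10_s)
  screen <- tryCatch(run_association_screen(table), error = function(e) NULL)
  structure(list(summary = summarize_cohort(table), normality = normality,
                 tug_test = tug_test, screen = screen),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  print(x$summary)
  cat("\nNormality (Shapiro-Wilk):\n")
  for (nm in names(x$normality)) {
    r <- x$normality[[nm]]
    if (!is.null(r)) {
      cat(sprintf("  %-14s W = %.3f, p = %.3f\n", nm, r$statistic, r$p_value))
    }
  }
  cat("\nTUG day 1 vs day 10:\n")
  print(x$tug_test)
  if (!is.null(x$screen)) {
    cat("\n")
    print(x$screen)
  }
  invisible(x)
}
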