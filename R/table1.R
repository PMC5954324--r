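#' Load the packaged reference cohort
#'
#' A published 16-participant relapsing-remitting MS cohort (age, sex,
#' EDSS, TUG Day 1 / Day 10, lesion volume) shipped as a plain-CSV fixture.
#' One participant did not complete the Day 10 TUG; that cell is `NA` and
#' is excluded pairwise by the paired analyses.
#'
#' @return Cohort data.frame.
#' @export
#' @examples
#' summarize_cohort(load_table1())
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "mwfr")
  if (path == "") stop_invalid("packaged fixture table1.csv not found")
  read_cohort(path)
}

# published summary values for the reference cohort, at printed precision
table1_reference <- function() {
  list(mean_age = 47.1, mean_tug_day1 = 12.8, mean_tug_day10 = 11.9,
       mean_lesion_volume = 7276.9, median_edss = 4.0,
       mean_tug_reduction = 1.1, sd_tug_change = 3.05,
       t_statistic = 1.4, cohens_d = 0.36, n_responders = 9)
}

#' Reproduce the reference cohort summaries
#'
#' Recomputes every published summary statistic of the packaged cohort
#' (means, median EDSS, TUG reduction, paired t, Cohen's d, responder
#' count) and compares each against its printed value under half-up
#' rounding at the printed precision.
#'
#' @param table cohort table; defaults to the packaged fixture.
#' @return data.frame with columns `quantity`, `computed`, `reference`,
#'   `rounded`, `match`; printed as a pass/fail table.
#' @export
#' @examples
#' reproduce_table1()
reproduce_table1 <- function(table = load_table1()) {
  s <- summarize_cohort(table)
  tt <- paired_ttest(table$tug_day1_s, table$tug_day10_s)
  ref <- table1_reference()
  comp <- list(mean_age = s$mean_age,
               mean_tug_day1 = s$mean_tug_day1,
               mean_tug_day10 = s$mean_tug_day10,
               mean_lesion_volume = s$mean_lesion_volume,
               median_edss = s$median_edss,
               mean_tug_reduction = -tt$mean_diff,
               sd_tug_change = tt$sd_diff,
               t_statistic = abs(tt$t_statistic),
               cohens_d = abs(tt$cohens_d),
               n_responders = s$n_responders)
  digits <- vapply(ref, function(v) {
    d <- nchar(sub("^[^.]*\\.?", "", format(v, trim = TRUE)))
    d
  }, integer(1))
  rounded <- mapply(function(v, d) round_half_up(v, d), comp, digits)
  out <- data.frame(quantity = names(ref),
                    computed = unlist(comp),
                    reference = unlist(ref),
                    rounded = rounded,
                    match = rounded == unlist(ref),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("table1_check", "data.frame")
  out
}

#' @export
print.table1_check <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 6)
  df$status <- ifelse(df$match, "pass", "FAIL")
  print(df[, c("quantity", "computed", "rounded", "reference", "status")],
        row.names = FALSE)
  cat(sprintf("%d/%d reproduced at printed precision\n",
              sum(x$match), nrow(x)))
  invisible(x)
}
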