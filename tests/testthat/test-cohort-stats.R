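# Cohort statistics on the packaged reference cohort and synthetic tables.

test_that("tug_change is the signed Day 10 minus Day 1 difference", {
  tab <- load_table1()
  ch <- tug_change(tab)
  expect_equal(ch[tab$subject_id == "01"], -7.0)
  expect_equal(ch[tab$subject_id == "09"], 0.0)
  expect_equal(ch[tab$subject_id == "10"], 7.0)
  expect_true(is.na(ch[tab$subject_id == "16"]))  # Day 10 not completed
})

test_that("paired t-test reproduces hand results and the cohort TUG test", {
  # hand closed form: differences {1, 2, 3}
  r <- paired_ttest(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$mean_diff, 2)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)

  # symmetric differences: t = 0, p = 1
  r0 <- paired_ttest(c(0, 0), c(1, -1))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)

  # reference cohort: 15 complete pairs, mean reduction 1.1 s
  tab <- load_table1()
  tt <- paired_ttest(tab$tug_day1_s, tab$tug_day10_s)
  expect_equal(tt$n_pairs, 15)
  expect_equal(tt$df, 14)
  expect_equal(tt$mean_diff, -1.1, tolerance = 1e-9)
  expect_equal(round_half_up(tt$sd_diff, 2), 3.05)
  expect_equal(round_half_up(abs(tt$t_statistic), 1), 1.4)
  expect_equal(round_half_up(abs(tt$cohens_d), 2), 0.36)

  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "degenerate")
})

test_that("degenerate paired input reports the exact constant difference", {
  x <- c(4, 9, 2.5)
  expect_error(paired_ttest(x, x + 3), "degenerate")
  # non-degenerate shifted case keeps the constant as the mean difference
  r <- paired_ttest(c(1, 2, 3), c(4, 5, 6.5))
  expect_equal(r$mean_diff, mean(c(3, 3, 3.5)))
})

test_that("Shapiro-Wilk gate behaves on reference and constructed data", {
  tab <- load_table1()
  sw <- shapiro_wilk(tab$lesion_volume_mm3)
  expect_gt(sw$p_value, 0.05)        # normality not rejected
  expect_equal(round_half_up(sw$statistic, 2), 0.98)

  # symmetric 5-point set
  expect_gt(shapiro_wilk(1:5 * 1.0)$statistic, 0.9)

  # power: strongly skewed draws are flagged in nearly every seed
  hits <- sapply(1:100, function(s) {
    set.seed(s)
    shapiro_wilk(runif(200)^4)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
  expect_error(shapiro_wilk(rep(2, 10)), "degenerate")
  expect_error(shapiro_wilk(c(1, 2)), "between 3 and 5000")
})

test_that("pearson_cor matches hand computations", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1.0, tolerance = 1e-12)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1.0, tolerance = 1e-12)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6,
               tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), 1:5), "degenerate")
})

test_that("simple regression satisfies the exact R^2 and F identities", {
  # perfect line
  reg <- simple_regression(1:8, 3 * (1:8) - 2)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  expect_equal(sum(residuals(reg)^2), 0, tolerance = 1e-18)

  # fuzzed identities: R^2 = r^2 and F = (n-2) R^2 / (1 - R^2)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n, 0.5 * x)
    reg <- simple_regression(x, y)
    pc <- pearson_cor(x, y)
    expect_equal(reg$r_squared, pc$r^2, tolerance = 1e-12)
    expect_equal(reg$f_statistic,
                 (n - 2) * reg$r_squared / (1 - reg$r_squared),
                 tolerance = 1e-9)
    expect_equal(reg$p_value, pc$p_value, tolerance = 1e-12)
  }
  expect_error(simple_regression(rep(1, 6), rnorm(6)), "degenerate")
})

test_that("null regression R^2 matches its known expectation 1/(n-1)", {
  set.seed(14)
  r2 <- replicate(1000, {
    x <- rnorm(14)
    y <- rnorm(14)
    simple_regression(x, y)$r_squared
  })
  expect_equal(mean(r2), 1 / 13, tolerance = 0.02)
})

test_that("cohort summary reproduces the reference cohort averages", {
  tab <- load_table1()
  s <- summarize_cohort(tab)
  expect_equal(round_half_up(s$mean_age, 1), 47.1)
  expect_equal(round_half_up(s$mean_lesion_volume, 1), 7276.9)
  expect_equal(round_half_up(s$mean_tug_day1, 1), 12.8)
  expect_equal(round_half_up(s$mean_tug_day10, 1), 11.9)
  expect_equal(s$median_edss, 4.0)
  expect_equal(s$n_responders, 9)
  expect_equal(unname(s$sex_counts["F"]), 15)

  # single-subject table: summary equals that subject
  s1 <- summarize_cohort(tab[3, ])
  expect_equal(s1$mean_age, 34)
  expect_equal(s1$median_edss, 4.5)
  expect_equal(s1$n_responders, 0)
})

test_that("statistics are invariant to cohort row order", {
  tab <- load_table1()
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(summarize_cohort(perm)$mean_age,
               summarize_cohort(tab)$mean_age)
  expect_equal(paired_ttest(perm$tug_day1_s, perm$tug_day10_s)$t_statistic,
               paired_ttest(tab$tug_day1_s, tab$tug_day10_s)$t_statistic,
               tolerance = 1e-12)
  sc1 <- run_association_screen(tab)
  sc2 <- run_association_screen(perm)
  expect_equal(sc1$screen$r, sc2$screen$r, tolerance = 1e-12)
})

test_that("association screen selects the planted predictor and degrades
           gracefully", {
  # planted mwf_ratio effect: selected in >= 95% of seeds at n = 80
  sel <- sapply(1:60, function(s) {
    tab <- simulate_cohort(cohort_params(n_subjects = 80), seed = s)
    run_association_screen(tab)$selected
  })
  expect_gte(mean(sel == "mwf_ratio"), 0.95)

  # all screen rows are reported, not only the winner
  sc <- run_association_screen(simulate_cohort(cohort_params(), seed = 2))
  expect_equal(nrow(sc$screen), 4)
  expect_true(all(sc$screen$status == "ok"))

  # missing MWF columns: screen runs on lesion volume only, rest skipped
  tab1 <- load_table1()
  sc1 <- run_association_screen(tab1)
  expect_equal(sc1$selected, "lesion_volume_mm3")
  expect_equal(sum(sc1$screen$status == "ok"), 1)
  expect_equal(sum(grepl("skipped", sc1$screen$status)), 3)

  # fewer than 3 complete cases anywhere: hard error
  tiny <- tab1[1:2, ]
  expect_error(run_association_screen(tiny), "insufficient|3 complete")
})

test_that("screen selection is symmetric across independent null predictors", {
  sel <- sapply(1:400, function(s) {
    set.seed(s)
    tab <- data.frame(tug_day1_s = rnorm(14, 12, 3),
                      tug_day10_s = rnorm(14, 12, 3),
                      lesion_volume_mm3 = rnorm(14),
                      lesion_mwf = rnorm(14),
                      nawm_mwf = rnorm(14),
                      mwf_ratio = rnorm(14))
    run_association_screen(tab)$selected
  })
  counts <- table(factor(sel, levels = c("lesion_volume_mm3", "lesion_mwf",
                                         "nawm_mwf", "mwf_ratio")))
  # each predictor should win about 100 of 400; allow ~4 binomial SDs
  expect_true(all(counts > 100 - 4 * sqrt(400 * 0.25 * 0.75)))
  expect_true(all(counts < 100 + 4 * sqrt(400 * 0.25 * 0.75)))
})

test_that("full reference-cohort reproduction passes at printed precision", {
  chk <- reproduce_table1()
  expect_true(all(chk$match))
  ca <- cohort_analysis(load_table1())
  expect_equal(ca$summary$n_complete_pairs, 15)
  expect_gt(ca$normality$lesion_volume$p_value, 0.05)
  expect_gt(ca$normality$tug_change$p_value, 0.05)
})
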