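#' Cohort simulation parameters
#'
#' Generator settings for a synthetic relapsing-remitting MS cohort in
#' which the lesion/NAWM MWF ratio linearly predicts the change in Timed Up
#' and Go (TUG) time over a walking intervention:
#' `delta_TUG = beta0 + beta1 * ratio + eps`, `eps ~ N(0, noise_sd)`.
#' Negative `delta_TUG` means improvement, so a negative `beta1` encodes
#' "less myelin disruption (ratio nearer 1) predicts greater improvement".
#'
#' Defaults mirror the observed cohort: NAWM MWF 0.0999 (SD 0.012), MWF
#' ratio 0.80 (SD 0.10), TUG day 1 12.8 s (SD 3.8), slope -15 s per unit
#' ratio with `noise_sd` set so the population R-squared of the
#' ratio-to-delta-TUG regression is 0.31 (see
#' [calibrate_noise_sd()]).
#'
#' @param n_subjects number of participants, >= 3.
#' @param nawm_mwf_mean,nawm_mwf_sd NAWM MWF distribution (unitless).
#' @param mwf_ratio_mean,mwf_ratio_sd lesion/NAWM MWF ratio distribution;
#'   draws are clipped to (0, 1.5].
#' @param slope_beta1 s per unit ratio.
#' @param intercept_beta0 s.
#' @param noise_sd residual SD of delta-TUG in s.
#' @param tug_day1_mean,tug_day1_sd baseline TUG distribution in s.
#' @param lesion_vol_meanlog,lesion_vol_sdlog log-normal lesion volume
#'   parameters (mm^3).
#' @param age_mean,age_sd years.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 14,
                          nawm_mwf_mean = 0.0999, nawm_mwf_sd = 0.012,
                          mwf_ratio_mean = 0.80, mwf_ratio_sd = 0.10,
                          slope_beta1 = -15,
                          intercept_beta0 = -1.1 - slope_beta1 * mwf_ratio_mean,
                          noise_sd = calibrate_noise_sd(slope_beta1,
                                                        mwf_ratio_sd, 0.31),
                          tug_day1_mean = 12.8, tug_day1_sd = 3.8,
                          lesion_vol_meanlog = log(7277) - 0.5 * 0.55^2,
                          lesion_vol_sdlog = 0.55,
                          age_mean = 47.1, age_sd = 12) {
  if (n_subjects < 3) stop_invalid("`n_subjects` must be at least 3")
  sds <- c(nawm_mwf_sd, mwf_ratio_sd, noise_sd, tug_day1_sd, age_sd)
  if (any(sds < 0)) stop_invalid("standard deviations must be >= 0")
  structure(as.list(environment()), class = "cohort_params")
}

#' Residual SD implied by a target population R-squared
#'
#' For the simple regression `y = beta0 + beta1 x + eps`, the population
#' R-squared is `beta1^2 var(x) / (beta1^2 var(x) + noise_sd^2)`; inverting
#' gives the residual SD that plants a chosen effect size.
#'
#' @param beta1 regression slope.
#' @param x_sd SD of the predictor.
#' @param r_squared target population R-squared in (0, 1).
#' @return Residual standard deviation.
#' @export
#' @examples
#' calibrate_noise_sd(-15, 0.10, 0.31)
calibrate_noise_sd <- function(beta1, x_sd, r_squared) {
  if (r_squared <= 0 || r_squared >= 1) {
    stop_invalid("`r_squared` must be in (0, 1)")
  }
  sqrt(beta1^2 * x_sd^2 * (1 - r_squared) / r_squared)
}

#' Simulate a cohort table
#'
#' Draws per-subject NAWM MWF and MWF ratio from normal distributions
#' (ratio clipped to (0, 1.5]), sets `lesion_mwf = ratio * nawm_mwf`,
#' draws baseline TUG, and plants
#' `delta_TUG = beta0 + beta1 * ratio + eps`. Day-10 TUG is the baseline
#' plus the planted change, floored at 1 s (times below a second are not
#' physically meaningful for this test).
#'
#' @param params a [cohort_params()].
#' @param seed integer RNG seed (default 0).
#' @return `data.frame` with columns `subject_id, age, sex, edss,
#'   tug_day1_s, tug_day10_s, lesion_volume_mm3, lesion_mwf, nawm_mwf,
#'   mwf_ratio`.
#' @export
#' @examples
#' head(simulate_cohort(cohort_params(), seed = 1))
simulate_cohort <- function(params = cohort_params(), seed = 0) {
  if (!inherits(params, "cohort_params")) {
    stop_invalid("`params` must be a cohort_params object")
  }
  n <- params$n_subjects
  with_seed(seed, {
    nawm <- stats::rnorm(n, params$nawm_mwf_mean, params$nawm_mwf_sd)
    nawm <- pmin(pmax(nawm, 1e-4), 1)
    ratio <- stats::rnorm(n, params$mwf_ratio_mean, params$mwf_ratio_sd)
    ratio <- pmin(pmax(ratio, 1e-6), 1.5)
    lesion <- ratio * nawm
    day1 <- pmax(stats::rnorm(n, params$tug_day1_mean, params$tug_day1_sd), 2)
    dtug <- params$intercept_beta0 + params$slope_beta1 * ratio +
      stats::rnorm(n, 0, params$noise_sd)
    day10 <- pmax(day1 + dtug, 1)
    vol <- stats::rlnorm(n, params$lesion_vol_meanlog, params$lesion_vol_sdlog)
    age <- round(pmin(pmax(stats::rnorm(n, params$age_mean, params$age_sd),
                           18), 90))
    sex <- ifelse(stats::runif(n) < 15 / 16, "F", "M")
    edss <- pmin(pmax(round(stats::rnorm(n, 4, 1.8) * 2) / 2, 0), 10)
    data.frame(
      subject_id = sprintf("%02d", seq_len(n)),
      age = age, sex = sex, edss = edss,
      tug_day1_s = day1, tug_day10_s = day10,
      lesion_volume_mm3 = vol,
      lesion_mwf = lesion, nawm_mwf = nawm, mwf_ratio = ratio,
      stringsAsFactors = FALSE
    )
  })
}
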