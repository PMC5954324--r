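# Umbrella pipeline: (optional) simulation -> voxelwise MWF fitting ->
# ROI statistics -> cohort statistics, with a run manifest sufficient to
# re-run the deterministic stages bit-identically.

#' Read a pipeline configuration
#'
#' YAML with optional blocks `protocol`, `fit`, `phantom`, `input`,
#' `cohort`, plus `seed` and `out_dir`. Exactly one of `phantom`
#' (simulate) or `input` (paths to an acquired volume and masks) must be
#' present. File paths referenced by `input` and `cohort$table` are
#' validated before any computation.
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a configuration list (as from [yaml::read_yaml()]).
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) cfg$seed <- 0
  if (cfg$seed != trunc(cfg$seed)) stop_invalid("`seed` must be an integer")
  if (is.null(cfg$out_dir)) stop_invalid("config needs `out_dir`")
  has_phantom <- !is.null(cfg$phantom)
  has_input <- !is.null(cfg$input)
  if (has_phantom == has_input) {
    stop_invalid("config needs exactly one of `phantom` or `input`")
  }
  if (has_input) {
    for (key in c("volume", "nawm_mask", "lesion_mask")) {
      p <- cfg$input[[key]]
      if (is.null(p)) stop_invalid("config `input` lacks `", key, "`")
      if (!file.exists(p)) stop_invalid("input file missing: ", p)
    }
  }
  if (!is.null(cfg$cohort$table) && !file.exists(cfg$cohort$table)) {
    stop_invalid("cohort table missing: ", cfg$cohort$table)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

protocol_from_config <- function(cfg) {
  if (is.null(cfg$protocol)) return(acquisition_protocol())
  acquisition_protocol(
    echo_times = if (!is.null(cfg$protocol$echo_times))
      as.numeric(cfg$protocol$echo_times) else seq(10, 320, 10),
    repetition_time = if (!is.null(cfg$protocol$repetition_time))
      cfg$protocol$repetition_time else 1000)
}

fit_config_from_config <- function(cfg) {
  f <- cfg$fit
  if (is.null(f)) return(fit_config())
  grid <- t2_grid(n = if (!is.null(f$grid_n)) f$grid_n else 40,
                  range = if (!is.null(f$grid_range))
                    as.numeric(f$grid_range) else c(15, 2000))
  fit_config(grid = grid,
             regularization = if (!is.null(f$regularization))
               f$regularization else "none",
             chi2_factor = if (!is.null(f$chi2_factor)) f$chi2_factor else 1.02)
}

phantom_spec_from_config <- function(cfg) {
  p <- cfg$phantom
  args <- list()
  if (!is.null(p$grid_shape)) args$grid_shape <- as.integer(unlist(p$grid_shape))
  if (!is.null(p$voxel_dims)) args$voxel_dims <- as.numeric(unlist(p$voxel_dims))
  if (!is.null(p$noise_sigma)) args$noise_sigma <- p$noise_sigma
  if (!is.null(p$noise_model)) args$noise_model <- p$noise_model
  if (!is.null(p$nawm)) {
    args$nawm_poolset <- pool_set(as.numeric(unlist(p$nawm$fractions)),
                                  as.numeric(unlist(p$nawm$t2)))
  }
  if (!is.null(p$lesions)) {
    args$lesion_poolsets <- lapply(p$lesions, function(l)
      pool_set(as.numeric(unlist(l$fractions)), as.numeric(unlist(l$t2))))
    args$lesion_geometry <- lapply(p$lesions, function(l)
      list(center = as.numeric(unlist(l$center)), radius = l$radius))
  }
  do.call(phantom_spec, args)
}

cohort_params_from_config <- function(cfg) {
  p <- cfg$cohort$params
  if (is.null(p)) return(cohort_params())
  known <- intersect(names(p), names(formals(cohort_params)))
  do.call(cohort_params, p[known])
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when configured) -> voxelwise MWF fitting -> ROI
#' statistics -> cohort statistics, writing each stage's outputs before
#' the next stage reads them, and emits a run manifest (config snapshot,
#' package version, file checksums, stage log, timestamps). For a fixed
#' config and seed every output except the manifest timestamps is
#' bit-identical across runs. Any stage error aborts with the failed stage
#' recorded in `manifest.json`.
#'
#' @param config a `pipeline_config`, or a path to a YAML config.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(unclass(config))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("mwfr")),
                   stages = list(), inputs = list(), outputs = list(),
                   timestamps = list(started = format(Sys.time())))
  stage <- "init"
  result <- tryCatch({
    protocol <- protocol_from_config(config)
    fitcfg <- fit_config_from_config(config)

    if (!is.null(config$phantom)) {
      stage <- "simulate-phantom"
      t0 <- Sys.time()
      ph <- make_phantom(phantom_spec_from_config(config), protocol,
                         seed = config$seed)
      vol_path <- file.path(out_dir, "echo_volume.nii.gz")
      write_echo_volume(ph$volume, protocol, vol_path,
                        voxel_dims = ph$spec$voxel_dims)
      nawm_path <- file.path(out_dir, "nawm_mask.nii.gz")
      lesion_path <- file.path(out_dir, "lesion_mask.nii.gz")
      write_volume3d(ph$nawm_mask, nawm_path, ph$spec$voxel_dims)
      write_volume3d(ph$lesion_mask, lesion_path, ph$spec$voxel_dims)
      write_volume3d(ph$truth, file.path(out_dir, "truth_mwf.nii.gz"),
                     ph$spec$voxel_dims)
      manifest$stages[["simulate-phantom"]] <- list(
        seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
        n_voxels = prod(ph$spec$grid_shape))
      voxel_dims <- ph$spec$voxel_dims
      volume <- ph$volume
      nawm <- ph$nawm_mask
      lesion <- ph$lesion_mask
    } else {
      stage <- "read-input"
      ev <- read_echo_volume(config$input$volume,
                             if (!is.null(config$input$metadata))
                               config$input$metadata else
                               sidecar_path(config$input$volume))
      volume <- ev$volume
      protocol <- ev$protocol
      voxel_dims <- ev$voxel_dims
      nawm <- read_volume3d(config$input$nawm_mask)$values
      lesion <- read_volume3d(config$input$lesion_mask)$values
      for (key in c("volume", "nawm_mask", "lesion_mask")) {
        manifest$inputs[[key]] <-
          unname(tools::md5sum(config$input[[key]]))
      }
    }

    stage <- "fit-mwf"
    t0 <- Sys.time()
    nawm_only <- subtract_mask(nawm, lesion)
    fit_mask <- array(as.integer(nawm_only == 1L | lesion == 1L),
                      dim(nawm_only))
    map <- fit_mwf_map(volume, fit_mask, protocol, fitcfg, voxel_dims)
    map_path <- file.path(out_dir, "mwf_map.nii.gz")
    write_volume3d(map, map_path)
    manifest$stages[["fit-mwf"]] <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      n_fitted = sum(!is.na(map$values)))

    stage <- "roi-stats"
    t0 <- Sys.time()
    nawm_stats <- roi_stats(map, nawm_only, label = "nawm")
    lesion_stats <- roi_stats(map, lesion, label = "lesion")
    stats_path <- file.path(out_dir, "roi_stats.csv")
    write_roi_stats(list(nawm_stats, lesion_stats), stats_path)
    ratio <- mwf_ratio(lesion_stats, nawm_stats)
    manifest$stages[["roi-stats"]] <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      mwf_ratio = ratio)

    stage <- "cohort-analysis"
    t0 <- Sys.time()
    cohort <- if (!is.null(config$cohort$table)) {
      manifest$inputs[["cohort_table"]] <-
        unname(tools::md5sum(config$cohort$table))
      read_cohort(config$cohort$table)
    } else {
      sim <- simulate_cohort(cohort_params_from_config(config),
                             seed = config$seed)
      write_cohort(sim, file.path(out_dir, "cohort.csv"))
      sim
    }
    ca <- cohort_analysis(cohort)
    report_path <- file.path(out_dir, "cohort_report.csv")
    write_cohort_report(ca, report_path)
    manifest$stages[["cohort-analysis"]] <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      n_subjects = nrow(cohort))

    for (f in list.files(out_dir, full.names = TRUE)) {
      nm <- basename(f)
      if (nm != "manifest.json") {
        manifest$outputs[[nm]] <- unname(tools::md5sum(f))
      }
    }
    manifest$status <- "success"
    manifest
  }, error = function(e) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    manifest
  })
  result$timestamps$finished <- format(Sys.time())
  # timings vary run to run; keep them with the timestamps, outside the
  # deterministic payload
  result$timestamps$stage_seconds <-
    lapply(result$stages, function(s) s$seconds)
  result$stages <- lapply(result$stages, function(s) {
    s$seconds <- NULL
    s
  })
  jsonlite::write_json(result, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (identical(result$status, "failed")) {
    stop_invalid("pipeline failed at stage '", result$failed_stage, "': ",
                 result$error)
  }
  invisible(result)
}

# long-format CSV report of the cohort analysis
write_cohort_report <- function(ca, path) {
  rows <- list(
    c("n_subjects", ca$summary$n),
    c("mean_age_years", ca$summary$mean_age),
    c("median_edss", ca$summary$median_edss),
    c("mean_tug_day1_s", ca$summary$mean_tug_day1),
    c("mean_tug_day10_s", ca$summary$mean_tug_day10),
    c("mean_lesion_volume_mm3", ca$summary$mean_lesion_volume),
    c("n_complete_pairs", ca$summary$n_complete_pairs),
    c("n_responders", ca$summary$n_responders),
    c("tug_mean_diff_s", ca$tug_test$mean_diff),
    c("tug_sd_diff_s", ca$tug_test$sd_diff),
    c("tug_t_statistic", ca$tug_test$t_statistic),
    c("tug_p_value", ca$tug_test$p_value),
    c("tug_cohens_d", ca$tug_test$cohens_d)
  )
  for (nm in names(ca$normality)) {
    r <- ca$normality[[nm]]
    if (!is.null(r)) {
      rows <- c(rows, list(c(paste0("shapiro_w_", nm), r$statistic),
                           c(paste0("shapiro_p_", nm), r$p_value)))
    }
  }
  if (!is.null(ca$screen)) {
    sc <- ca$screen$screen
    for (i in seq_len(nrow(sc))) {
      if (sc$status[i] == "ok") {
        rows <- c(rows, list(
          c(paste0("screen_r_", sc$predictor[i]), sc$r[i]),
          c(paste0("screen_p_", sc$predictor[i]), sc$p_value[i])))
      }
    }
    reg <- ca$screen$regression
    rows <- c(rows, list(
      c("selected_predictor", ca$screen$selected),
      c("regression_r_squared", reg$r_squared),
      c("regression_slope", reg$slope),
      c("regression_f", reg$f_statistic),
      c("regression_p", reg$p_value)))
  }
  df <- data.frame(metric = vapply(rows, `[`, "", 1),
                   value = vapply(rows, `[`, "", 2),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
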