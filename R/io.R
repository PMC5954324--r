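# NIfTI-1, CSV and JSON-sidecar readers/writers. NIfTI-1 has no standard
# echo-time field, so echo times travel in a JSON sidecar next to the
# volume.

#' Write a 4D multi-echo volume as NIfTI-1 with a metadata sidecar
#'
#' @param volume4d 4D numeric array, echo as 4th dimension.
#' @param protocol an [acquisition_protocol()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param metadata_path sidecar JSON path; default replaces the NIfTI
#'   extension with `.json`.
#' @param voxel_dims numeric length-3, mm.
#' @return `path`, invisibly.
#' @export
write_echo_volume <- function(volume4d, protocol, path,
                              metadata_path = sidecar_path(path),
                              voxel_dims = c(1, 1, 4)) {
  if (length(dim(volume4d)) != 4L) stop_invalid("`volume4d` must be 4D")
  if (!inherits(protocol, "acquisition_protocol")) {
    protocol <- acquisition_protocol(protocol)
  }
  if (dim(volume4d)[4] != length(protocol$echo_times)) {
    stop_invalid("4th dimension must match the protocol's echo count")
  }
  attr(volume4d, "pixdim") <- c(voxel_dims, 1)
  RNifti::writeNifti(RNifti::asNifti(volume4d), path)
  jsonlite::write_json(
    list(echo_times_ms = protocol$echo_times,
         repetition_time_ms = protocol$repetition_time),
    metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a 4D multi-echo volume and its acquisition protocol
#'
#' @param path NIfTI-1 file with echoes along the 4th dimension.
#' @param metadata_path JSON sidecar listing `echo_times_ms`.
#' @return List with `volume` (4D array), `protocol`
#'   ([acquisition_protocol()]), `voxel_dims`.
#' @export
read_echo_volume <- function(path, metadata_path = sidecar_path(path)) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_invalid("not a readable NIfTI file: ", path))
  vol <- array(as.numeric(img), dim(img))
  if (length(dim(vol)) != 4L) stop_invalid("volume is not 4D (format error)")
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  te <- as.numeric(meta$echo_times_ms)
  if (length(te) != dim(vol)[4]) {
    stop_invalid(sprintf(
      "metadata lists %d echo times but the volume has %d echoes (format error)",
      length(te), dim(vol)[4]))
  }
  tr <- if (!is.null(meta$repetition_time_ms)) meta$repetition_time_ms else 1000
  list(volume = vol,
       protocol = acquisition_protocol(te, tr),
       voxel_dims = RNifti::pixdim(img)[1:3])
}

#' Write a 3D volume (mask or map) as NIfTI-1
#'
#' MWF maps are written as 32-bit float with undefined voxels as `NaN`;
#' masks as integer 0/1.
#'
#' @param x 3D array, an [fit_mwf_map()] result, or a binary mask.
#' @param path output path.
#' @param voxel_dims mm per axis (taken from an `mwf_map` input).
#' @return `path`, invisibly.
#' @export
write_volume3d <- function(x, path, voxel_dims = c(1, 1, 4)) {
  if (inherits(x, "mwf_map")) {
    voxel_dims <- x$voxel_dims
    x <- x$values
  }
  if (length(dim(x)) != 3L) stop_invalid("`x` must be 3D")
  storage <- if (is.integer(x) || all(x[!is.na(x)] %in% c(0, 1))) "int16" else "float"
  x <- x + 0
  attr(x, "pixdim") <- voxel_dims
  RNifti::writeNifti(RNifti::asNifti(x, datatype = storage), path)
  invisible(path)
}

#' Read a 3D NIfTI volume
#'
#' @param path NIfTI-1 file.
#' @return List with `values` (3D array), `voxel_dims`.
#' @export
read_volume3d <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_invalid("not a readable NIfTI file: ", path))
  vol <- array(as.numeric(img), dim(img))
  if (length(dim(vol)) == 4L && dim(vol)[4] == 1L) {
    vol <- array(vol, dim(vol)[1:3])
  }
  if (length(dim(vol)) != 3L) stop_invalid("volume is not 3D (format error)")
  list(values = vol, voxel_dims = RNifti::pixdim(img)[1:3])
}

#' Read a cohort CSV
#'
#' Expected columns: `subject_id, age, edss, tug_day1_s, tug_day10_s,
#' lesion_volume_mm3` plus optional `sex, lesion_mwf, nawm_mwf, mwf_ratio`.
#' Empty cells (e.g. a Day 10 TUG not completed) become `NA`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  required <- c("subject_id", "age", "edss", "tug_day1_s", "tug_day10_s",
                "lesion_volume_mm3")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop_invalid("cohort CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  tab
}

#' Write a cohort CSV
#'
#' @param table cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write per-ROI statistics as CSV
#'
#' One row per ROI: `label, n_voxels, volume_mm3, mean_mwf, se_mwf`.
#'
#' @param stats_list a [roi_stats()] result or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_stats <- function(stats_list, path) {
  if (inherits(stats_list, "roi_stats")) stats_list <- list(stats_list)
  df <- do.call(rbind, lapply(stats_list, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
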