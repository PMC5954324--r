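# ROI mask handling and statistics.

# Coerce a mask to strict 0/1 integers; nonzero values other than 1 (some
# tools emit 0/255) are coerced to 1 with a warning.
coerce_mask <- function(mask) {
  v <- as.vector(mask)
  if (any(!(v %in% c(0, 1)))) {
    warning("mask contains values other than 0/1; coercing nonzero to 1",
            call. = FALSE)
  }
  array(as.integer(v != 0), dim(mask))
}

#' Subtract one ROI mask from another
#'
#' Removes lesion voxels from the NAWM mask so the two ROIs never overlap:
#' output voxel = 1 iff it is NAWM and not lesion.
#'
#' @param nawm,lesion binary 3D arrays of identical shape.
#' @return Binary 3D array, disjoint from `lesion`.
#' @export
#' @examples
#' a <- array(1, c(2, 2, 1)); b <- array(0, c(2, 2, 1)); b[1, 1, 1] <- 1
#' sum(subtract_mask(a, b))  # 3
subtract_mask <- function(nawm, lesion) {
  if (!identical(dim(nawm), dim(lesion))) {
    stop_invalid("mask shapes differ (registration error)")
  }
  nawm <- coerce_mask(nawm)
  lesion <- coerce_mask(lesion)
  array(as.integer(nawm == 1L & lesion == 0L), dim(nawm))
}

#' ROI statistics from an MWF map
#'
#' Mean and standard error of the defined (non-`NA`) map values under the
#' mask, plus the ROI volume (voxel count times voxel volume). Undefined
#' voxels are excluded from the mean, never treated as 0.
#'
#' @param map an [fit_mwf_map()] result, or a 3D numeric array (then
#'   `voxel_dims` must be given).
#' @param mask binary 3D array.
#' @param voxel_dims mm per axis; taken from `map` when it is an `mwf_map`.
#' @param label optional ROI label carried in the result.
#' @return Object of class `roi_stats`: list with `label`, `mean_mwf`,
#'   `se_mwf`, `n_voxels`, `volume_mm3`.
#' @export
roi_stats <- function(map, mask, voxel_dims = NULL, label = "roi") {
  if (inherits(map, "mwf_map")) {
    if (is.null(voxel_dims)) voxel_dims <- map$voxel_dims
    values <- map$values
  } else {
    values <- map
    if (is.null(voxel_dims)) stop_invalid("`voxel_dims` required for a bare array")
  }
  if (!identical(dim(values), dim(mask))) {
    stop_invalid("map and mask shapes differ (registration error)")
  }
  mask <- coerce_mask(mask)
  sel <- as.vector(mask) == 1L
  vals <- as.vector(values)[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop_invalid("empty effective ROI: no defined map voxels under the mask")
  }
  n <- length(vals)
  structure(list(label = label,
                 mean_mwf = mean(vals),
                 se_mwf = if (n > 1) stats::sd(vals) / sqrt(n) else 0,
                 n_voxels = sum(sel),
                 volume_mm3 = sum(sel) * prod(voxel_dims)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI '%s': %d voxels (%.1f mm^3), MWF %.4f +/- %.4f (SE)\n",
              x$label, x$n_voxels, x$volume_mm3, x$mean_mwf, x$se_mwf))
  invisible(x)
}

#' @export
as.data.frame.roi_stats <- function(x, ...) {
  data.frame(label = x$label, n_voxels = x$n_voxels,
             volume_mm3 = x$volume_mm3, mean_mwf = x$mean_mwf,
             se_mwf = x$se_mwf, stringsAsFactors = FALSE)
}

#' Lesion/NAWM MWF ratio
#'
#' Lesion ROI mean MWF divided by NAWM ROI mean MWF. Values closer to one
#' indicate less myelin disruption inside lesions; the ratio normalises
#' away between-subject differences in NAWM myelin content.
#'
#' @param lesion_stats,nawm_stats [roi_stats()] results (or bare means).
#' @return The ratio (unitless).
#' @export
#' @examples
#' mwf_ratio(0.080, 0.0999)
mwf_ratio <- function(lesion_stats, nawm_stats) {
  les <- if (inherits(lesion_stats, "roi_stats")) lesion_stats$mean_mwf
         else as.numeric(lesion_stats)
  naw <- if (inherits(nawm_stats, "roi_stats")) nawm_stats$mean_mwf
         else as.numeric(nawm_stats)
  if (!is.finite(naw) || naw <= 0) {
    stop_invalid("NAWM mean MWF must be positive for a defined ratio")
  }
  les / naw
}
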