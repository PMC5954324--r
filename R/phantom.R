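#' Phantom specification
#'
#' Ground-truth geometry and pool parameters for a simulated multi-echo
#' brain phantom: a cuboid of NAWM-like tissue carrying zero or more
#' spherical lesion blobs with their own pool sets. Geometry is deliberately
#' simple — the quantities under test are spectral, not anatomical — and
#' spheres make voxel-count oracles easy.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_dims numeric length-3, mm per axis (default 1 x 1 x 4 mm).
#' @param nawm_poolset [pool_set()] for normal-appearing white matter.
#'   Default plants MWF 0.0999.
#' @param lesion_poolsets list of [pool_set()], one per lesion blob.
#'   Default plants MWF 0.080 in three blobs (MS brains typically carry
#'   several lesions; the default total lesion volume, about
#'   10900 mm^3, is on the scale of the moderate-to-high lesion loads
#'   seen in relapsing-remitting cohorts).
#' @param lesion_geometry list of `list(center =, radius =)` in voxel
#'   units; all blobs must lie inside the grid.
#' @param noise_sigma additive noise standard deviation, same units as the
#'   pool `total_signal`; >= 0.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 16),
                         voxel_dims = c(1, 1, 4),
                         nawm_poolset = pool_set(c(0.0999, 0.8801, 0.02),
                                                 c(20, 80, 2000)),
                         lesion_poolsets = rep(list(
                           pool_set(c(0.080, 0.895, 0.025), c(20, 80, 2000))),
                           3),
                         lesion_geometry = list(
                           list(center = c(8, 8, 8), radius = 6),
                           list(center = c(24, 8, 8), radius = 6),
                           list(center = c(16, 24, 8), radius = 6)),
                         noise_sigma = 0,
                         noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop_invalid("`grid_shape` must be three positive integers")
  }
  check_numeric(voxel_dims, "voxel_dims", positive = TRUE)
  if (noise_sigma < 0) stop_invalid("`noise_sigma` must be >= 0")
  if (!inherits(nawm_poolset, "pool_set")) {
    stop_invalid("`nawm_poolset` must be a pool_set")
  }
  if (length(lesion_poolsets) != length(lesion_geometry)) {
    stop_invalid("one pool set per lesion blob is required")
  }
  for (geom in lesion_geometry) {
    ctr <- geom$center
    r <- geom$radius
    if (length(ctr) != 3L || length(r) != 1L || r <= 0) {
      stop_invalid("each lesion needs a 3-vector center and positive radius")
    }
    # voxel centers sit at 1..dim; the physical grid edge is half a voxel
    # beyond the outermost centers
    if (any(ctr - r < 0.5) || any(ctr + r > grid_shape + 0.5)) {
      stop_invalid("lesion blob extends outside the phantom grid")
    }
  }
  structure(list(grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
                 nawm_poolset = nawm_poolset,
                 lesion_poolsets = lesion_poolsets,
                 lesion_geometry = lesion_geometry,
                 noise_sigma = as.numeric(noise_sigma),
                 noise_model = noise_model),
            class = "phantom_spec")
}

# logical 3D array of voxels inside any lesion sphere; voxel centers at
# integer coordinates 1..dim
lesion_voxels <- function(spec) {
  dims <- spec$grid_shape
  inside <- array(0L, dims)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  label <- integer(nrow(idx))
  for (k in seq_along(spec$lesion_geometry)) {
    geom <- spec$lesion_geometry[[k]]
    d2 <- (idx[, 1] - geom$center[1])^2 + (idx[, 2] - geom$center[2])^2 +
      (idx[, 3] - geom$center[3])^2
    label[d2 <= geom$radius^2 & label == 0L] <- k
  }
  array(label, dims)
}

#' Simulate a multi-echo phantom
#'
#' Every voxel's noise-free decay follows [pool_signal()] for its tissue's
#' pool set; independent noise is then added per the spec's noise model.
#' Gaussian noise adds `N(0, sigma)` per echo; Rician noise takes the
#' magnitude of the signal plus complex Gaussian noise (`sigma` per
#' channel), the standard model for magnitude MRI. The ground-truth MWF map
#' records each tissue's [pool_set_mwf()]. The emitted NAWM and lesion
#' masks are disjoint: lesion voxels are excluded from the NAWM mask.
#'
#' @param spec a [phantom_spec()].
#' @param protocol an [acquisition_protocol()].
#' @param seed integer RNG seed (default 0); fixed seed gives bit-identical
#'   output.
#' @return Object of class `mwf_phantom`: list with `volume` (4D array,
#'   echo last), `nawm_mask`, `lesion_mask` (binary 3D arrays),
#'   `truth` (3D ground-truth MWF), `protocol`, `spec`, `seed`.
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(8, 8, 4),
#'                      lesion_geometry = list(list(center = c(4, 4, 2),
#'                                                  radius = 1)))
#' ph <- make_phantom(spec, seed = 1)
#' dim(ph$volume)
make_phantom <- function(spec = phantom_spec(),
                         protocol = acquisition_protocol(), seed = 0) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("`spec` must be a phantom_spec")
  if (!inherits(protocol, "acquisition_protocol")) {
    protocol <- acquisition_protocol(protocol)
  }
  dims <- spec$grid_shape
  n_echo <- length(protocol$echo_times)
  label <- lesion_voxels(spec)
  nawm_mask <- array(as.integer(label == 0L), dims)
  lesion_mask <- array(as.integer(label > 0L), dims)

  signals <- rbind(pool_signal(spec$nawm_poolset, protocol))
  truths <- pool_set_mwf(spec$nawm_poolset)
  for (ps in spec$lesion_poolsets) {
    signals <- rbind(signals, pool_signal(ps, protocol))
    truths <- c(truths, pool_set_mwf(ps))
  }

  flat_label <- as.vector(label) + 1L  # 1 = NAWM, 1+k = lesion k
  clean <- signals[flat_label, , drop = FALSE]  # n_voxel x n_echo
  truth <- array(truths[flat_label], dims)

  noisy <- with_seed(seed, {
    if (spec$noise_sigma == 0) {
      clean
    } else if (spec$noise_model == "gaussian") {
      clean + matrix(stats::rnorm(length(clean), 0, spec$noise_sigma),
                     nrow = nrow(clean))
    } else {
      n1 <- matrix(stats::rnorm(length(clean), 0, spec$noise_sigma),
                   nrow = nrow(clean))
      n2 <- matrix(stats::rnorm(length(clean), 0, spec$noise_sigma),
                   nrow = nrow(clean))
      sqrt((clean + n1)^2 + n2^2)
    }
  })

  volume <- array(noisy, c(dims, n_echo))
  structure(list(volume = volume, nawm_mask = nawm_mask,
                 lesion_mask = lesion_mask, truth = truth,
                 protocol = protocol, spec = spec, seed = seed),
            class = "mwf_phantom")
}

#' @export
print.mwf_phantom <- function(x, ...) {
  cat(sprintf("Multi-echo phantom: %s voxels x %d echoes\n",
              paste(x$spec$grid_shape, collapse = "x"),
              length(x$protocol$echo_times)))
  cat(sprintf("  NAWM voxels: %d (truth MWF %.4f)\n", sum(x$nawm_mask),
              pool_set_mwf(x$spec$nawm_poolset)))
  cat(sprintf("  lesion voxels: %d\n", sum(x$lesion_mask)))
  cat(sprintf("  noise: %s, sigma = %g, seed = %d\n",
              x$spec$noise_model, x$spec$noise_sigma, x$seed))
  invisible(x)
}
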