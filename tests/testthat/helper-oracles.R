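# Shared helpers: independent oracles and small fixtures built in code.

# Exact NNLS by exhaustive active-set enumeration: for every subset of
# columns solve the unconstrained least-squares problem; keep subsets whose
# solution is non-negative; the minimum achieved residual over those (and
# the zero solution) is the exact constrained optimum. Only feasible for
# small systems.
enumerate_nnls <- function(A, b) {
  n <- ncol(A)
  best <- sqrt(sum(b^2))  # zero solution
  best_x <- numeric(n)
  for (size in seq_len(n)) {
    for (cols in utils::combn(n, size, simplify = FALSE)) {
      beta <- tryCatch(qr.coef(qr(A[, cols, drop = FALSE]), b),
                       error = function(e) NULL)
      if (is.null(beta) || anyNA(beta) || any(beta < 0)) next
      x <- numeric(n)
      x[cols] <- beta
      r <- sqrt(sum((A %*% x - b)^2))
      if (r < best) {
        best <- r
        best_x <- x
      }
    }
  }
  list(x = best_x, residual_norm = best)
}

# small random NNLS system generator
random_small_system <- function(seed) {
  set.seed(seed)
  m <- sample(2:5, 1)
  n <- sample(2:4, 1)
  A <- matrix(abs(rnorm(m * n)), m, n)
  b <- rnorm(m)
  list(A = A, b = b)
}

# a phantom small enough for repeated fitting in tests (~58 lesion voxels)
small_phantom_spec <- function(noise_sigma = 0,
                               noise_model = "gaussian") {
  phantom_spec(grid_shape = c(10, 10, 6),
               lesion_poolsets = list(
                 pool_set(c(0.080, 0.895, 0.025), c(20, 80, 2000))),
               lesion_geometry = list(list(center = c(5, 5, 3), radius = 2.4)),
               noise_sigma = noise_sigma, noise_model = noise_model)
}

# on-grid fixture: grid containing the exact pool T2s
ongrid_config <- function() {
  fit_config(t2_grid(values = c(15, 20, 40, 80, 200, 500, 1000, 2000)))
}
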