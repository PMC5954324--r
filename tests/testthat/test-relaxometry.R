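# NNLS spectrum fitting: basis, solver optimality, window fractions, maps.

test_that("decay basis entries are exact exponentials", {
  basis <- build_decay_basis(acquisition_protocol(), t2_grid(values = c(10, 15, 1e9)))
  expect_equal(basis$matrix[1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(basis$matrix[1, 3], 1, tolerance = 1e-6)   # T2 -> Inf limit
  expect_equal(basis$matrix[32, 2], exp(-320 / 15), tolerance = 1e-12)
  expect_equal(exp(-320 / 15), 5.4e-10, tolerance = 1e-2)
  expect_true(all(basis$matrix > 0 & basis$matrix <= 1))
  expect_error(build_decay_basis(acquisition_protocol(), t2_grid(values = numeric(0))),
               "non-empty")
})

test_that("NNLS matches exhaustive active-set enumeration on small systems", {
  for (seed in 1:40) {
    sys <- random_small_system(seed)
    mine <- nnls_solve(sys$A, sys$b)
    oracle <- enumerate_nnls(sys$A, sys$b)
    expect_lt(abs(mine$residual_norm - oracle$residual_norm), 1e-10)
    expect_true(all(mine$x >= 0))
  }
})

test_that("NNLS agrees with an independent solver on realistic bases", {
  skip_if_not_installed("pracma")
  basis <- build_decay_basis()
  set.seed(11)
  for (i in 1:20) {
    sig <- pool_signal(pool_set(c(0.1, 0.88, 0.02), c(20, 80, 2000))) +
      rnorm(32, 0, 0.01)
    mine <- nnls_solve(basis$matrix, sig)
    ref <- pracma::lsqnonneg(basis$matrix, sig)
    expect_equal(mine$residual_norm, sqrt(ref$resid.norm), tolerance = 1e-8)
    expect_equal(mine$x, ref$x, tolerance = 1e-6)
  }
})

test_that("noise-free on-grid signals are recovered exactly", {
  cfg <- ongrid_config()
  basis <- build_decay_basis(acquisition_protocol(), cfg$grid)

  # single basis column
  fit1 <- fit_t2_spectrum(basis$matrix[, 4], basis)  # T2 = 80 ms column
  expect_lt(fit1$residual_norm, 1e-8)
  expect_equal(sum(fit1$amplitudes), 1, tolerance = 1e-6)
  expect_gt(fit1$amplitudes[4], 0.999)

  # planted biexponential on grid points 20 and 80 ms
  sig <- 0.1 * basis$matrix[, 2] + 0.9 * basis$matrix[, 4]
  fit2 <- fit_t2_spectrum(sig, basis)
  expect_lt(fit2$residual_norm, 1e-8)
  expect_equal(fit2$amplitudes[2], 0.1, tolerance = 1e-6)
  expect_equal(fit2$amplitudes[4], 0.9, tolerance = 1e-6)
  expect_equal(compute_mwf(fit2, cfg), 0.1, tolerance = 1e-6)
})

test_that("no random non-negative candidate beats the NNLS residual", {
  basis <- build_decay_basis(acquisition_protocol(), t2_grid(n = 10))
  set.seed(3)
  sig <- pool_signal(pool_set(c(0.15, 0.85), c(25, 90))) + rnorm(32, 0, 0.02)
  fit <- fit_t2_spectrum(sig, basis)
  A <- basis$matrix
  cand_res <- replicate(1e4, {
    x <- rexp(ncol(A)) * sample(c(0, 1), ncol(A), replace = TRUE, prob = c(0.5, 0.5))
    sqrt(sum((A %*% x - sig)^2))
  })
  expect_true(all(cand_res >= fit$residual_norm - 1e-12))
})

test_that("fitted amplitudes are non-negative on fuzzed signals", {
  basis <- build_decay_basis()
  set.seed(21)
  for (i in 1:30) {
    sig <- rnorm(32, 0.3, 0.4)  # includes negative, non-physical inputs
    fit <- fit_t2_spectrum(sig, basis)
    expect_true(all(fit$amplitudes >= 0))
    expect_gte(fit$residual_norm, 0)
  }
  expect_error(fit_t2_spectrum(c(rep(1, 31), NA), basis), "finite")
})

test_that("scaling the signal scales amplitudes and preserves MWF", {
  basis <- build_decay_basis()
  set.seed(5)
  sig <- pool_signal(pool_set(c(0.12, 0.86, 0.02), c(22, 85, 1800))) +
    rnorm(32, 0, 0.005)
  f1 <- fit_t2_spectrum(sig, basis)
  f2 <- fit_t2_spectrum(100 * sig, basis)
  expect_equal(f2$amplitudes, 100 * f1$amplitudes, tolerance = 1e-8)
  expect_equal(compute_mwf(f2), compute_mwf(f1), tolerance = 1e-12)
})

test_that("spectrum_fraction and compute_mwf follow the window rules", {
  cfg <- ongrid_config()
  basis <- build_decay_basis(acquisition_protocol(), cfg$grid)
  mk <- function(amp) {
    structure(list(grid = cfg$grid, amplitudes = amp, residual_norm = 0,
                   signal = drop(basis$matrix %*% amp), basis = basis,
                   method = "nnls"), class = "t2_spectrum")
  }
  amps <- numeric(8)
  amps[2] <- 0.1   # 20 ms
  amps[4] <- 0.9   # 80 ms
  sp <- mk(amps)
  expect_equal(spectrum_fraction(sp, c(15, 40)), 0.1, tolerance = 1e-12)
  expect_equal(spectrum_fraction(sp, c(40, 200)), 0.9, tolerance = 1e-12)
  expect_equal(compute_mwf(sp, cfg), 0.1, tolerance = 1e-12)

  # all mass inside / outside the window
  expect_equal(spectrum_fraction(mk(c(0, 1, rep(0, 6))), c(15, 40)), 1)
  expect_equal(spectrum_fraction(mk(c(0, 0, 0, 1, rep(0, 4))), c(15, 40)), 0)

  # the 40 ms edge is counted in the medium window, not the short one
  edge <- numeric(8); edge[3] <- 1  # exactly 40 ms
  expect_equal(spectrum_fraction(mk(edge), c(15, 40)), 0)
  expect_equal(spectrum_fraction(mk(edge), c(40, 200)), 1)

  # zero spectrum is undefined, never 0/0
  expect_true(is.na(compute_mwf(mk(numeric(8)), cfg)))
  expect_error(spectrum_fraction(sp, c(3000, 4000)), "intersect")
})

test_that("chi2-constrained fit reduces to plain NNLS at factor 1 and
           inflates the misfit by the requested factor", {
  basis <- build_decay_basis()
  set.seed(8)
  sig <- pool_signal(pool_set(c(0.1, 0.88, 0.02), c(20, 80, 2000))) +
    rnorm(32, 0, 0.01)
  plain <- fit_t2_spectrum(sig, basis)
  same <- fit_t2_spectrum(sig, basis, method = "chi2", chi2_factor = 1)
  expect_equal(same$residual_norm, plain$residual_norm, tolerance = 1e-6)
  expect_equal(compute_mwf(same), compute_mwf(plain), tolerance = 1e-6)

  reg <- fit_t2_spectrum(sig, basis, method = "chi2", chi2_factor = 1.02)
  expect_equal(reg$residual_norm^2 / plain$residual_norm^2, 1.02,
               tolerance = 1e-3)
  expect_true(all(reg$amplitudes >= 0))
  # minimum-energy side effect: the regularised spectrum is never larger
  # in Euclidean norm than the unregularised one
  expect_lte(sum(reg$amplitudes^2), sum(plain$amplitudes^2) + 1e-12)
})

test_that("regularisation reduces the voxelwise spread of MWF estimates", {
  basis <- build_decay_basis()
  sig0 <- pool_signal(pool_set(c(0.10, 0.88, 0.02), c(20, 80, 2000)))
  set.seed(13)
  mwf_plain <- numeric(60)
  mwf_reg <- numeric(60)
  for (i in 1:60) {
    s <- sig0 + rnorm(32, 0, 0.01)
    mwf_plain[i] <- compute_mwf(fit_t2_spectrum(s, basis))
    mwf_reg[i] <- compute_mwf(fit_t2_spectrum(s, basis, method = "chi2",
                                              chi2_factor = 1.02))
  }
  expect_lte(sd(mwf_reg), sd(mwf_plain))
})

test_that("MWF maps recover noise-free phantoms and respect masks", {
  spec <- small_phantom_spec()
  ph <- make_phantom(spec, seed = 0)
  cfg <- fit_config(t2_grid(values = c(15, 20, 40, 80, 200, 2000)))
  map <- fit_mwf_map(ph$volume, ph$nawm_mask, ph$protocol, cfg,
                     spec$voxel_dims)
  vals <- map$values[ph$nawm_mask == 1]
  expect_true(all(abs(vals - 0.0999) < 1e-6))
  expect_true(all(is.na(map$values[ph$lesion_mask == 1])))

  # empty mask: everything undefined
  empty <- array(0L, spec$grid_shape)
  map0 <- fit_mwf_map(ph$volume, empty, ph$protocol, cfg, spec$voxel_dims)
  expect_true(all(is.na(map0$values)))

  # registration guard
  bad <- array(1L, c(4, 4, 4))
  expect_error(fit_mwf_map(ph$volume, bad, ph$protocol, cfg), "registration")
})

test_that("map error grows monotonically with phantom noise", {
  cfg <- fit_config(t2_grid(n = 24))
  errs <- sapply(c(0, 0.005, 0.01, 0.02), function(sg) {
    ph <- make_phantom(small_phantom_spec(noise_sigma = sg), seed = 17)
    map <- fit_mwf_map(ph$volume, NULL, ph$protocol, cfg)
    mean(abs(map$values - ph$truth), na.rm = TRUE)
  })
  expect_true(all(diff(errs) >= -1e-12))
})
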