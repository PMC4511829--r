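test_that("initial-volume discard drops exactly the leading time points", {
  s <- series_from_matrix(matrix(seq_len(2 * 160), 2, 160), c(1, 2, 1))
  out <- discard_initial_volumes(s, 10)
  expect_equal(n_volumes(out), 150)
  expect_equal(out$data[1, 1, 1, 1], s$data[1, 1, 1, 11])
  expect_equal(n_volumes(discard_initial_volumes(s, 25)), 135)
  expect_identical(discard_initial_volumes(s, 0)$data, s$data)
  expect_error(discard_initial_volumes(s, 160), "cannot discard")
})

test_that("motion exclusion is strict at 2 mm / 2 degrees", {
  zero <- matrix(0, 20, 6)
  expect_false(motion_excluded(zero))

  spike <- zero; spike[5, 2] <- 2.5
  expect_true(motion_excluded(spike))

  rot <- zero; rot[3, 6] <- -2.4
  expect_true(motion_excluded(rot))

  boundary <- matrix(2, 20, 6)  # exactly at threshold: retained
  expect_false(motion_excluded(boundary))
})

test_that("nuisance regression leaves residuals orthogonal to the confounds", {
  set.seed(1)
  n <- 60
  c1 <- rnorm(n)
  vox <- 2 * c1 + rnorm(n, sd = 0.3)
  s <- series_from_matrix(rbind(vox, rnorm(n)), c(2, 1, 1))
  out <- regress_nuisance(s, cbind(c1))
  res <- out$data[1, 1, 1, ]
  expect_lt(abs(cor(res, c1)), 1e-10)
  expect_lt(abs(sum(res * c1)), 1e-8)
  # oracle: direct normal-equations solve
  d <- cbind(1, c1)
  beta <- solve(crossprod(d), crossprod(d, vox))
  expect_equal(res, as.vector(vox - d %*% beta), tolerance = 1e-10)

  # confound equal to the series itself annihilates it
  self <- regress_nuisance(s, cbind(vox))
  expect_lt(max(abs(self$data[1, 1, 1, ])), 1e-10)

  # no confounds: mean centering only
  centred <- regress_nuisance(s)
  expect_equal(as.vector(centred$data[1, 1, 1, ]), vox - mean(vox))

  # duplicated column is dropped with a warning, result unchanged
  expect_warning(dup <- regress_nuisance(s, cbind(c1, c1)), "dependent")
  expect_equal(dup$data, out$data, tolerance = 1e-10)
})

test_that("detrending removes linear trends exactly and is idempotent on residue", {
  n <- 80
  t_idx <- seq_len(n)
  lin <- series_from_matrix(rbind(3 + 0.5 * t_idx, rep(7, n)), c(2, 1, 1))
  out <- detrend(lin)
  expect_lt(max(abs(out$data)), 1e-9)

  sine <- sin(2 * pi * 5 * t_idx / n)
  s <- series_from_matrix(rbind(sine + 0.2 * t_idx - 4), c(1, 1, 1))
  rec <- detrend(s)$data[1, 1, 1, ]
  d <- cbind(1, t_idx)
  oracle <- sine + 0.2 * t_idx - 4 -
    as.vector(d %*% solve(crossprod(d), crossprod(d, sine + 0.2 * t_idx - 4)))
  expect_equal(rec, oracle, tolerance = 1e-10)
})

test_that("ideal band-pass keeps in-band bins exactly and kills out-of-band bins", {
  s_in <- sine_series(0.05, n = 150, tr = 2)   # bin 15 of 1/300 Hz spacing
  out <- bandpass(s_in)
  x0 <- s_in$data[1, 1, 1, ]; x1 <- out$data[1, 1, 1, ]
  expect_lt(abs(sum(x1^2) / sum(x0^2) - 1), 1e-10)

  s_hi <- sine_series(0.15, n = 150, tr = 2)
  expect_lt(max(abs(bandpass(s_hi)$data)), 1e-10)

  s_const <- uniform_series(rep(3, 150))
  expect_lt(max(abs(bandpass(s_const)$data)), 1e-10)

  expect_error(bandpass(s_in, high_hz = 0.3), "Nyquist")
  expect_error(bandpass(uniform_series(rnorm(20), tr = 0.1),
                        low_hz = 0.001, high_hz = 0.002), "no frequency bin")

  # idempotence on the same band
  twice <- bandpass(out)
  expect_equal(twice$data, out$data, tolerance = 1e-10)
})

test_that("gaussian smoothing preserves mass and matches brute-force convolution", {
  grid <- c(6, 6, 6)
  set.seed(2)
  vol <- array(rnorm(prod(grid)), grid)
  s <- bold_series(array(vol, c(grid, 1)), tr = 2)
  sm <- smooth_gaussian(s, fwhm_mm = 5)
  expect_equal(sum(sm$data), sum(vol), tolerance = 1e-10)

  # brute-force separable convolution with symmetric reflection
  sigma <- (5 / (2 * sqrt(2 * log(2)))) / 2
  r <- ceiling(4 * sigma)
  w <- dnorm(-r:r, sd = sigma); w <- w / sum(w)
  reflect <- function(j, n) {
    while (j < 1 || j > n) { if (j < 1) j <- 1 - j; if (j > n) j <- 2 * n + 1 - j }
    j
  }
  n <- grid[1]
  K1 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- reflect(i + o, n)
      K1[i, j] <- K1[i, j] + w[o + r + 1]
    }
  }
  S_full <- kronecker(K1, kronecker(K1, K1))  # Kz (x) Ky (x) Kx on vec()
  ref <- array(S_full %*% as.vector(vol), grid)
  expect_equal(sm$data[, , , 1], ref, tolerance = 1e-10)

  # impulse: peak shrinks, mass conserved
  imp <- array(0, grid); imp[3, 3, 3] <- 1
  si <- smooth_gaussian(bold_series(array(imp, c(grid, 1))), 5)
  expect_lt(max(si$data), 1)
  expect_equal(sum(si$data), 1, tolerance = 1e-10)

  # constant volume unchanged, tiny kernel is near-identity
  cst <- smooth_gaussian(bold_series(array(2, c(grid, 1))), 5)
  expect_equal(max(abs(cst$data - 2)), 0, tolerance = 1e-12)
  tiny <- smooth_gaussian(s, fwhm_mm = 1e-3)
  expect_equal(tiny$data, s$data, tolerance = 1e-8)
  expect_error(smooth_gaussian(s, 0), "positive")
})

test_that("per-metric plans apply the right steps in the right order", {
  set.seed(3)
  s <- series_from_matrix(matrix(rnorm(27 * 150), 27, 150), c(3, 3, 3))

  fc <- run_plan(s, "fc")
  expect_true(any(grepl("smooth", fc$provenance)))
  expect_true(any(grepl("bandpass", fc$provenance)))
  manual <- bandpass(detrend(smooth_gaussian(s, 5)))
  expect_equal(fc$data, manual$data, tolerance = 1e-12)

  reho <- run_plan(s, "reho")
  expect_false(any(grepl("smooth", reho$provenance)))
  expect_true(any(grepl("bandpass", reho$provenance)))

  falff <- run_plan(s, "falff")
  expect_true(any(grepl("smooth", falff$provenance)))
  expect_false(any(grepl("bandpass", falff$provenance)))

  # FC output has essentially no out-of-band power
  x <- fc$data[1, 1, 1, ]
  amp <- dft_amplitude(x)
  f <- seq_along(amp) / (150 * 2)
  out_band <- f < 0.01 - 1e-9 | f > 0.08 + 1e-9
  expect_lt(sum(amp[out_band]^2) / sum(amp^2), 1e-8)
})
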