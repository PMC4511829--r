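# independent KCC oracle: without ties, Kendall's W relates to the mean
# pairwise Spearman correlation as W = ((K - 1) * rbar + 1) / K
kcc_oracle <- function(x) {
  k <- ncol(x)
  rs <- cor(apply(x, 2, rank))
  ((k - 1) * mean(rs[upper.tri(rs)]) + 1) / k
}

test_that("Kendall's W matches hand-worked and oracle values", {
  expect_equal(kcc(matrix(rep(1:4, 3), 4, 3)), 1)           # perfect concordance
  expect_equal(kcc(cbind(1:3, 1:3, 3:1)), 2 / 18)           # R = (5,6,7)
  expect_equal(kcc(cbind(1:5, 5:1)), 0)                     # anti-ordered pair

  set.seed(21)
  for (i in 1:25) {
    x <- matrix(rnorm(20 * 5), 20, 5)
    w <- kcc(x)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_equal(w, kcc_oracle(x), tolerance = 1e-10)
    # invariant under a common strictly monotone transform
    expect_equal(kcc(exp(x)), w, tolerance = 1e-12)
    # permutation-symmetric in the series
    expect_equal(kcc(x[, sample(5)]), w, tolerance = 1e-12)
  }
  expect_error(kcc(matrix(1, 1, 3)), "2 x 2")
})

test_that("ReHo maps separate shared-signal regions from independent noise", {
  atl <- tiny_atlas()
  grid <- dim(atl$labels)
  mask <- atl$labels > 0
  diffs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    mat <- matrix(rnorm(prod(grid) * 60), prod(grid), 60)
    shared <- rnorm(60)
    idx <- which(atl$labels == 1)
    mat[idx, ] <- matrix(shared, length(idx), 60, byrow = TRUE) +
      0.7 * mat[idx, ]
    m <- reho_map(series_from_matrix(mat, grid), mask, standardize = FALSE)
    mean(m$values[atl$labels == 1]) - mean(m$values[atl$labels == 2])
  }, numeric(1))
  expect_true(all(diffs > 0))

  # raw W in [0, 1] and finite exactly on the mask
  set.seed(22)
  mat <- matrix(rnorm(prod(grid) * 40), prod(grid), 40)
  m <- reho_map(series_from_matrix(mat, grid), mask, standardize = FALSE)
  expect_true(all(m$values[mask] >= 0 & m$values[mask] <= 1))
  expect_true(all(is.na(m$values[!mask])))

  # all-identical series: z-scoring degenerates by contract
  same <- matrix(rep(rnorm(40), each = prod(grid)), prod(grid), 40)
  expect_error(reho_map(series_from_matrix(same, grid), mask), "constant")
})

test_that("clipped neighbourhoods use the actual member count", {
  mask <- array(FALSE, c(3, 3, 3)); mask[1:2, 1, 1] <- TRUE  # two lonely voxels
  set.seed(23)
  mat <- matrix(rnorm(27 * 30), 27, 30)
  m <- reho_map(series_from_matrix(mat, c(3, 3, 3)), mask, standardize = FALSE)
  idx <- which(mask)
  # K = 2 neighbourhood for both voxels: W computed pairwise
  expect_equal(m$values[idx[1]],
               kcc(cbind(mat[idx[1], ], mat[idx[2], ])), tolerance = 1e-12)
})

test_that("fALFF matches the direct spectral oracle on pure tones and noise", {
  mask <- array(TRUE, c(3, 3, 3))
  s_in <- sine_series(0.05, n = 150, tr = 2)
  m_in <- falff_map(s_in, mask, standardize = FALSE)
  expect_gte(min(m_in$values), 0.999)

  s_out <- sine_series(0.15, n = 150, tr = 2)
  m_out <- falff_map(s_out, mask, standardize = FALSE)
  expect_lte(max(m_out$values), 0.001)

  # oracle agreement + [0, 1] range + amplitude invariance on noise
  set.seed(24)
  x <- rnorm(150)
  s <- uniform_series(x)
  m <- falff_map(s, mask, standardize = FALSE)
  amp <- dft_amplitude(x)
  f <- seq_along(amp) / (150 * 2)
  oracle <- sum(amp[f >= 0.01 - 1e-12 & f <= 0.08 + 1e-12]) /
    sum(amp[f <= 0.25 + 1e-12])
  expect_equal(m$values[1, 1, 1], oracle, tolerance = 1e-10)
  expect_true(all(m$values >= 0 & m$values <= 1))
  m10 <- falff_map(uniform_series(10 * x), mask, standardize = FALSE)
  expect_equal(m10$values, m$values, tolerance = 1e-12)

  # white noise: expected ratio near the band's share of the spectrum bins
  set.seed(25)
  vals <- replicate(40, {
    falff_map(uniform_series(rnorm(150)), mask,
              standardize = FALSE)$values[1, 1, 1]
  })
  expect_equal(mean(vals), 22 / 75, tolerance = 0.05 / (22 / 75))
})

test_that("seed FC maps behave like voxelwise correlations with the seed", {
  atl <- tiny_atlas()
  grid <- dim(atl$labels)
  mask <- atl$labels > 0
  set.seed(26)
  seed_sig <- rnorm(80)
  mat <- matrix(rnorm(prod(grid) * 80), prod(grid), 80)
  for (l in 1:4) {
    idx <- which(atl$labels == l)
    mat[idx, ] <- matrix(seed_sig, length(idx), 80, byrow = TRUE) +
      (l - 1) * mat[idx, ]   # increasing noise away from the seed
  }
  s <- series_from_matrix(mat, grid)
  raw <- seed_fc_map(s, atl, seed_label = 1, transform = "fisher")
  r <- tanh(raw$values)
  expect_true(all(abs(r[mask]) <= 1))
  expect_true(all(is.na(raw$values[!mask])))
  # correlation decreases as voxel noise grows
  med <- vapply(1:4, function(l) median(r[atl$labels == l]), numeric(1))
  expect_true(all(diff(med) < 0))
  # fisher values match Eq.-style correlation of constructed series
  idx2 <- which(atl$labels == 2)[1]
  expect_equal(r[idx2],
               pearson_cc(mat[idx2, ], region_mean_series(s, atl, 1)),
               tolerance = 1e-10)

  # a mask on the wrong grid is rejected
  expect_error(falff_map(s, array(TRUE, c(2, 2, 2))), "geometry")
  expect_error(reho_map(s, array(TRUE, c(2, 2, 2))), "geometry")

  # degenerate spatial z-scoring when every voxel carries the seed series
  same <- matrix(rep(seed_sig, each = prod(grid)), prod(grid), 80)
  expect_error(seed_fc_map(series_from_matrix(same, grid), atl, 1,
                           transform = "spatial"), "constant")
  # both anterior seeds are supported
  expect_s3_class(seed_fc_map(s, atl, seed_label = 2), "biomarker_map")
})

test_that("fast cohort maps equal the voxelwise reference for all three kinds", {
  atl <- tiny_atlas()
  coh <- simulate_cohort(atl, cohort_spec(n_healthy = 1, n_subhealthy = 1,
                                          n_volumes = 60, rng_seed = 27))
  mask <- atl$labels > 0
  for (kind in c("fc", "reho", "falff")) {
    fast <- cohort_biomarker_maps(coh, atl, kind = kind, seed_label = 1,
                                  transform = "fisher")
    for (id in coh$manifest$subject_id) {
      raw <- subject_data(coh, id)$series
      pre <- run_plan(discard_initial_volumes(raw, 10),
                      switch(kind, fc = "fc", reho = "reho", falff = "falff"))
      slow <- switch(kind,
                     fc = seed_fc_map(pre, atl, 1, transform = "fisher"),
                     reho = reho_map(pre, mask),
                     falff = falff_map(pre, mask))
      expect_equal(fast[[id]]$values[mask], slow$values[mask],
                   tolerance = 1e-8)
    }
  }
})
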