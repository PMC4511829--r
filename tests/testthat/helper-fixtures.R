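# Small programmatic fixtures shared across test files.

# 10x10x10 atlas with four 2x2x2 blocks, 2 mm voxels
tiny_atlas <- function() {
  block <- function(x0, y0, z0) {
    as.matrix(expand.grid(x = x0 + 0:1, y = y0 + 0:1, z = z0 + 0:1))
  }
  make_atlas(c(10, 10, 10), list(
    region_spec(1, block(2, 7, 5)),
    region_spec(2, block(7, 7, 7)),
    region_spec(3, block(2, 2, 2)),
    region_spec(4, block(7, 2, 5))
  ))
}

# 12x12x12 atlas with four 3x3x3 blocks (enough voxels for ICA/Dice tests)
small_atlas <- function() {
  block <- function(x0, y0, z0) {
    as.matrix(expand.grid(x = x0 + 0:2, y = y0 + 0:2, z = z0 + 0:2))
  }
  make_atlas(c(12, 12, 12), list(
    region_spec(1, block(2, 8, 5)),
    region_spec(2, block(8, 8, 8)),
    region_spec(3, block(2, 2, 2)),
    region_spec(4, block(8, 2, 5))
  ))
}

# bold_series wrapping a voxels x time matrix on an arbitrary grid
series_from_matrix <- function(mat, grid, tr = 2, voxel_size = c(2, 2, 2)) {
  bold_series(array(mat, c(grid, ncol(mat))), tr = tr, voxel_size = voxel_size)
}

# single-voxel-per-point constant-geometry series from one time series,
# replicated over every voxel of a small grid
uniform_series <- function(ts, grid = c(3, 3, 3), tr = 2) {
  series_from_matrix(matrix(ts, prod(grid), length(ts), byrow = TRUE),
                     grid, tr = tr)
}

sine_series <- function(freq_hz, n = 150, tr = 2, grid = c(3, 3, 3)) {
  uniform_series(sin(2 * pi * freq_hz * (0:(n - 1)) * tr), grid, tr)
}

# feature columns in the fixed on-disk pair order
cc_columns <- function() {
  c("cc_1_2", "cc_1_3", "cc_2_3", "cc_1_4", "cc_2_4", "cc_3_4")
}

# spectral amplitude of x at every positive frequency, by explicit DFT —
# the independent oracle for band-pass / fALFF checks
dft_amplitude <- function(x) {
  n <- length(x)
  k <- seq_len(floor(n / 2))
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))
  }, numeric(1))
}
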