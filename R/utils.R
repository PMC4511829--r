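# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream of derived seeds, kept below 2^31 - 1 so they remain
# valid R integers. Exact in double arithmetic (48271 * 2^31 < 2^53).
derive_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m + 48271 * (as.numeric(i) %% m)) %% m)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# voxels x time matrix view of a 4D (x, y, z, t) array
flatten_series <- function(data) {
  d <- dim(data)
  matrix(data, prod(d[1:3]), d[4])
}

unflatten_series <- function(mat, grid) {
  array(mat, c(grid, ncol(mat)))
}
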