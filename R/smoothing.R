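# Separable 3D Gaussian smoothing and its linear-operator views.
#
# Smoothing is a linear map S = Kz (x) Ky (x) Kx built from per-axis
# convolution matrices with symmetric (reflective) boundary padding, so
# per-volume mass is preserved. Exposing S as explicit matrices gives two
# fast, algebraically exact shortcuts used by the cohort drivers:
#   * region-mean of smoothed data  ==  (S' u_r)' X   (u_r = region indicator
#     average), computed without ever smoothing the 4D volume;
#   * smoothed values restricted to a small mask  ==  S[mask, ] X with a
#     sparse row block.

# 1D Gaussian convolution matrix (n x n) with symmetric padding
gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) abort("smoothing sigma must be positive")
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- i + o
      # reflect repeatedly for kernels wider than the grid
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      K[i, j] <- K[i, j] + w[o + r + 1L]
    }
  }
  K
}

fwhm_to_sigma <- function(fwhm_mm, voxel_mm) {
  (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm
}

axis_kernels <- function(fwhm_mm, grid, voxel_size) {
  lapply(1:3, function(a) {
    gaussian_kernel_matrix(grid[a], fwhm_to_sigma(fwhm_mm, voxel_size[a]))
  })
}

apply_axis1 <- function(arr, K) {
  d <- dim(arr)
  array(K %*% matrix(arr, d[1], prod(d[-1])), d)
}

# apply per-axis matrices K[[1..3]] along the first three dims of a 3D/4D array
apply_separable <- function(arr, K) {
  nd <- length(dim(arr))
  perm2 <- if (nd == 4L) c(2, 1, 3, 4) else c(2, 1, 3)
  perm3 <- if (nd == 4L) c(3, 2, 1, 4) else c(3, 2, 1)
  arr <- apply_axis1(arr, K[[1]])
  arr <- aperm(apply_axis1(aperm(arr, perm2), K[[2]]), perm2)
  aperm(apply_axis1(aperm(arr, perm3), K[[3]]), perm3)
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3D Gaussian smoothing with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, scaled by the voxel size.
#' Boundaries use symmetric (reflective) padding, so the per-volume sum is
#' preserved.
#'
#' @param series A [bold_series].
#' @param fwhm_mm Kernel full width at half maximum in mm (> 0, default 5).
#' @return A smoothed [bold_series].
#' @export
smooth_gaussian <- function(series, fwhm_mm = 5) {
  stopifnot(inherits(series, "bold_series"))
  stopifnot_scalar_number(fwhm_mm, "fwhm_mm", positive = TRUE)
  K <- axis_kernels(fwhm_mm, dim(series$data)[1:3], series$voxel_size)
  update_series(series, apply_separable(series$data, K),
                sprintf("smooth(fwhm=%gmm)", fwhm_mm))
}

# 4 x nvox matrix W with W[r, ] = S' u_r, u_r the normalized indicator of
# region r, so W %*% X gives the region-mean series of the smoothed data.
region_projection <- function(template, fwhm_mm = 5) {
  grid <- dim(template$labels)
  K <- axis_kernels(fwhm_mm, grid, template$voxel_size)
  Kt <- lapply(K, t)
  W <- matrix(0, 4, prod(grid))
  for (r in 1:4) {
    idx <- which(template$labels == r)
    if (!length(idx)) abort(sprintf("label %d missing from template", r))
    u <- array(0, grid)
    u[idx] <- 1 / length(idx)
    W[r, ] <- as.vector(apply_separable(u, Kt))
  }
  W
}

# sparse (nmask x nvox) row block of the smoothing operator
smoothing_rows <- function(mask, fwhm_mm, voxel_size) {
  grid <- dim(mask)
  K <- axis_kernels(fwhm_mm, grid, voxel_size)
  nz <- lapply(K, function(k) apply(k != 0, 1, which, simplify = FALSE))
  vox <- which(mask, arr.ind = TRUE)
  triplets <- vector("list", nrow(vox))
  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1]; j <- vox[v, 2]; k <- vox[v, 3]
    jx <- nz[[1]][[i]]; jy <- nz[[2]][[j]]; jz <- nz[[3]][[k]]
    g <- expand.grid(x = jx, y = jy, z = jz)
    w <- K[[1]][i, g$x] * K[[2]][j, g$y] * K[[3]][k, g$z]
    triplets[[v]] <- cbind(v, g$x + (g$y - 1) * grid[1] +
                                (g$z - 1) * grid[1] * grid[2], w)
  }
  tr <- do.call(rbind, triplets)
  sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
               dims = c(nrow(vox), prod(grid)))
}
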