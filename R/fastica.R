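#' Fixed-point spatial ICA
#'
#' Symmetric fixed-point ICA with the logcosh (tanh) contrast, operating on
#' a time-by-voxel matrix: rows are mixtures, columns (voxels) are the
#' samples, so the recovered sources are spatial maps. The data are reduced
#' to `n_comp` principal components and whitened before the fixed-point
#' iteration with symmetric decorrelation. Written in-package so the
#' decomposition is fully deterministic given `seed`; non-convergent runs
#' are retried with derived seeds before erroring.
#'
#' @param x Numeric matrix (time points x voxels).
#' @param n_comp Number of components (>= 2, at most `nrow(x)`).
#' @param seed Integer seed for the random orthogonal initialization.
#' @param max_iter,tol Fixed-point iteration controls. The default
#'   tolerance of 1e-3 on the decorrelation change accommodates strongly
#'   band-limited data, whose low effective temporal rank makes the noise
#'   components rotation-degenerate and slow to pin down more tightly.
#' @param retries How many fresh initializations to attempt on
#'   non-convergence before raising an error.
#' @return List with `S` (`n_comp` x voxels spatial maps, unit variance
#'   across voxels), `A` (time x `n_comp` mixing matrix), `iterations`,
#'   `converged`, and `seed_used`.
#' @export
fastica_decompose <- function(x, n_comp, seed = 1, max_iter = 500,
                              tol = 1e-3, retries = 5) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix.")
  n_comp <- as.integer(n_comp)
  if (n_comp < 2L) abort("`n_comp` must be at least 2.")
  nt <- nrow(x); nv <- ncol(x)
  x <- x - rowMeans(x)
  # PCA whitening from the small (time x time) covariance
  cv <- tcrossprod(x) / nv
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(pos) < n_comp) {
    n_comp <- sum(pos)
    if (n_comp < 2L) abort("data rank too low for ICA")
    warn(sprintf("rank-limited: reducing to %d components", n_comp))
  }
  d <- eg$values[seq_len(n_comp)]
  U <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  Kw <- diag(1 / sqrt(d), n_comp) %*% t(U)    # whitening (n_comp x time)
  Z <- Kw %*% x                               # n_comp x voxels, white

  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
  }

  for (try in seq_len(retries)) {
    seed_try <- if (try == 1L) seed else derive_seed(seed, try)
    W <- with_seed(seed_try,
                   matrix(rnorm(n_comp * n_comp), n_comp, n_comp))
    W <- sym_decorrelate(W)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      U1 <- W %*% Z
      G <- tanh(U1)
      W1 <- sym_decorrelate(G %*% t(Z) / nv -
                              diag(rowMeans(1 - G^2), n_comp) %*% W)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) {
      S <- W %*% Z
      A <- U %*% diag(sqrt(d), n_comp) %*% t(W)
      return(list(S = S, A = A, iterations = it, converged = TRUE,
                  seed_used = seed_try, n_comp = n_comp))
    }
  }
  abort(sprintf("ICA failed to converge after %d initializations", retries))
}
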