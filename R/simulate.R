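#' Synthetic cohort specification
#'
#' Declares the generating conditions for a ground-truth BOLD cohort:
#' group sizes, the target pairwise correlation among the four DMN regions
#' for healthy (`cc_healthy`) and sub-healthy (`cc_subhealthy`) subjects,
#' voxel-level noise, and acquisition timing. Defaults mirror a resting-state
#' protocol with TR = 2 s and 160 acquired volumes (150 retained after the
#' usual 10-volume discard), with healthy inter-region correlations around
#' 0.6 that drop to 0.25 in sub-healthy subjects.
#'
#' Region signals are built from a shared band-limited (0.01--0.08 Hz)
#' latent source: region r receives
#' `sqrt(rho) * common + sqrt(1 - rho) * independent_r`, so every one of the
#' six region pairs has expected correlation `rho`. Voxels add white noise
#' with standard deviation `noise_sd`; background voxels are pure noise.
#'
#' @param n_healthy,n_subhealthy Group sizes (healthy subjects carry truth
#'   label +1, sub-healthy -1).
#' @param cc_healthy,cc_subhealthy Target pairwise region correlations in
#'   (0, 1\] and \[0, 1) respectively, with `cc_subhealthy < cc_healthy`.
#' @param noise_sd Voxel-level white-noise standard deviation (signal units;
#'   region signals have unit variance).
#' @param tr Repetition time in seconds.
#' @param n_volumes Raw acquired volume count (>= 20).
#' @param motion_spike_prob Probability that a subject's motion trace
#'   contains one supra-threshold (> 2 mm) translation spike, to exercise
#'   the motion exclusion rule. Default 0.
#' @param rng_seed Integer master seed; per-subject seeds are derived from it.
#' @return A `cohort_spec` object.
#' @seealso [simulate_subject()], [simulate_cohort()]
#' @export
cohort_spec <- function(n_healthy = 74, n_subhealthy = 10,
                        cc_healthy = 0.6, cc_subhealthy = 0.25,
                        noise_sd = 1, tr = 2, n_volumes = 160,
                        motion_spike_prob = 0, rng_seed = 1) {
  for (nm in c("cc_healthy", "cc_subhealthy", "noise_sd", "tr",
               "motion_spike_prob", "rng_seed")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (n_healthy < 0 || n_subhealthy < 0) abort("group sizes must be >= 0")
  if (n_volumes < 20) abort("`n_volumes` must be at least 20.")
  if (cc_healthy <= 0 || cc_healthy > 1 || cc_subhealthy < 0 ||
      cc_subhealthy >= 1) {
    abort("target correlations must lie in (0, 1] (healthy) and [0, 1) (sub-healthy).")
  }
  if (cc_subhealthy >= cc_healthy) {
    abort("`cc_subhealthy` must be strictly below `cc_healthy`.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (motion_spike_prob < 0 || motion_spike_prob > 1) {
    abort("`motion_spike_prob` must be in [0, 1].")
  }
  structure(list(n_healthy = as.integer(n_healthy),
                 n_subhealthy = as.integer(n_subhealthy),
                 cc_healthy = cc_healthy, cc_subhealthy = cc_subhealthy,
                 noise_sd = noise_sd, tr = tr,
                 n_volumes = as.integer(n_volumes),
                 motion_spike_prob = motion_spike_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# Unit-variance Gaussian series ideal-filtered to [low, high] Hz, so the
# latent region signals survive the analysis band-pass unchanged.
band_limited_series <- function(n, tr, low = 0.01, high = 0.08) {
  x <- rnorm(n)
  f <- bin_frequencies(n, tr)
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  if (!any(keep)) abort("no frequency bin falls inside the latent band")
  xf <- fft(x)
  xf[!keep] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) abort("degenerate band-limited draw")
  y / s
}

# two-sided bin frequencies (Hz) of a length-n series sampled at 1/tr
bin_frequencies <- function(n, tr) {
  k <- 0:(n - 1)
  pmin(k, n - k) / (n * tr)
}

#' Simulate one synthetic subject
#'
#' Generates a 4D BOLD-like volume on the atlas grid. All voxels of region r
#' share a band-limited region time series with pairwise inter-region
#' correlation `cc_healthy` (or `cc_subhealthy` when `subhealthy = TRUE`)
#' plus i.i.d. voxel noise; background voxels are pure noise. A 6-column
#' rigid-motion trace (3 translations in mm, 3 rotations in degrees) with
#' sub-threshold jitter is generated alongside; with probability
#' `motion_spike_prob` one volume receives a > 2 mm translation spike.
#' Output is bit-reproducible given `seed`.
#'
#' @param atlas A [labeled_atlas] carrying all four region labels.
#' @param spec A [cohort_spec()].
#' @param subhealthy Logical; use the lowered target correlation?
#' @param seed Integer seed for this subject.
#' @return List with `series` (a [bold_series]) and `motion`
#'   (an `n_volumes` x 6 matrix).
#' @examples
#' atl <- default_atlas()
#' sub <- simulate_subject(atl, cohort_spec(n_volumes = 40), seed = 7)
#' sub$series
#' @export
simulate_subject <- function(atlas, spec, subhealthy = FALSE, seed = 1) {
  stopifnot(inherits(atlas, "labeled_atlas"), inherits(spec, "cohort_spec"))
  if (!all(1:4 %in% atlas$labels)) abort("`atlas` must carry all four labels.")
  rho <- if (subhealthy) spec$cc_subhealthy else spec$cc_healthy
  grid <- atlas_grid(atlas)
  nv <- spec$n_volumes
  with_seed(seed, {
    common <- band_limited_series(nv, spec$tr)
    region_ts <- vapply(1:4, function(r) {
      sqrt(rho) * common + sqrt(1 - rho) * band_limited_series(nv, spec$tr)
    }, numeric(nv))                       # nv x 4
    mat <- matrix(rnorm(prod(grid) * nv, sd = spec$noise_sd), prod(grid), nv)
    for (r in 1:4) {
      idx <- label_indices(atlas, r)
      mat[idx, ] <- mat[idx, ] +
        matrix(region_ts[, r], length(idx), nv, byrow = TRUE)
    }
    motion <- cbind(matrix(rnorm(3 * nv, sd = 0.2), nv, 3),
                    matrix(rnorm(3 * nv, sd = 0.15), nv, 3))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    if (runif(1) < spec$motion_spike_prob) {
      motion[sample.int(nv, 1), sample.int(3, 1)] <-
        2.5 + runif(1)                    # clearly above the 2 mm rule
    }
    series <- bold_series(unflatten_series(mat, grid), tr = spec$tr,
                          voxel_size = atlas$voxel_size)
    series$provenance <- sprintf("simulated(rho=%g, seed=%d)", rho, seed)
    list(series = series, motion = motion)
  })
}

#' Simulate a labeled cohort
#'
#' Lays out `n_healthy` healthy (truth +1) and `n_subhealthy` sub-healthy
#' (truth -1) subjects with per-subject seeds derived deterministically from
#' `spec$rng_seed`. To keep memory flat for large cohorts the 4D volumes are
#' not materialized here; [subject_data()] regenerates any subject on demand
#' from its stored seed, and [write_cohort()] streams the cohort to disk.
#'
#' @inheritParams simulate_subject
#' @return A `synthetic_cohort`: list with `manifest` (tibble: subject_id,
#'   group, truth, seed), `atlas`, `spec`.
#' @examples
#' coh <- simulate_cohort(default_atlas(),
#'                        cohort_spec(n_healthy = 3, n_subhealthy = 1,
#'                                    n_volumes = 40))
#' coh$manifest
#' @export
simulate_cohort <- function(atlas, spec) {
  stopifnot(inherits(atlas, "labeled_atlas"), inherits(spec, "cohort_spec"))
  n <- spec$n_healthy + spec$n_subhealthy
  truth <- rep(c(1L, -1L), c(spec$n_healthy, spec$n_subhealthy))
  manifest <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = ifelse(truth == 1L, "healthy", "subhealthy"),
    truth = truth,
    seed = vapply(seq_len(n), function(i) derive_seed(spec$rng_seed, i),
                  integer(1))
  )
  structure(list(manifest = manifest, atlas = atlas, spec = spec),
            class = "synthetic_cohort")
}

#' @rdname simulate_cohort
#' @param cohort A `synthetic_cohort`.
#' @param subject_id One subject id from the manifest.
#' @return `subject_data()` returns the `list(series, motion)` for one
#'   subject, regenerated deterministically.
#' @export
subject_data <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  row <- cohort$manifest[cohort$manifest$subject_id == subject_id, ]
  if (nrow(row) != 1L) abort(sprintf("unknown subject_id '%s'", subject_id))
  simulate_subject(cohort$atlas, cohort$spec,
                   subhealthy = row$truth == -1L, seed = row$seed)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d healthy + %d sub-healthy, ",
                     "rho %g vs %g, %d volumes @ TR %gs (master seed %d)\n"),
              x$spec$n_healthy, x$spec$n_subhealthy, x$spec$cc_healthy,
              x$spec$cc_subhealthy, x$spec$n_volumes, x$spec$tr,
              x$spec$rng_seed))
  invisible(x)
}
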