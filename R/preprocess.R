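# Temporal preprocessing: volume discard, motion exclusion, nuisance
# regression, linear detrending and ideal band-pass filtering. The matrix
# workers (voxels x time) are shared with the high-throughput cohort paths.

#' Discard initial volumes
#'
#' Drops the first `n_discard` time points (scanner calibration /
#' acclimatization volumes); the remaining data are unchanged.
#'
#' @param series A [bold_series].
#' @param n_discard Number of leading volumes to drop (default 10); must be
#'   smaller than the number of volumes.
#' @return A [bold_series] with `n_volumes - n_discard` volumes.
#' @export
discard_initial_volumes <- function(series, n_discard = 10) {
  stopifnot(inherits(series, "bold_series"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) abort("`n_discard` must be >= 0.")
  if (n_discard >= n_volumes(series)) {
    abort(sprintf("cannot discard %d of %d volumes", n_discard,
                  n_volumes(series)))
  }
  if (n_discard == 0L) return(series)
  update_series(series, series$data[, , , -seq_len(n_discard), drop = FALSE],
                sprintf("discard(%d)", n_discard))
}

#' Motion-based subject exclusion rule
#'
#' A subject is excluded when any translation exceeds `max_mm` millimetres
#' or any rotation exceeds `max_deg` degrees, in absolute value and
#' strictly ("more than"): a trace touching exactly 2 mm is retained. Each
#' of the three rotation parameters is compared against the degree
#' threshold directly; no composite rotation norm is formed.
#'
#' @param trace Numeric matrix with 6 columns: translations x, y, z (mm)
#'   then rotations (degrees), one row per acquired volume.
#' @param max_mm,max_deg Exclusion thresholds (defaults 2 mm, 2 degrees).
#' @return `TRUE` if the subject should be excluded.
#' @export
motion_excluded <- function(trace, max_mm = 2, max_deg = 2) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 1L || ncol(trace) != 6L) {
    abort("`trace` must be a non-empty matrix with 6 columns.")
  }
  max(abs(trace[, 1:3])) > max_mm || max(abs(trace[, 4:6])) > max_deg
}

# least-squares residuals of each row of `mat` (voxels x time) against the
# column space of `design` (time x p); intercept always included
residualize_mat <- function(mat, design) {
  design <- cbind(intercept = rep(1, ncol(mat)), design)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    warn(sprintf("dropping %d linearly dependent confound column(s): %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  t(qr.resid(qr_d, t(mat)))
}

#' Nuisance regression
#'
#' Replaces every voxel time series by its least-squares residual against an
#' intercept plus the supplied per-volume confound regressors (e.g. motion
#' parameters, white-matter and CSF signals). Residuals are orthogonal to
#' every confound column. Linearly dependent confound columns are dropped
#' with a warning.
#'
#' @param series A [bold_series].
#' @param confounds Numeric matrix with one row per volume (or `NULL` for
#'   intercept-only regression, i.e. mean centering).
#' @return A [bold_series] of residuals.
#' @export
regress_nuisance <- function(series, confounds = NULL) {
  stopifnot(inherits(series, "bold_series"))
  nt <- n_volumes(series)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt) {
      abort(sprintf("confounds have %d rows but the series has %d volumes",
                    nrow(confounds), nt))
    }
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- sprintf("c%d", seq_len(ncol(confounds)))
    }
  }
  mat <- residualize_mat(flatten_series(series$data), confounds)
  update_series(series, unflatten_series(mat, dim(series$data)[1:3]),
                sprintf("nuisance(%d)", if (is.null(confounds)) 0L
                        else ncol(confounds)))
}

detrend_mat <- function(mat) {
  residualize_mat(mat, seq_len(ncol(mat)))
}

#' Linear detrending
#'
#' Removes the per-voxel least-squares linear trend (including the mean).
#'
#' @param series A [bold_series].
#' @return A detrended [bold_series].
#' @export
detrend <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  mat <- detrend_mat(flatten_series(series$data))
  update_series(series, unflatten_series(mat, dim(series$data)[1:3]),
                "detrend")
}

bandpass_mat <- function(mat, tr, low, high) {
  nt <- ncol(mat)
  nyquist <- 1 / (2 * tr)
  if (high > nyquist + 1e-12) {
    abort(sprintf("upper band edge %g Hz exceeds the Nyquist frequency %g Hz",
                  high, nyquist))
  }
  if (low > high) abort("`low_hz` must not exceed `high_hz`.")
  f <- bin_frequencies(nt, tr)
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  if (!any(keep)) {
    abort(sprintf("no frequency bin of a %d-point series at TR %gs falls in [%g, %g] Hz",
                  nt, tr, low, high))
  }
  xf <- mvfft(t(mat))
  xf[!keep, ] <- 0
  t(Re(mvfft(xf, inverse = TRUE)) / nt)
}

#' Ideal band-pass filter
#'
#' Frequency-domain boxcar filter: discrete-frequency bins with
#' `low_hz <= f <= high_hz` (inclusive at both edges) are retained, all
#' others -- including the DC bin -- are zeroed. This ideal-filter
#' convention makes pass/stop behaviour exact at on-bin frequencies.
#'
#' @param series A [bold_series].
#' @param low_hz,high_hz Band edges in Hz (defaults 0.01 and 0.08);
#'   `high_hz` must not exceed the Nyquist frequency `1 / (2 tr)`.
#' @return A filtered [bold_series].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(series, "bold_series"))
  mat <- bandpass_mat(flatten_series(series$data), series$tr, low_hz, high_hz)
  update_series(series, unflatten_series(mat, dim(series$data)[1:3]),
                sprintf("bandpass(%g-%g Hz)", low_hz, high_hz))
}

#' Per-metric preprocessing plans
#'
#' Each voxelwise metric uses its own preprocessing variant:
#' * `"fc"` (functional connectivity): smooth, detrend, band-pass;
#' * `"reho"` (regional homogeneity): detrend, band-pass -- no smoothing,
#'   since smoothing would inflate rank agreement among neighbours;
#' * `"falff"`: smooth, detrend -- no band-pass, since the metric is a
#'   ratio of band amplitude to full-spectrum amplitude.
#'
#' @param metric One of `"fc"`, `"reho"`, `"falff"`.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 5).
#' @param low_hz,high_hz Analysis band in Hz (defaults 0.01--0.08).
#' @return A `preproc_plan` (list of ordered steps and parameters).
#' @export
preproc_plan <- function(metric = c("fc", "reho", "falff"), fwhm_mm = 5,
                         low_hz = 0.01, high_hz = 0.08) {
  metric <- match.arg(metric)
  steps <- switch(metric,
                  fc = c("smooth", "detrend", "bandpass"),
                  reho = c("detrend", "bandpass"),
                  falff = c("smooth", "detrend"))
  structure(list(metric = metric, steps = steps, fwhm_mm = fwhm_mm,
                 low_hz = low_hz, high_hz = high_hz),
            class = "preproc_plan")
}

#' @rdname preproc_plan
#' @param series A [bold_series].
#' @param plan A `preproc_plan` (or a metric name).
#' @return `run_plan()` returns the processed [bold_series]; the applied
#'   plan is recorded in its provenance.
#' @export
run_plan <- function(series, plan) {
  if (is.character(plan)) plan <- preproc_plan(plan)
  stopifnot(inherits(series, "bold_series"), inherits(plan, "preproc_plan"))
  for (step in plan$steps) {
    series <- switch(step,
                     smooth = smooth_gaussian(series, fwhm_mm = plan$fwhm_mm),
                     detrend = detrend(series),
                     bandpass = bandpass(series, plan$low_hz, plan$high_hz))
  }
  series$provenance <- c(series$provenance, sprintf("plan(%s)", plan$metric))
  series
}
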