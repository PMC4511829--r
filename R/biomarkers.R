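# Voxelwise DMN biomarkers: seed-based functional connectivity, regional
# homogeneity (Kendall's coefficient of concordance over the 26-voxel
# neighbourhood) and fractional amplitude of low-frequency fluctuation.

biomarker_map <- function(values, kind, voxel_size, mask, ...) {
  structure(list(values = values, kind = kind,
                 voxel_size = as.numeric(voxel_size), mask = mask, ...),
            class = c("biomarker_map", "spatial_map"))
}

#' @export
print.biomarker_map <- function(x, ...) {
  cat(sprintf("<biomarker_map:%s> %s grid, %d mask voxels\n", x$kind,
              paste(dim(x$values), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Kendall's coefficient of concordance
#'
#' Rank agreement W of K time series over n time points:
#' `W = (sum(R_i^2) - n Rbar^2) / (K^2 (n^3 - n) / 12)` where `R_i` is the
#' across-series rank sum at time point i and `Rbar = (n + 1) K / 2`.
#' Each series is ranked over its own time points with mid-rank (average)
#' assignment for ties and no tie-correction term. W lies in \[0, 1\] and
#' equals 1 under perfect concordance.
#'
#' @param x Numeric matrix, time points in rows (n >= 2) and series in
#'   columns (K >= 2).
#' @return The concordance W.
#' @examples
#' kcc(matrix(rep(1:4, 3), 4, 3))  # identical monotone series: W = 1
#' @export
kcc <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) abort("`x` must be at least 2 x 2 (time x series).")
  ranks <- apply(x, 2, rank)
  ri <- rowSums(ranks)
  rbar <- (n + 1) * k / 2
  (sum(ri^2) - n * rbar^2) / (k^2 * (n^3 - n) / 12)
}

# neighbourhood offsets for a given connectivity (26 / 18 / 6)
neighbourhood_offsets <- function(connectivity = 26) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "26" = o,
         "18" = o[rowSums(abs(o)) <= 2, , drop = FALSE],
         "6" = o[rowSums(abs(o)) == 1, , drop = FALSE],
         abort("`connectivity` must be 6, 18 or 26"))
}

# list of in-mask member indices (into the mask-voxel ordering) for each
# mask voxel: itself plus its in-mask neighbours
mask_neighbourhoods <- function(mask, connectivity = 26) {
  grid <- dim(mask)
  vox <- which(mask, arr.ind = TRUE)
  pos <- array(0L, grid)
  pos[mask] <- seq_len(nrow(vox))
  offs <- neighbourhood_offsets(connectivity)
  members <- rep(list(NULL), nrow(vox))
  for (v in seq_len(nrow(vox))) members[[v]] <- pos[vox[v, 1], vox[v, 2], vox[v, 3]]
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid[3]
    id <- rep(0L, nrow(vox))
    id[ok] <- pos[nb[ok, , drop = FALSE]]
    hit <- which(id > 0L)
    for (v in hit) members[[v]] <- c(members[[v]], id[v])
  }
  members
}

check_mask_geometry <- function(mask, series) {
  if (!identical(dim(mask), dim(series$data)[1:3])) {
    abort("`mask` geometry does not match the series grid.")
  }
  if (!any(mask)) abort("`mask` is empty.")
  mask
}

# shared z-scoring used by all three maps
standardize_masked <- function(raw, mask, grid, kind, voxel_size,
                               standardize, ...) {
  vals <- array(NA_real_, grid)
  if (standardize) {
    s <- sd(raw)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("%s map is constant over the mask; z-scoring is undefined",
                    kind))
    }
    vals[mask] <- (raw - mean(raw)) / s
    kind <- paste0("z", kind)
  } else {
    vals[mask] <- raw
  }
  biomarker_map(vals, kind, voxel_size, mask, ...)
}

.seed_fc_core <- function(y, seed_ts, transform) {
  yc <- y - rowMeans(y)
  sc <- seed_ts - mean(seed_ts)
  ss <- sqrt(sum(sc^2))
  vv <- sqrt(rowSums(yc^2))
  if (ss == 0) abort("seed series has zero variance")
  r <- as.vector(yc %*% sc) / (vv * ss)
  nzero <- sum(vv == 0)
  if (nzero > 0) {
    r[vv == 0] <- 0
    inform(sprintf("%d zero-variance voxel(s) set to r = 0", nzero))
  }
  if (transform == "fisher") atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)) else r
}

#' Seed-based functional connectivity map
#'
#' Correlates the seed region's mean time series with every DMN-mask voxel
#' and returns the map of correlations r. Two normalizations are offered
#' for the subsequent group comparison: `transform = "spatial"` (default)
#' standardizes the r map to mean 0 / sd 1 over the mask, while
#' `transform = "fisher"` applies the variance-stabilizing `atanh(r)`
#' voxelwise without spatial standardization.
#'
#' @param series A [bold_series] preprocessed with the FC plan.
#' @param template `labeled_template` carrying the seed region.
#' @param seed_label Seed region label (the anterior seeds 1 = prefrontal
#'   and 2 = parietal are conventional).
#' @param mask Binary 3D array of DMN voxels (default: template support).
#' @param transform `"spatial"` or `"fisher"` (see above).
#' @return A `biomarker_map` of kind `"zFC"`.
#' @export
seed_fc_map <- function(series, template, seed_label = 1, mask = NULL,
                        transform = c("spatial", "fisher")) {
  transform <- match.arg(transform)
  mask <- if (is.null(mask)) template$labels > 0 else mask != 0
  mask <- check_mask_geometry(mask, series)
  seed_ts <- region_mean_series(series, template, seed_label)
  y <- flatten_series(series$data)[which(mask), , drop = FALSE]
  r <- .seed_fc_core(y, seed_ts, transform)
  standardize_masked(r, mask, dim(series$data)[1:3], "FC", series$voxel_size,
                     standardize = (transform == "spatial"),
                     seed_label = seed_label, transform = transform)
}

.reho_core <- function(y, members) {
  ranks <- t(apply(y, 1, rank))          # nmask x n of temporal ranks
  n <- ncol(y)
  vapply(members, function(m) {
    k <- length(m)
    if (k < 2L) return(NA_real_)
    ri <- colSums(ranks[m, , drop = FALSE])
    (sum(ri^2) - n * ((n + 1) * k / 2)^2) / (k^2 * (n^3 - n) / 12)
  }, numeric(1))
}

#' Regional homogeneity (ReHo) map
#'
#' Kendall's coefficient of concordance of each mask voxel's time series
#' with its nearest 26 neighbours (face, edge and corner), computed on
#' unsmoothed data. Neighbourhoods are clipped to in-mask, in-bounds voxels
#' and the actual member count K enters the formula, so boundary voxels use
#' K < 27; voxels with no in-mask neighbour get `NA`.
#'
#' @param series A [bold_series] preprocessed with the ReHo plan (detrend +
#'   band-pass, no smoothing).
#' @param mask Binary 3D array of DMN voxels.
#' @param standardize Z-score the map over the mask (default `TRUE`)?
#' @return A `biomarker_map` of kind `"zReHo"` (or `"ReHo"`).
#' @export
reho_map <- function(series, mask, standardize = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  mask <- check_mask_geometry(mask != 0, series)
  y <- flatten_series(series$data)[which(mask), , drop = FALSE]
  w <- .reho_core(y, mask_neighbourhoods(mask, 26))
  standardize_masked(w, mask, dim(series$data)[1:3], "ReHo",
                     series$voxel_size, standardize)
}

.falff_core <- function(y, tr, band, full_upper) {
  n <- ncol(y)
  amp <- Mod(mvfft(t(y)))                # n x nmask amplitude spectrum
  f <- bin_frequencies(n, tr)
  half <- seq_len(floor(n / 2)) + 1L     # positive-frequency bins, DC excluded
  fb <- f[half]
  in_band <- fb >= band[1] - 1e-12 & fb <= band[2] + 1e-12
  in_full <- fb <= full_upper + 1e-12
  num <- colSums(amp[half[in_band], , drop = FALSE])
  den <- colSums(amp[half[in_full], , drop = FALSE])
  ratio <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    inform(sprintf("%d zero-amplitude voxel(s) set to fALFF = 0",
                   sum(den == 0)))
  }
  ratio
}

#' Fractional ALFF map
#'
#' Square roots of the power spectrum are summed over the low-frequency
#' band (0.01--0.08 Hz) and divided by the sum over the full frequency
#' range up to `full_upper_hz` (default: the Nyquist frequency, 0.25 Hz at
#' TR = 2 s). The input must not be band-pass filtered. The DC bin is
#' excluded from the denominator: the data are detrended, so it carries no
#' fluctuation amplitude.
#'
#' @param series A [bold_series] preprocessed with the fALFF plan (smooth +
#'   detrend, no band-pass).
#' @param mask Binary 3D array of DMN voxels.
#' @param band Low-frequency band in Hz.
#' @param full_upper_hz Upper edge of the full range (default Nyquist).
#' @param standardize Z-score the map over the mask (default `TRUE`)?
#' @return A `biomarker_map` of kind `"zfALFF"` (or `"fALFF"`), raw values
#'   in \[0, 1\].
#' @export
falff_map <- function(series, mask, band = c(0.01, 0.08),
                      full_upper_hz = NULL, standardize = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  mask <- check_mask_geometry(mask != 0, series)
  full_upper <- full_upper_hz %||% (1 / (2 * series$tr))
  if (band[2] > full_upper + 1e-12) {
    abort("`band` must lie inside the full frequency range")
  }
  y <- flatten_series(series$data)[which(mask), , drop = FALSE]
  ratio <- .falff_core(y, series$tr, band, full_upper)
  standardize_masked(ratio, mask, dim(series$data)[1:3], "fALFF",
                     series$voxel_size, standardize)
}

#' Per-subject biomarker maps for a whole cohort
#'
#' Runs the metric-specific preprocessing variant and the corresponding
#' biomarker for every subject. For the smoothing-based variants the maps
#' only need smoothed values inside the DMN mask, so a sparse row block of
#' the smoothing operator replaces full-volume smoothing; temporal steps
#' then act on mask voxels only. This is algebraically identical to the
#' voxelwise route and much faster.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param template `labeled_template` (its support is the DMN mask).
#' @param kind `"fc"`, `"reho"` or `"falff"`.
#' @param seed_label Seed region for `kind = "fc"`.
#' @param transform FC normalization (see [seed_fc_map()]).
#' @param n_discard Leading volumes to drop (default 10).
#' @param fwhm_mm Smoothing FWHM for the smoothing-based variants.
#' @param subjects Optional subset of subject ids.
#' @return Named list of `biomarker_map`s, one per subject.
#' @export
cohort_biomarker_maps <- function(cohort, template,
                                  kind = c("fc", "reho", "falff"),
                                  seed_label = 1,
                                  transform = c("spatial", "fisher"),
                                  n_discard = 10, fwhm_mm = 5,
                                  subjects = NULL) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mask <- template$labels > 0
  grid <- dim(mask)
  ids <- subjects %||% cohort$manifest$subject_id
  tr <- cohort$spec$tr
  if (kind %in% c("fc", "falff")) {
    S <- smoothing_rows(mask, fwhm_mm, template$voxel_size)
  }
  if (kind == "fc") W <- region_projection(template, fwhm_mm)
  if (kind == "reho") members <- mask_neighbourhoods(mask, 26)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    x <- flatten_series(subject_data(cohort, ids[i])$series$data)
    x <- x[, -seq_len(n_discard), drop = FALSE]
    out[[i]] <- switch(kind,
      fc = {
        y <- bandpass_mat(detrend_mat(as.matrix(S %*% x)), tr, 0.01, 0.08)
        seed_ts <- as.vector(bandpass_mat(detrend_mat(W %*% x), tr,
                                          0.01, 0.08)[seed_label, ])
        r <- .seed_fc_core(y, seed_ts, transform)
        standardize_masked(r, mask, grid, "FC", template$voxel_size,
                           standardize = (transform == "spatial"),
                           seed_label = seed_label, transform = transform)
      },
      reho = {
        y <- bandpass_mat(detrend_mat(x[which(mask), , drop = FALSE]),
                          tr, 0.01, 0.08)
        standardize_masked(.reho_core(y, members), mask, grid, "ReHo",
                           template$voxel_size, TRUE)
      },
      falff = {
        y <- detrend_mat(as.matrix(S %*% x))
        standardize_masked(.falff_core(y, tr, c(0.01, 0.08), 1 / (2 * tr)),
                           mask, grid, "fALFF", template$voxel_size, TRUE)
      })
  }
  out
}
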