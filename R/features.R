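# Pairwise region-correlation features. The six DMN region pairs are kept
# in a fixed, non-lexicographic order (within-anterior pairs before the
# occipital pairs); this order is part of the on-disk feature format.

dmn_pairs <- function() {
  cbind(a = c(1L, 1L, 2L, 1L, 2L, 3L), b = c(2L, 3L, 3L, 4L, 4L, 4L))
}

feature_names <- function() {
  p <- dmn_pairs()
  sprintf("cc_%d_%d", p[, "a"], p[, "b"])
}

#' Region-mean time series
#'
#' Per-timepoint mean over all voxels carrying `label` in the template.
#'
#' @param series A [bold_series].
#' @param template A [labeled_atlas] / `labeled_template` on the same grid.
#' @param label Region label in 1..4.
#' @return Numeric vector of length `n_volumes(series)`.
#' @export
region_mean_series <- function(series, template, label) {
  stopifnot(inherits(series, "bold_series"),
            inherits(template, "labeled_atlas"))
  if (!identical(dim(template$labels), dim(series$data)[1:3])) {
    abort("template geometry does not match the series grid.")
  }
  idx <- label_indices(template, label)
  if (!length(idx)) abort(sprintf("label %s is empty in the template", label))
  colMeans(flatten_series(series$data)[idx, , drop = FALSE])
}

#' Pearson correlation of two time series
#'
#' The plain product-moment correlation
#' `cov(x, y) / sqrt(var(x) var(y))`, with explicit validation: equal
#' lengths of at least 3 and non-degenerate variance in both arguments.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 time points.")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite.")
  if (var(x) == 0 || var(y) == 0) {
    abort("correlation undefined for a zero-variance series")
  }
  cor(x, y)
}

#' Pairwise-correlation feature vector
#'
#' The six pairwise Pearson correlations among the four region-mean time
#' series, in the fixed pair order prefrontal-parietal,
#' prefrontal-temporal, parietal-temporal, prefrontal-occipital,
#' parietal-occipital, temporal-occipital.
#'
#' @inheritParams region_mean_series
#' @param subject_id Optional id stored in the output row.
#' @return One-row tibble: `subject_id`, `cc_1_2`, `cc_1_3`, `cc_2_3`,
#'   `cc_1_4`, `cc_2_4`, `cc_3_4`.
#' @export
feature_vector <- function(series, template, subject_id = NA_character_) {
  ts <- vapply(1:4, function(l) region_mean_series(series, template, l),
               numeric(n_volumes(series)))
  p <- dmn_pairs()
  cc <- vapply(seq_len(nrow(p)),
               function(i) pearson_cc(ts[, p[i, 1]], ts[, p[i, 2]]),
               numeric(1))
  out <- tibble(subject_id = subject_id)
  out[feature_names()] <- as.list(cc)
  out
}

#' Cohort feature table
#'
#' Computes the six-correlation feature vector for every subject of a
#' synthetic cohort under the FC preprocessing variant (volume discard,
#' smooth, detrend, band-pass). Two algebraically identical routes are
#' available: `"voxelwise"` materializes and preprocesses each 4D volume,
#' while `"projected"` (default) exploits the linearity of smoothing,
#' detrending and filtering -- region means of the smoothed volume equal
#' smoothed-indicator-weighted means of the raw volume, after which the
#' temporal steps act on four series instead of the whole grid. The two
#' routes agree to numerical precision and the projected route is orders of
#' magnitude faster.
#'
#' Subjects whose motion trace violates [motion_excluded()] are dropped;
#' their ids are kept in the `excluded` attribute of the result.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param template A [labeled_atlas] / `labeled_template` defining the ROIs.
#' @param n_discard Leading volumes to drop (default 10).
#' @param fwhm_mm,low_hz,high_hz FC-plan parameters (defaults 5 mm,
#'   0.01--0.08 Hz).
#' @param method `"projected"` (fast) or `"voxelwise"` (reference).
#' @param exclude_motion Apply the 2 mm / 2 degree exclusion rule?
#' @return Tibble with `subject_id`, `group`, `truth` and the six `cc_*`
#'   columns, one row per retained subject.
#' @export
cohort_features <- function(cohort, template, n_discard = 10, fwhm_mm = 5,
                            low_hz = 0.01, high_hz = 0.08,
                            method = c("projected", "voxelwise"),
                            exclude_motion = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(template, "labeled_atlas"))
  method <- match.arg(method)
  man <- cohort$manifest
  if (method == "projected") {
    W <- region_projection(template, fwhm_mm)
  }
  p <- dmn_pairs()
  rows <- vector("list", nrow(man))
  excluded <- character(0)
  for (i in seq_len(nrow(man))) {
    sub <- subject_data(cohort, man$subject_id[i])
    if (exclude_motion && motion_excluded(sub$motion)) {
      excluded <- c(excluded, man$subject_id[i])
      next
    }
    if (method == "projected") {
      x <- flatten_series(sub$series$data)[, -seq_len(n_discard), drop = FALSE]
      ts <- t(bandpass_mat(detrend_mat(W %*% x), cohort$spec$tr,
                           low_hz, high_hz))
      cc <- vapply(seq_len(nrow(p)),
                   function(k) pearson_cc(ts[, p[k, 1]], ts[, p[k, 2]]),
                   numeric(1))
      row <- tibble(subject_id = man$subject_id[i])
      row[feature_names()] <- as.list(cc)
    } else {
      s <- run_plan(discard_initial_volumes(sub$series, n_discard),
                    preproc_plan("fc", fwhm_mm = fwhm_mm, low_hz = low_hz,
                                 high_hz = high_hz))
      row <- feature_vector(s, template, man$subject_id[i])
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- tibble(subject_id = character(0), group = character(0),
                  truth = integer(0))
    out[feature_names()] <- lapply(feature_names(), function(x) numeric(0))
  } else {
    out <- dplyr::left_join(man[, c("subject_id", "group", "truth")],
                            bind_rows(rows), by = "subject_id")
    out <- out[!out$subject_id %in% excluded & !is.na(out$cc_1_2), ]
  }
  if (length(excluded)) {
    inform(sprintf("excluded %d subject(s) for head motion: %s",
                   length(excluded), paste(excluded, collapse = ", ")))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Read or write a feature table
#'
#' Tab-separated on-disk format with columns `subject_id` followed by the
#' six correlations in the fixed pair order (plus any extra columns, e.g.
#' `group` and `truth` for synthetic cohorts).
#'
#' @param features Feature tibble.
#' @param file Path to a TSV file.
#' @return `read_features_tsv()` returns a tibble.
#' @export
write_features_tsv <- function(features, file) {
  write.table(features, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(file) {
  as_tibble(read.delim(file, sep = "\t", stringsAsFactors = FALSE))
}
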