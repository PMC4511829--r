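# Structural-functional DMN template construction: per-subject ICA DMN maps
# -> group mean -> z-score -> z >= 2.0 binarization -> voxelwise product
# with the labeled structural atlas.

spatial_map <- function(values, voxel_size) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %s grid, range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

map_values <- function(m) if (inherits(m, "spatial_map")) m$values else m

#' Extract a subject's DMN component
#'
#' Runs spatial ICA ([fastica_decompose()]) on a (preprocessed) BOLD series
#' and returns the component whose absolute spatial map correlates best with
#' a binary reference mask (ties broken by larger in-mask mean). The map
#' sign is fixed so that its mean inside the reference is positive.
#'
#' With `combine = "best"` exactly one component is returned. Because ICA
#' prefers spatially sparse maps, a network whose regions are spatially
#' disjoint is often split across several near-equally matching components;
#' `combine = "sum"` (the default) therefore returns the sum of all
#' sign-aligned components whose match score reaches `match_frac` of the
#' best score. When a single component dominates the match, the two options
#' coincide.
#'
#' @param series A preprocessed [bold_series].
#' @param reference Binary 3D array (or [labeled_atlas], whose support is
#'   used) marking where the DMN is expected.
#' @param n_components ICA model order (default 20).
#' @param seed Integer seed (ICA initialization).
#' @param combine `"sum"` (default) or `"best"`; see Details.
#' @param match_frac Inclusion fraction for `combine = "sum"` (default 0.8).
#' @param ... Passed on to [fastica_decompose()].
#' @return A `spatial_map` with attributes `component` (selected indices)
#'   and `match` (their selection correlations).
#' @export
extract_subject_dmn <- function(series, reference, n_components = 20,
                                seed = 1, combine = c("sum", "best"),
                                match_frac = 0.8, ...) {
  combine <- match.arg(combine)
  stopifnot(inherits(series, "bold_series"))
  if (inherits(reference, "labeled_atlas")) reference <- reference$labels > 0
  ref <- as.numeric(reference != 0)
  if (!identical(dim(reference), dim(series$data)[1:3])) {
    abort("`reference` geometry does not match the series grid.")
  }
  if (sum(ref) == 0) abort("`reference` mask is empty.")
  n_components <- min(n_components, n_volumes(series) - 1L)
  ica <- fastica_decompose(t(flatten_series(series$data)), n_components,
                           seed = seed, ...)
  score <- apply(ica$S, 1, function(s) cor(abs(s), ref))
  in_mean <- apply(ica$S, 1, function(s) mean(s[ref == 1]))
  best <- order(-score, -abs(in_mean))[1]
  sel <- if (combine == "best") best
         else which(score >= match_frac * score[best])
  map <- rep(0, ncol(ica$S))
  for (k in sel) {
    map <- map + ica$S[k, ] * sign(mean(ica$S[k, ref == 1]))
  }
  out <- spatial_map(array(map, dim(reference)), series$voxel_size)
  attr(out, "component") <- sel
  attr(out, "match") <- score[sel]
  out
}

#' Template-construction primitives
#'
#' `group_mean_map()` averages subject maps voxelwise. `zscore_map()`
#' standardizes a map to mean 0 / sd 1 over a support mask (the whole grid
#' by default). `binarize_zmap()` keeps voxels with `z >= threshold`
#' (inclusive). `intersect_templates()` multiplies the structural label
#' field by the binary functional mask voxelwise, so structural labels
#' survive only inside the functional mask; it errors if any of the four
#' labels is lost entirely, since downstream feature extraction needs all
#' four ROIs.
#'
#' @param maps List of `spatial_map`s (or 3D arrays) on a common grid.
#' @return `group_mean_map()`: a `spatial_map`.
#' @export
group_mean_map <- function(maps) {
  vals <- lapply(maps, map_values)
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1)))) {
    abort("maps must share one grid geometry")
  }
  vs <- if (inherits(maps[[1]], "spatial_map")) maps[[1]]$voxel_size else c(2, 2, 2)
  spatial_map(Reduce(`+`, vals) / length(vals), vs)
}

#' @rdname group_mean_map
#' @param map A `spatial_map` or 3D array.
#' @param support Optional binary 3D array; statistics are computed over its
#'   voxels only (default: all voxels).
#' @return `zscore_map()`: a `spatial_map` with mean 0 and sd 1 over the
#'   support. Errors when the support values are constant.
#' @export
zscore_map <- function(map, support = NULL) {
  v <- map_values(map)
  sup <- if (is.null(support)) rep(TRUE, length(v)) else as.vector(support != 0)
  if (!any(sup)) abort("`support` is empty.")
  mu <- mean(v[sup]); s <- sd(v[sup])
  if (!is.finite(s) || s == 0) {
    abort("map is constant over the support; z-scoring is undefined")
  }
  vs <- if (inherits(map, "spatial_map")) map$voxel_size else c(2, 2, 2)
  spatial_map(array((v - mu) / s, dim(map_values(map))), vs)
}

#' @rdname group_mean_map
#' @param zmap A z-scored `spatial_map` (or 3D array).
#' @param threshold Inclusive z threshold (default 2.0).
#' @return `binarize_zmap()`: an integer 3D array with 1 where
#'   `z >= threshold`.
#' @export
binarize_zmap <- function(zmap, threshold = 2) {
  v <- map_values(zmap)
  mask <- array(as.integer(v >= threshold), dim(v))
  if (!any(mask == 1L)) {
    warn(sprintf("no voxel reaches z >= %g; the functional mask is empty",
                 threshold))
  }
  mask
}

#' @rdname group_mean_map
#' @param structural A [labeled_atlas].
#' @param functional Binary 3D array (the thresholded functional mask).
#' @return `intersect_templates()`: a `labeled_template` (inherits
#'   `labeled_atlas`).
#' @export
intersect_templates <- function(structural, functional) {
  stopifnot(inherits(structural, "labeled_atlas"))
  functional <- map_values(functional)
  if (!identical(dim(structural$labels), dim(functional))) {
    abort("structural and functional templates have different geometries.")
  }
  labels <- structural$labels * as.integer(functional != 0)
  lost <- setdiff(1:4, unique(labels[labels > 0]))
  if (length(lost)) {
    abort(sprintf("label(s) %s (%s) lost in the structural-functional intersection",
                  paste(lost, collapse = ", "),
                  paste(region_names()[lost], collapse = ", ")))
  }
  structure(list(labels = labels, voxel_size = structural$voxel_size),
            class = c("labeled_template", "labeled_atlas"))
}

#' Build the labeled structural-functional DMN template
#'
#' Full template pipeline over a healthy cohort: per-subject preprocessing
#' (volume discard + the FC plan), ICA DMN extraction against the atlas
#' support, group mean, z-scoring, inclusive z >= `z_threshold`
#' binarization, and intersection with the structural atlas.
#'
#' @param cohort A [simulate_cohort()] result (healthy subjects are used),
#'   or a list of ready [bold_series].
#' @param atlas The structural [labeled_atlas].
#' @param subjects Optional subject ids to use (default: all healthy
#'   subjects in the manifest, or all list elements).
#' @param n_components ICA model order (default 20).
#' @param z_threshold Binarization threshold (default 2.0).
#' @param n_discard Leading volumes to drop (default 10; cohort input only).
#' @param seed Integer seed driving the per-subject ICA seeds.
#' @return List of class `dmn_template_fit`: `template`
#'   (`labeled_template`), `zmap`, `functional_mask`, and `selection`
#'   (tibble of per-subject chosen components and match scores).
#' @export
build_dmn_template <- function(cohort, atlas, subjects = NULL,
                               n_components = 20, z_threshold = 2,
                               n_discard = 10, seed = 1) {
  if (inherits(cohort, "synthetic_cohort")) {
    man <- cohort$manifest
    ids <- subjects %||% man$subject_id[man$truth == 1L]
    get_series <- function(i) {
      s <- subject_data(cohort, ids[i])$series
      run_plan(discard_initial_volumes(s, n_discard), "fc")
    }
    n <- length(ids)
  } else {
    ids <- subjects %||% sprintf("S%03d", seq_along(cohort))
    get_series <- function(i) cohort[[i]]
    n <- length(cohort)
  }
  if (n < 1L) abort("no subjects available for template construction")
  maps <- vector("list", n)
  comp <- integer(n); match_r <- numeric(n)
  for (i in seq_len(n)) {
    m <- extract_subject_dmn(get_series(i), atlas,
                             n_components = n_components,
                             seed = derive_seed(seed, i))
    comp[i] <- length(attr(m, "component"))
    match_r[i] <- max(attr(m, "match"))
    maps[[i]] <- m
  }
  zmap <- zscore_map(group_mean_map(maps))
  fmask <- binarize_zmap(zmap, z_threshold)
  template <- intersect_templates(atlas, fmask)
  structure(list(template = template, zmap = zmap, functional_mask = fmask,
                 selection = tibble(subject_id = ids, n_components = comp,
                                    best_match = match_r)),
            class = "dmn_template_fit")
}

#' Dice overlap between two binary masks
#'
#' @param a,b Binary 3D arrays (or label fields; nonzero = in mask).
#' @return Dice coefficient `2|A&B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(a, b) {
  a <- map_values(a) != 0; b <- map_values(b) != 0
  if (!identical(dim(a), dim(b))) abort("masks have different geometries")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NaN)
  2 * sum(a & b) / denom
}
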