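# Voxelwise pooled-variance two-sample t-test and cluster-extent
# thresholding of the resulting statistic field.

maps_to_matrix <- function(maps, mask) {
  idx <- which(mask)
  do.call(cbind, lapply(maps, function(m) {
    v <- map_values(m)
    if (!identical(dim(v), dim(mask))) abort("map geometry mismatch")
    v[idx]
  }))
}

#' Voxelwise two-sample t-test (pooled variance)
#'
#' For each mask voxel,
#' `T = (m1 - m2) / sqrt(((s1^2 (n1-1) + s2^2 (n2-1)) / (n1+n2-2)) * (1/n1 + 1/n2))`
#' with unbiased sample variances; group 1 first, so a negative T means
#' group 1 below group 2. Voxels with zero pooled variance get T = 0 (with
#' a message). A Welch-type unequal-variance denominator is available
#' behind `welch = TRUE` for sensitivity analyses.
#'
#' @param group1,group2 Lists of `biomarker_map`s (or 3D arrays) on a
#'   common grid; both groups need at least 2 members.
#' @param mask Binary 3D array; default: the first map's mask, else all
#'   finite voxels.
#' @param welch Use the unequal-variance denominator (default `FALSE`).
#' @return A `stat_map`: 3D `values` (NA off-mask), `mask`, `n1`, `n2`,
#'   `voxel_size`.
#' @export
two_sample_t <- function(group1, group2, mask = NULL, welch = FALSE) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) abort("both groups need at least 2 maps")
  if (is.null(mask)) {
    mask <- if (inherits(group1[[1]], "biomarker_map")) group1[[1]]$mask
            else is.finite(map_values(group1[[1]]))
  }
  mask <- mask != 0
  x1 <- maps_to_matrix(group1, mask)
  x2 <- maps_to_matrix(group2, mask)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    se <- sqrt((v1 * (n1 - 1) + v2 * (n2 - 1)) / (n1 + n2 - 2) *
                 (1 / n1 + 1 / n2))
  }
  tval <- ifelse(se > 0, (m1 - m2) / se, 0)
  if (any(se == 0)) {
    inform(sprintf("%d voxel(s) with zero pooled variance set to T = 0",
                   sum(se == 0)))
  }
  vals <- array(NA_real_, dim(mask))
  vals[mask] <- tval
  vs <- if (inherits(group1[[1]], "biomarker_map")) group1[[1]]$voxel_size
        else c(2, 2, 2)
  structure(list(values = vals, mask = mask, n1 = n1, n2 = n2,
                 voxel_size = vs),
            class = c("stat_map", "spatial_map"))
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s grid, n1 = %d vs n2 = %d, |T| max = %.3f\n",
              paste(dim(x$values), collapse = "x"), x$n1, x$n2,
              max(abs(x$values), na.rm = TRUE)))
  invisible(x)
}

# connected components of a logical 3D array, via igraph
connected_components <- function(supra, connectivity) {
  vox <- which(supra, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0L) return(list())
  grid <- dim(supra)
  pos <- array(0L, grid)
  pos[supra] <- seq_len(n)
  offs <- neighbourhood_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid[3]
    id <- rep(0L, n)
    id[ok] <- pos[nb[ok, , drop = FALSE]]
    hit <- id > 0L
    edges[[o]] <- cbind(which(hit), id[hit])
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(rbind(e, cbind(seq_len(n), seq_len(n))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(k) {
    linear <- which(supra)[comp == k]
    linear
  })
}

#' Cluster-extent thresholding
#'
#' Keeps connected groups of supra-threshold voxels (`|T| > t_thresh`,
#' strict) whose volume reaches `min_volume_mm3`. Positive and negative
#' voxels are clustered separately; with 2 mm isotropic voxels the default
#' 784 mm3 floor corresponds to 98 voxels. Peak coordinates are reported
#' both on the grid and in grid-centred mm.
#'
#' @param tmap A `stat_map` from [two_sample_t()].
#' @param t_thresh Statistic threshold (default 2.1, strict inequality).
#' @param min_volume_mm3 Minimum cluster volume (default 784).
#' @param connectivity Neighbourhood definition: 26 (default), 18 or 6.
#' @return A `cluster_result`: `clusters` tibble sorted by size
#'   (cluster_id, sign, n_voxels, volume_mm3, peak grid / mm coordinates,
#'   peak_t) and `map`, the t-field restricted to surviving clusters (0
#'   elsewhere in the mask).
#' @export
cluster_threshold <- function(tmap, t_thresh = 2.1, min_volume_mm3 = 784,
                              connectivity = 26) {
  stopifnot(inherits(tmap, "stat_map"))
  if (t_thresh <= 0 || min_volume_mm3 <= 0) {
    abort("thresholds must be positive")
  }
  vol_vox <- prod(tmap$voxel_size)
  grid <- dim(tmap$values)
  vals <- tmap$values
  keep <- array(0, grid)
  keep[tmap$mask] <- 0
  recs <- list()
  for (sgn in c(1, -1)) {
    supra <- !is.na(vals) & (sgn * vals > t_thresh)
    for (comp in connected_components(supra, connectivity)) {
      volume <- length(comp) * vol_vox
      if (volume < min_volume_mm3) next
      pk <- comp[which.max(sgn * vals[comp])]
      co <- arrayInd(pk, grid)
      recs[[length(recs) + 1L]] <- tibble(
        sign = if (sgn > 0) "increase" else "decrease",
        n_voxels = length(comp), volume_mm3 = volume,
        peak_x = co[1], peak_y = co[2], peak_z = co[3],
        peak_x_mm = (co[1] - (grid[1] + 1) / 2) * tmap$voxel_size[1],
        peak_y_mm = (co[2] - (grid[2] + 1) / 2) * tmap$voxel_size[2],
        peak_z_mm = (co[3] - (grid[3] + 1) / 2) * tmap$voxel_size[3],
        peak_t = vals[pk])
      keep[comp] <- vals[comp]
    }
  }
  clusters <- if (length(recs)) {
    out <- arrange(bind_rows(recs), desc(n_voxels))
    mutate(out, cluster_id = dplyr::row_number(), .before = 1)
  } else {
    tibble(cluster_id = integer(0), sign = character(0),
           n_voxels = integer(0), volume_mm3 = numeric(0),
           peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
           peak_x_mm = numeric(0), peak_y_mm = numeric(0),
           peak_z_mm = numeric(0), peak_t = numeric(0))
  }
  keep[!tmap$mask] <- NA_real_
  structure(list(clusters = clusters, map = keep, t_thresh = t_thresh,
                 min_volume_mm3 = min_volume_mm3,
                 connectivity = connectivity, voxel_size = tmap$voxel_size),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> |T| > %g, >= %g mm3: %d surviving cluster(s)\n",
              x$t_thresh, x$min_volume_mm3, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Compare biomarker maps between groups
#'
#' Runs the voxelwise pooled two-sample t-test (sub-healthy group first, so
#' decreases appear as negative T) followed by cluster-extent thresholding,
#' and annotates each surviving cluster with its overlap fractions against
#' the four template regions.
#'
#' @param maps List of per-subject `biomarker_map`s (one kind).
#' @param truth Vector of class labels aligned with `maps`: -1 = sub-healthy
#'   (group 1), +1 = healthy control (group 2).
#' @param template Optional `labeled_template` for region-overlap columns.
#' @param t_thresh,min_volume_mm3,connectivity See [cluster_threshold()].
#' @param welch See [two_sample_t()].
#' @return A `group_comparison`: `tmap`, `result` (a `cluster_result`), and
#'   the annotated `clusters` tibble.
#' @export
compare_groups <- function(maps, truth, template = NULL, t_thresh = 2.1,
                           min_volume_mm3 = 784, connectivity = 26,
                           welch = FALSE) {
  if (length(maps) != length(truth)) abort("`maps` and `truth` length mismatch")
  if (!all(truth %in% c(-1, 1))) abort("`truth` must contain only +1 / -1")
  tmap <- two_sample_t(maps[truth == -1], maps[truth == 1], welch = welch)
  res <- cluster_threshold(tmap, t_thresh, min_volume_mm3, connectivity)
  clusters <- res$clusters
  if (!is.null(template) && nrow(clusters)) {
    grid <- dim(tmap$values)
    surv <- res$map
    fracs <- matrix(0, nrow(clusters), 4)
    # recompute per-cluster membership from the surviving map by sign/peak
    for (i in seq_len(nrow(clusters))) {
      sgn <- if (clusters$sign[i] == "increase") 1 else -1
      supra <- !is.na(surv) & (sgn * surv > res$t_thresh)
      comps <- connected_components(supra, connectivity)
      pk <- clusters$peak_x[i] + (clusters$peak_y[i] - 1) * grid[1] +
        (clusters$peak_z[i] - 1) * grid[1] * grid[2]
      comp <- comps[[which(vapply(comps, function(cm) pk %in% cm,
                                  logical(1)))[1]]]
      fracs[i, ] <- vapply(1:4, function(l) {
        mean(template$labels[comp] == l)
      }, numeric(1))
    }
    colnames(fracs) <- paste0("frac_", region_names())
    clusters <- dplyr::bind_cols(clusters, as_tibble(fracs))
  }
  structure(list(tmap = tmap, result = res, clusters = clusters),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d vs %d subjects\n", x$tmap$n1, x$tmap$n2))
  print(x$result)
  invisible(x)
}
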