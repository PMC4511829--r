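# broom-style accessors for fitted objects.

#' Tidy the two-fold SVM iteration history
#'
#' One row per training round: the one-class bootstrap (round 0, `par1` =
#' nu, `par2` = gamma) and each two-class refinement round (`par1` = cost,
#' `par2` = gamma, `cv_score` = cross-validated accuracy), with the running
#' negative-set size.
#'
#' @param x A `tfsvm` model.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tfsvm
#' @export
tidy.tfsvm <- function(x, ...) {
  x$iteration_log
}

#' One-row summary of a two-fold SVM model
#'
#' @param x A `tfsvm` model.
#' @param ... Unused.
#' @return Tibble with the selected hyperparameters, number of refinement
#'   rounds, and final negative-set size.
#' @method glance tfsvm
#' @export
glance.tfsvm <- function(x, ...) {
  tibble(
    ocsvm_nu = x$ocsvm$nu, ocsvm_gamma = x$ocsvm$gamma,
    tcsvm_cost = if (is.null(x$tcsvm)) NA_real_ else x$tcsvm$cost,
    tcsvm_gamma = if (is.null(x$tcsvm)) NA_real_ else x$tcsvm$gamma,
    n_rounds = max(x$iteration_log$round),
    n_negative = length(x$negative_ids)
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return The annotated cluster tibble (one row per surviving cluster).
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  x$clusters
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(n1 = x$tmap$n1, n2 = x$tmap$n2,
         n_clusters = nrow(x$clusters),
         n_decrease = sum(x$clusters$sign == "decrease"),
         n_increase = sum(x$clusters$sign == "increase"),
         t_thresh = x$result$t_thresh,
         min_volume_mm3 = x$result$min_volume_mm3)
}
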