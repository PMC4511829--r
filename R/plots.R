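# ggplot2 graphics for feature tables, fitted classifiers and maps.

#' Boxplots of the six pairwise region correlations
#'
#' Distribution of each feature (pair order prefrontal-parietal, ...,
#' temporal-occipital) per group, the standard way to eyeball the lowered
#' inter-region connectivity of sub-healthy subjects.
#'
#' @param features Feature tibble from [cohort_features()] (needs the six
#'   `cc_*` columns and a grouping column).
#' @param group Name of the grouping column (default `"group"`).
#' @return A ggplot.
#' @export
plot_cc_distributions <- function(features, group = "group") {
  long <- tidyr::pivot_longer(features, dplyr::all_of(feature_names()),
                              names_to = "pair", values_to = "cc")
  long$pair <- factor(long$pair, levels = feature_names())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$cc,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "DMN region pair", y = "Pearson correlation",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot tfsvm
#' @export
autoplot.tfsvm <- function(object, ...) {
  log <- object$iteration_log
  ggplot2::ggplot(log, ggplot2::aes(x = .data$round,
                                    y = .data$n_negative_total)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 2) +
    ggplot2::scale_x_continuous(breaks = log$round) +
    ggplot2::labs(x = "training round", y = "accumulated negatives",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

slice_tibble <- function(values, slices) {
  d <- dim(values)
  slices <- slices %||% unique(round(seq(1, d[3], length.out = min(6, d[3]))))
  bind_rows(lapply(slices, function(z) {
    tibble(x = rep(seq_len(d[1]), d[2]),
           y = rep(seq_len(d[2]), each = d[1]),
           z = z, value = as.vector(values[, , z]))
  }))
}

#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, slices = NULL, ...) {
  df <- slice_tibble(object$values, slices)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90",
                                  high = "red", na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "T") +
    ggplot2::theme_minimal()
}

#' @method autoplot biomarker_map
#' @export
autoplot.biomarker_map <- function(object, slices = NULL, ...) {
  df <- slice_tibble(object$values, slices)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = object$kind) +
    ggplot2::theme_minimal()
}
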