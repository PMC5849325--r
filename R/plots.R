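# ggplot2 views of the result objects ------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_col geom_line
#'   geom_point geom_abline facet_wrap labs coord_flip theme_minimal
NULL

#' Distributions of fitness and effective-feature count
#'
#' @param object An `lgp_models` tibble.
#' @param ... Unused.
#' @return A ggplot: histograms of held-out MCE and per-model effective
#'   feature counts.
#' @method autoplot lgp_models
#' @export
autoplot.lgp_models <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "mce", "n_features_effective"),
    dplyr::everything(), names_to = "metric", values_to = "value"
  )
  ggplot(long, aes(x = .data$value)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    facet_wrap(~metric, scales = "free") +
    labs(x = NULL, y = "models",
         title = "Best-model fitness and effective-feature counts") +
    theme_minimal()
}

#' Top-k occurrence bar chart
#'
#' @param object An `lgp_occurrence`.
#' @param k Number of entries.
#' @param which `"features"` or `"pairs"`.
#' @param ... Unused.
#' @return A ggplot bar chart of occurrence frequencies.
#' @method autoplot lgp_occurrence
#' @export
autoplot.lgp_occurrence <- function(object, k = 20,
                                    which = c("features", "pairs"), ...) {
  which <- match.arg(which)
  tb <- top_k(object, k, which)
  if (which == "pairs") {
    tb$feature <- paste(tb$feature_a, tb$feature_b, sep = " & ")
  }
  tb$feature <- factor(tb$feature, levels = rev(tb$feature))
  ggplot(tb, aes(x = .data$feature, y = .data$frequency)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "occurrence frequency",
         title = sprintf("Top %d most common %s", nrow(tb), which)) +
    theme_minimal()
}

#' Degree distribution of a synergy network
#'
#' @param object A `synergy_network`.
#' @param ... Unused.
#' @return A ggplot of the degree histogram.
#' @method autoplot synergy_network
#' @export
autoplot.synergy_network <- function(object, ...) {
  dd <- degree_distribution_net(object)
  ggplot(dd$histogram, aes(x = .data$degree, y = .data$n_vertices)) +
    geom_col(fill = "steelblue") +
    labs(x = "degree", y = "vertices",
         title = "Synergy-network degree distribution") +
    theme_minimal()
}

#' ROC curve plot
#'
#' @param roc A tibble from [roc_points()], or a `roc` list-column entry of
#'   an `lgp_models` tibble.
#' @param auc Optional AUC to print in the title.
#' @return A ggplot ROC curve with the chance diagonal.
#' @export
plot_roc <- function(roc, auc = NULL) {
  ttl <- if (is.null(auc)) "ROC curve" else
    sprintf("ROC curve (AUC = %.3f)", auc)
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "steelblue") +
    geom_point(size = 0.8, colour = "steelblue") +
    labs(x = "false positive rate", y = "true positive rate", title = ttl) +
    theme_minimal()
}
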