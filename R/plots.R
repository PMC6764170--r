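#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_boxplot
#'   geom_jitter facet_wrap labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `vf_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vf_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#2166ac", linewidth = 0.8) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Plot per-fold accuracies of a cross-validation run
#'
#' @param object A `vf_cv` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot: per-repeat accuracy distribution.
#' @export
autoplot.vf_cv <- function(object, ...) {
  ggplot(object$folds,
         aes(x = factor(.data$repeat_id), y = .data$accuracy)) +
    geom_boxplot(fill = "#d1e5f0") +
    labs(x = "CV repeat", y = "Held-out accuracy (%)",
         title = sprintf("%s on %s features", object$config$algorithm,
                         object$config$feature_set)) +
    theme_minimal()
}

#' Compare feature distributions between groups
#'
#' Boxplots of each feature by group label, faceted with free scales --
#' the visual counterpart of [compare_feature_groups()].
#'
#' @param features A feature table from [extract_features()].
#' @param which Feature columns to show (default: all present).
#' @return A ggplot.
#' @export
plot_feature_comparison <- function(features, which = NULL) {
  cols <- which %||% intersect(c(hrv_feature_names(), qrs_feature_names()),
                               names(features))
  long <- tidyr::pivot_longer(features[, c("label", cols)],
                              cols = dplyr::all_of(cols),
                              names_to = "feature", values_to = "value")
  ggplot(long, aes(x = .data$label, y = .data$value, fill = .data$label)) +
    geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Compare algorithm accuracies across feature sets
#'
#' @param experiments A named list of `vf_cv` objects (e.g.
#'   `vf_run$experiments`).
#' @return A ggplot of per-fold accuracies by algorithm and feature set.
#' @export
plot_algorithm_comparison <- function(experiments) {
  folds <- dplyr::bind_rows(lapply(experiments, function(e) e$folds))
  ggplot(folds, aes(x = .data$algorithm, y = .data$accuracy,
                    fill = .data$feature_set)) +
    geom_boxplot(position = "dodge", outlier.size = 0.6) +
    labs(x = NULL, y = "Held-out accuracy (%)", fill = "Feature set") +
    theme_minimal()
}
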