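#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-fold metrics of a cross-validation run
#'
#' @param x A `vf_cv` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble with one row per (repeat, fold): algorithm, feature
#'   set, sensitivity, specificity, accuracy, and the per-repeat AUC joined
#'   on.
#' @export
tidy.vf_cv <- function(x, ...) {
  dplyr::left_join(x$folds, x$aucs,
                   by = c("algorithm", "feature_set", "repeat_id"))
}

#' One-row summary of a cross-validation run
#'
#' @param x A `vf_cv` from [run_experiment()].
#' @param ... Unused.
#' @return A one-row tibble: mean/SD accuracy, mean sensitivity and
#'   specificity, mean AUC.
#' @export
glance.vf_cv <- function(x, ...) {
  tibble(
    algorithm = x$config$algorithm,
    feature_set = x$config$feature_set,
    n_features = length(feature_set_columns(x$config$feature_set)),
    mean_accuracy = mean(x$folds$accuracy),
    sd_accuracy = sd(x$folds$accuracy),
    mean_sensitivity = mean(x$folds$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$folds$specificity, na.rm = TRUE),
    mean_auc = mean(x$aucs$auc),
    k = x$config$k, repeats = x$config$repeats, n = x$config$n
  )
}

#' Tidy a trained network's weights
#'
#' @param x A `vf_ann` from [ann_train()].
#' @param ... Unused.
#' @return A long tibble: `layer`, `from`, `to`, `weight` (biases have
#'   `from = "bias"`).
#' @export
tidy.vf_ann <- function(x, ...) {
  w1 <- tibble(layer = "hidden",
               from = rep(rownames(x$W1) %||% paste0("x", seq_len(nrow(x$W1))),
                          ncol(x$W1)),
               to = rep(paste0("h", seq_len(ncol(x$W1))), each = nrow(x$W1)),
               weight = as.numeric(x$W1))
  b1 <- tibble(layer = "hidden", from = "bias",
               to = paste0("h", seq_along(x$b1)), weight = x$b1)
  w2 <- tibble(layer = "output", from = paste0("h", seq_len(nrow(x$W2))),
               to = "y", weight = as.numeric(x$W2))
  b2 <- tibble(layer = "output", from = "bias", to = "y", weight = x$b2)
  dplyr::bind_rows(w1, b1, w2, b2)
}

#' One-row summary of a trained network
#'
#' @param x A `vf_ann`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, final and initial training
#'   loss, epochs.
#' @export
glance.vf_ann <- function(x, ...) {
  tibble(n_inputs = nrow(x$W1), n_hidden = ncol(x$W1),
         epochs = x$config$epochs,
         initial_loss = x$loss_history[1],
         final_loss = tail(x$loss_history, 1))
}

#' @export
tidy.vf_roc <- function(x, ...) x$points

#' @export
glance.vf_roc <- function(x, ...) tibble(auc = x$auc)

#' @export
tidy.vf_anova <- function(x, ...) x$tukey

#' @export
glance.vf_anova <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df_between = x$df[1],
         df_within = x$df[2], p_value = x$p_value)
}
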