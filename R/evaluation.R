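#' Repeated (stratified) k-fold assignments
#'
#' For each repeat, partitions the samples into `k` folds whose sizes
#' differ by at most one. By default the split is stratified: each class is
#' dealt to folds so the 27/28-style balance is preserved; class remainders
#' go to the currently smallest folds (ties broken at random), which keeps
#' overall fold sizes within one of each other. When a class has fewer
#' members than `k`, stratification falls back to a plain shuffle with a
#' warning.
#'
#' @param labels Vector of class labels, one per sample.
#' @param k Folds per repeat (default 10).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed; assignments are reproducible.
#' @param stratified Stratify by class (default `TRUE`).
#' @return A tibble with columns `repeat_id`, `sample`, `fold`.
#' @export
#' @examples
#' f <- make_folds(rep(c("VF", "control"), c(27, 28)), seed = 1)
#' table(f$fold[f$repeat_id == 1])
make_folds <- function(labels, k = 10, repeats = 10, seed = 1,
                       stratified = TRUE) {
  n <- length(labels)
  if (n < k) {
    abort(sprintf("Cannot split %d samples into %d folds.", n, k),
          class = "vf_invalid_parameter")
  }
  if (stratified && any(table(labels) < k)) {
    warn("A class has fewer members than `k`; using non-stratified folds.")
    stratified <- FALSE
  }
  with_seed(seed, {
    out <- lapply(seq_len(repeats), function(r) {
      fold <- integer(n)
      if (!stratified) {
        sizes <- rep(n %/% k, k)
        extra <- sample.int(k, n %% k)
        sizes[extra] <- sizes[extra] + 1L
        fold[sample.int(n)] <- rep(seq_len(k), times = sizes)
      } else {
        totals <- integer(k)
        for (cl in sample(unique(as.character(labels)))) {
          idx <- sample(which(labels == cl))
          base <- length(idx) %/% k
          rem <- length(idx) %% k
          counts <- rep(base, k)
          if (rem > 0) {
            # remainders to the smallest folds so far (random among ties)
            ord <- order(totals + runif(k) * 1e-9)
            counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
          }
          fold[idx] <- rep(seq_len(k), times = counts)
          totals <- totals + counts
        }
      }
      tibble(repeat_id = r, sample = seq_len(n), fold = fold)
    })
    dplyr::bind_rows(out)
  })
}

#' Sensitivity, specificity and accuracy of a prediction set
#'
#' VF is the positive class: sensitivity = 100 TP / (TP + FN),
#' specificity = 100 TN / (TN + FP), accuracy = 100 (TP + TN) / n.
#' When the truth contains no positives, sensitivity is `NA` with a
#' warning (and symmetrically for specificity).
#'
#' @param predictions,truth Label vectors of equal length
#'   (`VF`/`control`).
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `accuracy` (percent).
#' @export
#' @examples
#' confusion_metrics(rep(c("VF", "control"), c(9, 11)),
#'                   rep(c("VF", "control"), c(10, 10)))
confusion_metrics <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    abort("`predictions` and `truth` must have the same length.",
          class = "vf_contract_error")
  }
  p <- as.character(predictions) == "VF"
  y <- as.character(truth) == "VF"
  tp <- sum(p & y); fn <- sum(!p & y)
  tn <- sum(!p & !y); fp <- sum(p & !y)
  sens <- if (tp + fn == 0) {
    warn("No positive cases in truth; sensitivity undefined.")
    NA_real_
  } else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warn("No negative cases in truth; specificity undefined.")
    NA_real_
  } else 100 * tn / (tn + fp)
  tibble(sensitivity = sens, specificity = spec,
         accuracy = 100 * (tp + tn) / length(y))
}

#' ROC curve and AUC of a score set
#'
#' Sweeps every threshold over the scores (VF = positive class), builds the
#' ROC polyline and integrates it with the trapezoidal rule. Tied scores
#' are handled as a single threshold step, so the AUC equals the rank-based
#' (Mann-Whitney) statistic exactly.
#'
#' @param scores Numeric scores, higher = more VF-like.
#' @param truth Labels (`VF`/`control`); both classes must be present.
#' @return An object of class `vf_roc`: `auc` and a tibble `points`
#'   (`threshold`, `fpr`, `tpr`).
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c("control", "control", "VF", "VF"))$auc
roc_auc <- function(scores, truth) {
  y <- as.character(truth) == "VF"
  if (!any(y) || all(y)) {
    abort("Both classes must be present to compute a ROC curve.",
          class = "vf_invalid_parameter")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # collapse tied scores into single steps
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(yy)[last_of_tie]
  fp <- cumsum(!yy)[last_of_tie]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(!y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(
    list(auc = auc,
         points = tibble(threshold = c(Inf, s[last_of_tie]),
                         fpr = fpr, tpr = tpr)),
    class = "vf_roc"
  )
}

#' @export
print.vf_roc <- function(x, ...) {
  cat(sprintf("<vf_roc> AUC = %.4f (%d points)\n", x$auc, nrow(x$points)))
  invisible(x)
}

# Feature-set column selectors.
feature_set_columns <- function(feature_set = c("hrv", "qrs", "combined")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
    hrv = hrv_feature_names(),
    qrs = qrs_feature_names(),
    combined = c(hrv_feature_names(), qrs_feature_names())
  )
}

#' Run a repeated cross-validated prediction experiment
#'
#' The full evaluation loop for one feature set and one algorithm:
#' repeated stratified 10-fold cross-validation in which, per fold, the
#' standardizer is fit on the 9 training folds only (set
#' `scaler_scope = "global"` for the all-data variant), the classifier is
#' trained on the standardized training folds and evaluated on the held-out
#' fold. Per-fold sensitivity/specificity/accuracy are recorded; per
#' repeat, the held-out scores are pooled into one ROC/AUC.
#'
#' @param features A feature table: tibble with `record_id`, `label` and
#'   feature columns (from [extract_features()]).
#' @param feature_set `"hrv"` (11 features), `"qrs"` (4) or `"combined"`
#'   (15).
#' @param algorithm See [fit_classifier()].
#' @param k,repeats,seed,stratified Cross-validation settings, see
#'   [make_folds()].
#' @param scaler_scope `"fold"` (default) or `"global"`.
#' @param threshold Decision threshold for [predict_label()].
#' @param ... Passed to [fit_classifier()].
#' @return An object of class `vf_cv`: per-fold metrics (`folds`),
#'   per-repeat AUC (`aucs`), pooled scores and the run configuration. Use
#'   [tidy()] / [glance()] / [autoplot()] on it.
#' @export
run_experiment <- function(features, feature_set = "hrv", algorithm = "ANN",
                           k = 10, repeats = 10, seed = 1, stratified = TRUE,
                           scaler_scope = c("fold", "global"),
                           threshold = 0.5, ...) {
  scaler_scope <- match.arg(scaler_scope)
  cols <- feature_set_columns(feature_set)
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("Feature table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "vf_contract_error")
  }
  xm <- as.matrix(features[, cols])
  if (anyNA(xm)) {
    abort("Feature table contains missing values.",
          class = "vf_contract_error")
  }
  labels <- as.character(features$label)
  folds <- make_folds(labels, k = k, repeats = repeats, seed = seed,
                      stratified = stratified)
  global_sc <- if (scaler_scope == "global") fit_standardizer(xm) else NULL

  fold_rows <- list()
  auc_rows <- list()
  score_rows <- list()
  for (r in seq_len(repeats)) {
    fr <- folds[folds$repeat_id == r, ]
    rep_scores <- numeric(nrow(xm))
    for (f in sort(unique(fr$fold))) {
      test_idx <- fr$sample[fr$fold == f]
      train_idx <- setdiff(seq_len(nrow(xm)), test_idx)
      sc <- global_sc %||% fit_standardizer(xm[train_idx, , drop = FALSE])
      xtr <- apply_standardizer(sc, xm[train_idx, , drop = FALSE])
      xte <- apply_standardizer(sc, xm[test_idx, , drop = FALSE])
      clf <- tryCatch(
        fit_classifier(xtr, labels[train_idx], algorithm = algorithm,
                       seed = seed + 1000L * r + f, ...),
        error = function(e) {
          abort(sprintf("repeat %d fold %d: %s", r, f, conditionMessage(e)),
                parent = e)
        }
      )
      prob <- predict_prob(clf, xte)
      rep_scores[test_idx] <- prob
      cm <- confusion_metrics(predict_label(prob, threshold),
                              labels[test_idx])
      fold_rows[[length(fold_rows) + 1L]] <-
        dplyr::bind_cols(tibble(algorithm = algorithm,
                                feature_set = feature_set,
                                repeat_id = r, fold = f), cm)
    }
    auc_rows[[r]] <- tibble(algorithm = algorithm, feature_set = feature_set,
                            repeat_id = r,
                            auc = roc_auc(rep_scores, labels)$auc)
    score_rows[[r]] <- tibble(repeat_id = r, sample = seq_len(nrow(xm)),
                              label = labels, score = rep_scores)
  }
  structure(
    list(folds = dplyr::bind_rows(fold_rows),
         aucs = dplyr::bind_rows(auc_rows),
         scores = dplyr::bind_rows(score_rows),
         config = list(feature_set = feature_set, algorithm = algorithm,
                       k = k, repeats = repeats, seed = seed,
                       stratified = stratified, scaler_scope = scaler_scope,
                       threshold = threshold,
                       n = nrow(xm))),
    class = "vf_cv"
  )
}

#' @export
print.vf_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<vf_cv> %s on %s-%d: accuracy %.1f +/- %.1f %%, AUC %.3f (%dx%d-fold CV, n = %d)\n",
    x$config$algorithm, x$config$feature_set,
    length(feature_set_columns(x$config$feature_set)),
    g$mean_accuracy, g$sd_accuracy, g$mean_auc,
    x$config$repeats, x$config$k, x$config$n))
  invisible(x)
}

#' Welch two-sample two-tailed t-test between groups
#'
#' Unequal-variance (Welch) by default; `var_equal = TRUE` gives the pooled
#' Student variant. Degenerate inputs where both groups are constant are
#' resolved by convention: equal means give t = 0, p = 1; unequal constant
#' means give p = 0.
#'
#' @param x,y Numeric samples (each >= 2 values).
#' @param var_equal Pooled-variance variant (default `FALSE`).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' compare_groups_ttest(rnorm(20), rnorm(20, 2))
compare_groups_ttest <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least 2 values.",
          class = "vf_insufficient_data")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(statistic = 0, df = length(x) + length(y) - 2,
                    p_value = 1))
    }
    return(tibble(statistic = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p_value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' One-way ANOVA over algorithm accuracies with Tukey HSD
#'
#' Balanced one-way ANOVA of the per-(repeat, fold) accuracies across
#' algorithms, followed by Tukey's honestly-significant-difference pairwise
#' comparisons.
#'
#' @param accuracies A data frame with columns `algorithm` and `accuracy`
#'   (equal replicate counts per algorithm), e.g. stacked `folds` tables of
#'   several [run_experiment()] results.
#' @return A list of class `vf_anova`: `f_statistic`, `df` (c(between,
#'   within)), `p_value`, and `tukey`, a tibble of pairwise differences
#'   with adjusted p-values.
#' @export
compare_algorithms_anova <- function(accuracies) {
  if (!all(c("algorithm", "accuracy") %in% names(accuracies))) {
    abort("Need columns `algorithm` and `accuracy`.",
          class = "vf_contract_error")
  }
  counts <- table(accuracies$algorithm)
  if (length(counts) < 2) {
    abort("Need at least 2 algorithms.", class = "vf_invalid_parameter")
  }
  if (length(unique(counts)) != 1) {
    abort("Replicate counts must be equal across algorithms.",
          class = "vf_invalid_parameter")
  }
  df <- data.frame(algorithm = factor(accuracies$algorithm),
                   accuracy = accuracies$accuracy)
  fit <- aov(accuracy ~ algorithm, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$algorithm
  structure(
    list(f_statistic = an[["F value"]][1],
         df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
         p_value = an[["Pr(>F)"]][1],
         tukey = tibble(comparison = rownames(tk),
                        diff = tk[, "diff"], lwr = tk[, "lwr"],
                        upr = tk[, "upr"], p_adj = tk[, "p adj"])),
    class = "vf_anova"
  )
}

#' @export
print.vf_anova <- function(x, ...) {
  cat(sprintf("<vf_anova> F(%d, %d) = %.3f, p = %.4g; %d Tukey pairs\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value, nrow(x$tukey)))
  invisible(x)
}
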