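test_that("stratified folds partition 55 samples into sizes 5 and 6", {
  labels <- rep(c("VF", "control"), c(27, 28))
  f <- make_folds(labels, k = 10, repeats = 10, seed = 1)
  for (r in 1:10) {
    fr <- f[f$repeat_id == r, ]
    expect_setequal(fr$sample, 1:55)
    sizes <- as.integer(table(fr$fold))
    expect_true(all(sizes %in% c(5L, 6L)))
    # stratification keeps both classes in (almost) every fold
    tab <- table(fr$fold, labels[fr$sample])
    expect_true(all(tab >= 2))
  }
  # repeats differ, same seed reproduces
  expect_false(identical(f$fold[f$repeat_id == 1], f$fold[f$repeat_id == 2]))
  expect_identical(f, make_folds(labels, k = 10, repeats = 10, seed = 1))
  expect_error(make_folds(labels[1:5], k = 10),
               class = "vf_invalid_parameter")
  expect_warning(make_folds(rep(c("VF", "control"), c(3, 30)), k = 10,
                            repeats = 1), "non-stratified")
})

test_that("confusion metrics reproduce the hand-computed example", {
  # TP=8 FN=2 TN=9 FP=1 -> sens 80, spec 90, acc 85
  truth <- rep(c("VF", "control"), each = 10)
  pred <- c(rep("VF", 8), rep("control", 2), rep("control", 9), "VF")
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 80)
  expect_equal(cm$specificity, 90)
  expect_equal(cm$accuracy, 85)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  accuracy = 100))

  allctl <- confusion_metrics(rep("control", 20), truth)
  expect_equal(allctl$sensitivity, 0)
  expect_equal(allctl$specificity, 100)
  expect_equal(allctl$accuracy, 50)

  expect_warning(confusion_metrics(rep("control", 3), rep("control", 3)),
                 "sensitivity undefined")
  # accuracy identity acc = (sens*P + spec*N) / (P+N)
  set.seed(14)
  for (i in 1:20) {
    tr <- sample(c("VF", "control"), 30, replace = TRUE, prob = c(.4, .6))
    if (length(unique(tr)) < 2) next
    pr <- sample(c("VF", "control"), 30, replace = TRUE)
    cm <- confusion_metrics(pr, tr)
    P <- sum(tr == "VF"); N <- sum(tr != "VF")
    expect_equal(cm$accuracy, (cm$sensitivity * P + cm$specificity * N) / (P + N))
  }
})

test_that("trapezoidal AUC equals the rank-based statistic", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("control", "control", "VF", "VF"))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(rep(0, 10), rep(1, 10)),
                       rep(c("control", "VF"), each = 10))$auc, 1.0)
  expect_error(roc_auc(runif(5), rep("VF", 5)),
               class = "vf_invalid_parameter")

  # independent library cross-check on one fixed score set
  set.seed(98)
  sc <- runif(40); tr <- rep(c("VF", "control"), 20)
  expect_equal(roc_auc(sc, tr)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 response = factor(tr, levels = c("control", "VF")),
                 predictor = sc, quiet = TRUE))),
               tolerance = 1e-12)

  set.seed(99)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    truth <- sample(c("VF", "control"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # include heavy ties
    expect_equal(roc_auc(scores, truth)$auc, oracle_rank_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(5)
  aucs <- replicate(30, {
    truth <- rep(c("VF", "control"), each = 100)
    roc_auc(runif(200), truth)$auc
  })
  expect_true(all(abs(aucs - 0.5) < 0.15))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("Welch t-test handles degenerate and strong-effect cases", {
  x <- c(5, 5, 5)
  expect_equal(compare_groups_ttest(x, x)$statistic, 0)
  expect_equal(compare_groups_ttest(x, x)$p_value, 1)

  set.seed(8)
  a <- rnorm(30); b <- rnorm(30, 5)
  expect_lt(compare_groups_ttest(a, b)$p_value, 1e-10)

  # oracle: closed-form Welch statistic and t CDF on a fixed pair
  x1 <- c(3.1, 4.2, 2.8, 5.0, 3.9)
  x2 <- c(6.0, 5.5, 7.2, 6.8)
  tt <- compare_groups_ttest(x1, x2)
  v1 <- var(x1) / 5; v2 <- var(x2) / 4
  tstat <- (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 4 + v2^2 / 3)
  expect_equal(tt$statistic, tstat, tolerance = 1e-12)
  expect_equal(tt$df, df, tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_error(compare_groups_ttest(1, c(2, 3)),
               class = "vf_insufficient_data")
})

test_that("ANOVA F matches hand computation and Tukey flags planted effects", {
  # 3 algorithms x 4 replicates toy table
  acc <- data.frame(
    algorithm = rep(c("A", "B", "C"), each = 4),
    accuracy = c(80, 82, 78, 80, 90, 92, 88, 90, 80, 81, 79, 80)
  )
  res <- compare_algorithms_anova(acc)
  grand <- mean(acc$accuracy)
  ssb <- 4 * sum((tapply(acc$accuracy, acc$algorithm, mean) - grand)^2)
  ssw <- sum((acc$accuracy - ave(acc$accuracy, acc$algorithm))^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(res$f_statistic, f_hand, tolerance = 1e-9)
  expect_equal(unname(res$df), c(2, 9))

  # identical groups: F = 0, no rejections
  same <- data.frame(algorithm = rep(c("A", "B"), each = 5),
                     accuracy = rep(c(70, 71, 72, 73, 74), 2))
  res0 <- compare_algorithms_anova(same)
  expect_equal(res0$f_statistic, 0)
  expect_true(all(res0$tukey$p_adj > 0.95))

  # 4 equal groups + 1 shifted by 3 within-SDs: exactly its 4 pairs flagged
  set.seed(123)
  base <- rnorm(20 * 4, 85, 2)
  shifted <- rnorm(20, 85 + 6, 2)
  tab <- data.frame(
    algorithm = rep(c("A", "B", "C", "D", "E"), each = 20),
    accuracy = c(base, shifted)
  )
  res1 <- compare_algorithms_anova(tab)
  sig <- res1$tukey$comparison[res1$tukey$p_adj < 0.05]
  expect_length(sig, 4)
  expect_true(all(grepl("E", sig)))

  expect_error(compare_algorithms_anova(
    data.frame(algorithm = c("A", "A", "B"), accuracy = 1:3)),
    class = "vf_invalid_parameter")
})

test_that("type-I error of the feature t-test is nominal under the null", {
  # 1000 comparisons of SDNN between two groups generated with identical
  # parameters (27 vs 28 short RR series each)
  p0 <- preset_params("null")
  sdnn_of <- function(seed, params) {
    hrv_time_domain(generate_rr(params, duration = 120, seed = seed))$sdnn
  }
  set.seed(17)
  seeds <- matrix(sample.int(2^30, 1000 * 16), 1000, 16)
  pvals <- vapply(seq_len(1000), function(i) {
    g1 <- vapply(seeds[i, 1:8], sdnn_of, numeric(1), params = p0$vf)
    g2 <- vapply(seeds[i, 9:16], sdnn_of, numeric(1), params = p0$control)
    compare_groups_ttest(g1, g2)$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("cross-validation experiment wiring is sound", {
  co <- generate_cohort(10, 10, seed = 21)
  fx <- suppressMessages(extract_features(co))
  cv <- run_experiment(fx, "qrs", "NB", k = 5, repeats = 2, seed = 2)
  expect_s3_class(cv, "vf_cv")
  expect_equal(nrow(cv$folds), 10)
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 100))
  expect_true(all(cv$aucs$auc >= 0 & cv$aucs$auc <= 1))
  g <- glance(cv)
  expect_gte(g$mean_accuracy, min(cv$folds$accuracy))
  expect_lte(g$mean_accuracy, max(cv$folds$accuracy))
  td <- tidy(cv)
  expect_true(all(c("repeat_id", "fold", "accuracy", "auc") %in% names(td)))

  # combined-15 run reports 15 input features
  cv15 <- run_experiment(fx, "combined", "NB", k = 5, repeats = 1, seed = 3)
  expect_equal(glance(cv15)$n_features, 15)
  expect_error(run_experiment(fx[, 1:5], "qrs", "NB"),
               class = "vf_contract_error")
})
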