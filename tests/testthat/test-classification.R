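test_that("standardizer centres and scales with training statistics only", {
  sc <- fit_standardizer(data.frame(f = c(1, 3)))
  expect_equal(unname(sc$mu), 2)
  expect_equal(unname(sc$s), 1)
  expect_equal(as.numeric(apply_standardizer(sc, data.frame(f = c(1, 3)))),
               c(-1, 1))
  expect_equal(as.numeric(apply_standardizer(sc, data.frame(f = 2))), 0)

  set.seed(9)
  train <- matrix(rnorm(60, 5, 3), 20, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  sc2 <- fit_standardizer(train)
  z <- apply_standardizer(sc2, train)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, function(v) mean(v^2))), rep(1, 3),
               tolerance = 1e-9)

  err <- tryCatch(fit_standardizer(data.frame(flat = c(5, 5))),
                  condition = identity)
  expect_s3_class(err, "vf_invalid_parameter")
  expect_match(conditionMessage(err), "flat")
})

test_that("forward pass honours the layer equations", {
  m0 <- list(W1 = matrix(0, 2, 3), b1 = numeric(3),
             W2 = matrix(0, 3, 1), b2 = 0, bias_after_activation = FALSE)
  expect_equal(ann_forward(m0, c(1, -2)), 0.5)

  # ReLU by cases
  expect_equal(vfforecast:::relu(-3.2), 0)
  expect_equal(vfforecast:::relu(2.5), 2.5)

  # 1-1-1 identity chain: sigmoid(ln 3) = 0.75
  m1 <- list(W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(1, 1, 1), b2 = 0,
             bias_after_activation = FALSE)
  expect_equal(ann_forward(m1, log(3)), 0.75)

  expect_error(ann_forward(m1, c(1, 2)), class = "vf_contract_error")

  # output stays in [0,1] and is continuous in x
  set.seed(4)
  m <- ann_train(matrix(rnorm(40), 20, 2), rep(c("VF", "control"), 10),
                 epochs = 5, seed = 1)
  p <- ann_forward(m, matrix(rnorm(200), 100, 2))
  expect_true(all(p >= 0 & p <= 1 & is.finite(p)))

  # post-activation-bias variant clips to [0,1]
  mlit <- list(W1 = matrix(1, 1, 2), b1 = c(0, 0), W2 = matrix(1, 2, 1),
               b2 = 0.9, bias_after_activation = TRUE)
  expect_lte(max(ann_forward(mlit, matrix(c(5, -5), 2, 1))), 1)
})

test_that("training separates a margin-2SD synthetic set and is reproducible", {
  set.seed(202)
  x <- rbind(matrix(rnorm(200, -2), 100, 2), matrix(rnorm(200, 2), 100, 2))
  y <- rep(c("control", "VF"), each = 100)
  m <- ann_train(x, y, seed = 3)
  acc <- mean(predict_label(ann_forward(m, x)) == y)
  expect_gte(acc, 0.99)
  # loss decreases from the first epoch to the last
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])

  m2 <- ann_train(x, y, seed = 3)
  expect_identical(m$W1, m2$W1)
  expect_identical(m$W2, m2$W2)
  expect_identical(m$b1, m2$b1)

  expect_error(ann_train(x, rep("VF", 200)), class = "vf_invalid_parameter")
  expect_error(ann_train(x, y, epochs = 0), class = "vf_invalid_parameter")
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  x <- matrix(rnorm(24), 8, 3)
  y <- rep(c(1, 0), 4)
  m <- ann_train(x, y, epochs = 3, seed = 2)
  got <- vfforecast:::ann_loss_grads(m, x, y)
  h <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2")) {
    w <- m[[nm]]
    num <- w
    for (i in seq_along(w)) {
      up <- m; up[[nm]][i] <- up[[nm]][i] + h
      dn <- m; dn[[nm]][i] <- dn[[nm]][i] - h
      num[i] <- (vfforecast:::ann_loss_grads(up, x, y)$loss -
                   vfforecast:::ann_loss_grads(dn, x, y)$loss) / (2 * h)
    }
    rel <- abs(num - got$grads[[nm]]) / pmax(abs(num), 1e-4)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("probability thresholding follows the >= convention", {
  expect_equal(as.character(predict_label(c(0.9, 0.1, 0.5))),
               c("VF", "control", "VF"))
  expect_error(predict_label(1.2), class = "vf_contract_error")
})

test_that("comparison classifiers fit, predict and reproduce under a seed", {
  set.seed(77)
  x <- rbind(matrix(rnorm(120, -3), 60, 2), matrix(rnorm(120, 3), 60, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("control", "VF"), each = 60)

  # NB on two well-separated Gaussians reaches near-Bayes accuracy
  nb <- fit_classifier(x, y, "NB")
  expect_gte(mean(predict_label(predict_prob(nb, x)) == y), 0.95)

  # KNN trained on one duplicated point predicts that class everywhere
  xk <- matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2")))
  knn <- fit_classifier(xk, rep("VF", 5), "KNN")
  expect_equal(as.character(predict_label(predict_prob(knn, x))),
               rep("VF", nrow(x)))

  # RF with a fixed seed is deterministic
  rf1 <- fit_classifier(x, y, "RF", seed = 5)
  rf2 <- fit_classifier(x, y, "RF", seed = 5)
  expect_identical(predict_prob(rf1, x), predict_prob(rf2, x))

  sv <- fit_classifier(x, y, "SVM", seed = 1)
  expect_gte(mean(predict_label(predict_prob(sv, x)) == y), 0.95)

  expect_error(fit_classifier(x, rep("VF", nrow(x)), "SVM"),
               class = "vf_invalid_parameter")
})

test_that("standardize-train-predict is invariant to affine feature rescaling", {
  set.seed(31)
  x <- rbind(matrix(rnorm(100, -1.5), 50, 2), matrix(rnorm(100, 1.5), 50, 2))
  y <- rep(c("control", "VF"), each = 50)
  x2 <- sweep(sweep(x, 2, c(1000, 0.01), "*"), 2, c(-7, 3), "+")
  sc1 <- fit_standardizer(x)
  sc2 <- fit_standardizer(x2)
  m1 <- ann_train(apply_standardizer(sc1, x), y, seed = 8)
  m2 <- ann_train(apply_standardizer(sc2, x2), y, seed = 8)
  expect_equal(ann_forward(m1, apply_standardizer(sc1, x)),
               ann_forward(m2, apply_standardizer(sc2, x2)),
               tolerance = 1e-9)
})

test_that("model JSON serialization round-trips", {
  set.seed(12)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("VF", "control"), 10)
  m <- ann_train(x, y, epochs = 10, seed = 4)
  path <- file.path(withr::local_tempdir(), "model.json")
  ann_to_json(m, path, standardizer = fit_standardizer(x))
  back <- ann_from_json(path)
  expect_equal(back$W1, m$W1, tolerance = 1e-12)
  expect_equal(ann_forward(back, x), ann_forward(m, x), tolerance = 1e-12)
})
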