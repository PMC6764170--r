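#' Fit one of the five prediction algorithms
#'
#' A uniform wrapper around the network of [ann_train()] (`"ANN"`) and the
#' four comparison classifiers: radial-kernel support vector machine
#' (`"SVM"`, e1071), k-nearest neighbours (`"KNN"`, k = 5, class), random
#' forest (`"RF"`, randomForest) and Gaussian naive Bayes (`"NB"`, e1071).
#' All stochastic fits are seeded. Features are expected already
#' standardized.
#'
#' @param x Numeric matrix of z-scored training features.
#' @param y Labels (`VF`/`control`); both classes must be present (KNN
#'   excepted, which predicts from whatever neighbours exist).
#' @param algorithm One of `"ANN"`, `"SVM"`, `"KNN"`, `"RF"`, `"NB"`.
#' @param seed Integer seed.
#' @param ... Passed to the underlying fitter ([ann_train()] for `"ANN"`).
#' @return An object of class `vf_classifier`.
#' @export
fit_classifier <- function(x, y, algorithm = c("ANN", "SVM", "KNN", "RF", "NB"),
                           seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  yf <- factor(as.character(y), levels = c("control", "VF"))
  if (algorithm != "KNN" && length(unique(yf)) < 2) {
    abort("Training data must contain both classes.",
          class = "vf_invalid_parameter")
  }
  fit <- switch(algorithm,
    ANN = ann_train(x, yf, seed = seed, ...),
    SVM = with_seed(seed,
      e1071::svm(x, yf, kernel = "radial", probability = TRUE, ...)),
    KNN = list(train = x, cl = yf, k = 5L),
    RF = with_seed(seed, randomForest::randomForest(x, yf, ...)),
    NB = e1071::naiveBayes(x, yf, ...)
  )
  structure(list(algorithm = algorithm, fit = fit, seed = seed),
            class = "vf_classifier")
}

#' Predicted VF probability from a fitted classifier
#'
#' @param object A [fit_classifier()] result.
#' @param x New feature rows (matrix).
#' @param ... Unused.
#' @return Numeric vector of P(VF) scores in [0, 1].
#' @export
predict_prob <- function(object, x, ...) {
  stopifnot(inherits(object, "vf_classifier"))
  x <- as.matrix(x)
  switch(object$algorithm,
    ANN = ann_forward(object$fit, x),
    SVM = {
      pr <- predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "VF"]
    },
    KNN = {
      k <- min(object$fit$k, nrow(object$fit$train))
      pred <- class::knn(object$fit$train, x, object$fit$cl, k = k,
                         prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "VF", win, 1 - win)
    },
    RF = predict(object$fit, x, type = "prob")[, "VF"],
    NB = predict(object$fit, x, type = "raw")[, "VF"]
  )
}

#' @export
print.vf_classifier <- function(x, ...) {
  cat(sprintf("<vf_classifier> %s (seed %d)\n", x$algorithm, x$seed))
  invisible(x)
}
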