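#' Fit a feature standardizer (z-scoring)
#'
#' Records per-feature mean and population SD from the training rows, so
#' test rows can be transformed with the training statistics only:
#' `z = (x - mu) / s`.
#'
#' @param x A data frame or matrix of training feature rows (>= 2 rows).
#' @return An object of class `standardizer` with fields `mu`, `s`,
#'   `features`.
#' @export
#' @examples
#' sc <- fit_standardizer(data.frame(a = c(1, 3)))
#' apply_standardizer(sc, data.frame(a = 2))
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    abort("Need at least 2 training rows to fit a standardizer.",
          class = "vf_insufficient_data")
  }
  mu <- colMeans(x)
  s <- apply(x, 2, sd_pop)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    nm <- colnames(x)[zero] %||% which(zero)
    abort(sprintf("Zero-variance feature(s): %s", paste(nm, collapse = ", ")),
          class = "vf_invalid_parameter")
  }
  structure(list(mu = mu, s = s, features = colnames(x)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param object A [fit_standardizer()] result.
#' @param x New feature rows (data frame or matrix with the same columns).
#' @return A numeric matrix of z-scores.
#' @export
apply_standardizer <- function(object, x) {
  stopifnot(inherits(object, "standardizer"))
  x <- as.matrix(x)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    x <- x[, object$features, drop = FALSE]
  }
  if (ncol(x) != length(object$mu)) {
    abort("Feature count does not match the fitted standardizer.",
          class = "vf_contract_error")
  }
  sweep(sweep(x, 2, object$mu, "-"), 2, object$s, "/")
}
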