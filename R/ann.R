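#' Forward pass of the 3-layer prediction network
#'
#' The network maps a z-scored feature vector through one hidden layer of
#' `m` rectified-linear units to a single sigmoid output interpreted as the
#' probability of the VF class. By default biases are added before the
#' activations (`sigmoid(W2 relu(W1 x + b1) + b2)`). With
#' `bias_after_activation = TRUE` the biases are added *after* each
#' activation (`relu(W1 x) + b1`, `sigmoid(W2 h) + b2`) and the output is
#' clipped to [0, 1]; this variant is kept as a strict reading of the
#' layer equations but breaks the probability interpretation of the output
#' and is not the default.
#'
#' @param model A `vf_ann` model from [ann_train()] (or a bare list with
#'   `W1`, `b1`, `W2`, `b2`).
#' @param x Numeric vector of length n, or matrix with n columns.
#' @return Probabilities in [0, 1] (one per input row).
#' @export
#' @examples
#' m <- list(W1 = matrix(0, 1, 1), b1 = 0, W2 = matrix(0, 1, 1), b2 = 0,
#'           bias_after_activation = FALSE)
#' ann_forward(m, 0.7)  # all-zero weights: sigmoid(0) = 0.5
ann_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$W1)) {
    abort(sprintf("Input has %d features; model expects %d.",
                  ncol(x), nrow(model$W1)),
          class = "vf_contract_error")
  }
  literal <- isTRUE(model$bias_after_activation)
  if (literal) {
    H <- relu(x %*% model$W1)
    H <- sweep(H, 2, model$b1, "+")
    out <- sigmoid(H %*% model$W2) + model$b2
    pmin(pmax(as.numeric(out), 0), 1)
  } else {
    H <- relu(sweep(x %*% model$W1, 2, model$b1, "+"))
    as.numeric(sigmoid(H %*% model$W2 + model$b2))
  }
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train the 3-layer network with Adam on binary cross-entropy
#'
#' Mini-batch gradient training of the network of [ann_forward()]:
#' seeded small-uniform weight initialisation, binary cross-entropy loss,
#' Adam updates (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). Identical data
#' and seed give bit-identical final weights.
#'
#' @param x Numeric matrix of z-scored features (rows = samples).
#' @param y Labels: factor/character with levels `VF`/`control`, or 0/1
#'   numeric (1 = VF). Both classes must be present.
#' @param hidden Hidden units (default 6).
#' @param learning_rate,epochs,batch_size Adam step size and schedule.
#' @param seed Integer seed for initialisation and batch shuffling.
#' @param bias_after_activation Strict post-activation bias variant, see
#'   [ann_forward()].
#' @return An object of class `vf_ann`: weights, config and the per-epoch
#'   mean training loss (`loss_history`).
#' @export
ann_train <- function(x, y, hidden = 6, learning_rate = 1e-3, epochs = 200,
                      batch_size = 8, seed = 1,
                      bias_after_activation = FALSE) {
  x <- as.matrix(x)
  y <- as_binary_label(y)
  if (length(unique(y)) < 2) {
    abort("Training data must contain both classes.",
          class = "vf_invalid_parameter")
  }
  if (epochs < 1 || learning_rate <= 0) {
    abort("`epochs` must be >= 1 and `learning_rate` > 0.",
          class = "vf_invalid_parameter")
  }
  n <- nrow(x); p <- ncol(x); m <- hidden
  model <- with_seed(seed, {
    init <- function(nr, nc) {
      matrix(runif(nr * nc, -0.5, 0.5) / sqrt(nr), nr, nc)
    }
    model <- list(W1 = init(p, m), b1 = numeric(m),
                  W2 = init(m, 1), b2 = 0,
                  bias_after_activation = bias_after_activation)
    # Adam state
    ms <- lapply(model[1:4], function(w) w * 0)
    vs <- ms
    t_step <- 0
    loss_hist <- numeric(epochs)
    eps_clip <- 1e-12
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        # forward
        A1 <- xb %*% model$W1
        if (bias_after_activation) {
          H <- relu(A1)
          Hb <- sweep(H, 2, model$b1, "+")
          Z <- Hb %*% model$W2
          phat <- as.numeric(sigmoid(Z)) + model$b2
        } else {
          A1 <- sweep(A1, 2, model$b1, "+")
          H <- relu(A1)
          Hb <- H
          Z <- Hb %*% model$W2 + model$b2
          phat <- as.numeric(sigmoid(Z))
        }
        pc <- pmin(pmax(phat, eps_clip), 1 - eps_clip)
        losses <- c(losses, -mean(yb * log(pc) + (1 - yb) * log(1 - pc)))
        # backward: dL/dphat * dphat/dZ; for in-range outputs with
        # pre-activation bias this collapses to (p - y)/nb
        dphat <- (pc - yb) / (pc * (1 - pc)) / nb
        in_range <- (phat > 0 & phat < 1) | !bias_after_activation
        dphat[!in_range] <- 0
        sz <- as.numeric(sigmoid(Z))
        dZ <- dphat * sz * (1 - sz)
        gW2 <- t(Hb) %*% dZ
        gb2 <- if (bias_after_activation) sum(dphat) else sum(dZ)
        dH <- dZ %*% t(model$W2)
        dA1 <- dH * (A1 > 0)
        gW1 <- t(xb) %*% dA1
        gb1 <- if (bias_after_activation) colSums(dH) else colSums(dA1)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        t_step <- t_step + 1
        for (nm in names(grads)) {
          ms[[nm]] <- 0.9 * ms[[nm]] + 0.1 * grads[[nm]]
          vs[[nm]] <- 0.999 * vs[[nm]] + 0.001 * grads[[nm]]^2
          mhat <- ms[[nm]] / (1 - 0.9^t_step)
          vhat <- vs[[nm]] / (1 - 0.999^t_step)
          model[[nm]] <- model[[nm]] -
            learning_rate * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      loss_hist[ep] <- mean(losses)
    }
    model$loss_history <- loss_hist
    model
  })
  model$config <- list(hidden = hidden, learning_rate = learning_rate,
                       epochs = epochs, batch_size = batch_size, seed = seed,
                       bias_after_activation = bias_after_activation)
  class(model) <- "vf_ann"
  model
}

as_binary_label <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) {
      abort("Numeric labels must be 0/1 (1 = VF).",
            class = "vf_invalid_parameter")
    }
    return(as.numeric(y))
  }
  as.numeric(as.character(y) == "VF")
}

#' Threshold a probability into a class label
#'
#' @param probability Probabilities in [0, 1].
#' @param threshold Decision threshold; the VF label is assigned when
#'   `probability >= threshold` (ties go to VF).
#' @return Factor with levels `control`, `VF`.
#' @export
#' @examples
#' predict_label(c(0.9, 0.1, 0.5))
predict_label <- function(probability, threshold = 0.5) {
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    abort("`probability` must lie in [0, 1].", class = "vf_contract_error")
  }
  factor(ifelse(probability >= threshold, "VF", "control"),
         levels = c("control", "VF"))
}

#' @export
print.vf_ann <- function(x, ...) {
  cat(sprintf("<vf_ann> %d-%d-1 network, %d epochs (final BCE %.4f)\n",
              nrow(x$W1), ncol(x$W1), x$config$epochs,
              tail(x$loss_history, 1)))
  invisible(x)
}

# BCE loss and analytic gradients at a point, used by the gradient check.
ann_loss_grads <- function(model, x, y) {
  x <- as.matrix(x); y <- as_binary_label(y)
  nb <- nrow(x)
  A1 <- sweep(x %*% model$W1, 2, model$b1, "+")
  H <- relu(A1)
  Z <- H %*% model$W2 + model$b2
  phat <- as.numeric(sigmoid(Z))
  pc <- pmin(pmax(phat, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dZ <- (pc - y) / nb
  gW2 <- t(H) %*% dZ
  gb2 <- sum(dZ)
  dH <- dZ %*% t(model$W2)
  dA1 <- dH * (A1 > 0)
  list(loss = loss,
       grads = list(W1 = t(x) %*% dA1, b1 = colSums(dA1),
                    W2 = gW2, b2 = gb2))
}

#' Serialize / restore a trained network as JSON
#'
#' The JSON schema stores the weight matrices, biases, training config and,
#' when supplied, the standardizer, so a fitted model is fully
#' reproducible from the file.
#'
#' @param model A `vf_ann`.
#' @param path Output JSON path.
#' @param standardizer Optional [fit_standardizer()] result stored with the
#'   model.
#' @return `path` invisibly (`ann_to_json`); a `vf_ann` (`ann_from_json`).
#' @export
ann_to_json <- function(model, path, standardizer = NULL) {
  stopifnot(inherits(model, "vf_ann"))
  payload <- list(
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    bias_after_activation = isTRUE(model$bias_after_activation),
    config = model$config,
    standardizer = if (!is.null(standardizer)) {
      list(mu = as.list(standardizer$mu), s = as.list(standardizer$s),
           features = standardizer$features)
    }
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname ann_to_json
#' @export
ann_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
                W2 = as.matrix(p$W2), b2 = as.numeric(p$b2),
                bias_after_activation = isTRUE(p$bias_after_activation),
                config = p$config)
  class(model) <- "vf_ann"
  model
}
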