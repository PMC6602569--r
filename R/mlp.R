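# Minimal feed-forward multi-layer perceptron for binary classification:
# ReLU hidden layers, sigmoid output, binary cross-entropy loss, minibatch
# stochastic gradient descent with classical momentum. Written in plain
# matrix algebra; deterministic given a seed.

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(sizes) {
  # Glorot-uniform initialization per layer
  W <- list()
  b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     nrow = sizes[l], ncol = sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, x) {
  L <- length(net$W)
  a <- list(x)
  for (l in seq_len(L)) {
    z <- a[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow = nrow(a[[l]]),
                                        ncol = length(net$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l < L) pmax(z, 0) else sigmoid(z)
  }
  a
}

#' Fit a multi-layer perceptron
#'
#' Trains a ReLU-hidden / sigmoid-output network on 0/1 labels by minibatch
#' SGD with momentum, minimizing binary cross-entropy. A stratified
#' `val_fraction` of the rows is held out and training stops early when the
#' held-out loss has not improved for `patience` epochs; the weights with the
#' best held-out loss are kept. This guards the perceptron against
#' memorizing the (rebalanced) training set, which would otherwise push
#' out-of-sample points in the class-overlap region to extreme scores.
#'
#' @param x Numeric matrix (standardized features recommended).
#' @param y 0/1 labels.
#' @param hidden Hidden layer sizes (default `c(20, 15)`).
#' @param lr Learning rate (default 0.1).
#' @param momentum Momentum coefficient (default 0.8).
#' @param epochs Maximum epochs (default 200).
#' @param batch Minibatch size (default 32).
#' @param patience Early-stopping patience in epochs (default 20).
#' @param val_fraction Fraction of rows held out for the early-stopping loss
#'   (default 0.1, stratified); with fewer than 20 rows, or when an explicit
#'   monitor set is given, no internal split is made.
#' @param x_val,y_val Optional explicit monitor set for the early-stopping
#'   loss (used by [train_driver_model()] to monitor on raw, pre-resampling
#'   rows so that synthetic minority copies cannot mask overfitting).
#' @param seed RNG seed for initialization and minibatch shuffling.
#' @return An `mlp` model object.
#' @export
mlp_fit <- function(x, y, hidden = c(20, 15), lr = 0.1, momentum = 0.8,
                    epochs = 200, batch = 32, patience = 20,
                    val_fraction = 0.1, x_val = NULL, y_val = NULL, seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  sizes <- c(ncol(x), hidden, 1L)
  with_seed(seed, {
    n_all <- nrow(x)
    if (!is.null(x_val)) {
      x_val <- as.matrix(x_val)
      y_val <- as.numeric(y_val)
      val_idx <- NA  # external monitor; no rows removed from training
    } else {
      val_idx <- integer(0)
      if (n_all >= 20 && val_fraction > 0) {
        # stratified hold-out so both classes appear in the monitoring set
        for (cls in unique(y)) {
          i_cls <- which(y == cls)
          n_v <- max(1L, floor(val_fraction * length(i_cls)))
          val_idx <- c(val_idx, sample(i_cls, n_v))
        }
      }
      x_val <- x[val_idx, , drop = FALSE]
      y_val <- y[val_idx]
      if (length(val_idx) > 0) {
        x <- x[-val_idx, , drop = FALSE]
        y <- y[-val_idx]
      }
    }
    net <- mlp_init(sizes)
    vW <- lapply(net$W, function(w) w * 0)
    vb <- lapply(net$b, function(b) b * 0)
    n <- nrow(x)
    L <- length(net$W)
    best <- net
    best_loss <- Inf
    stale <- 0L
    eps <- 1e-12
    x_mon <- if (nrow(x_val) > 0) x_val else x
    y_mon <- if (nrow(x_val) > 0) y_val else y
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = batch)
      for (s in starts) {
        b_idx <- idx[s:min(s + batch - 1, n)]
        xb <- x[b_idx, , drop = FALSE]
        yb <- y[b_idx]
        a <- mlp_forward(net, xb)
        m <- length(b_idx)
        # output delta for sigmoid + BCE: (yhat - y)
        delta <- (a[[L + 1]] - matrix(yb, ncol = 1)) / m
        for (l in rev(seq_len(L))) {
          gW <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(net$W[[l]])) * (a[[l]] > 0)
          }
          vW[[l]] <- momentum * vW[[l]] - lr * gW
          vb[[l]] <- momentum * vb[[l]] - lr * gb
          net$W[[l]] <- net$W[[l]] + vW[[l]]
          net$b[[l]] <- net$b[[l]] + vb[[l]]
        }
      }
      p <- mlp_forward(net, x_mon)[[L + 1]][, 1]
      ll <- -(y_mon * log(p + eps) + (1 - y_mon) * log(1 - p + eps))
      # class-balanced monitor loss: matches the balanced training objective
      # even when the monitor rows are imbalanced
      loss <- if (length(unique(y_mon)) == 2) {
        (mean(ll[y_mon == 1]) + mean(ll[y_mon == 0])) / 2
      } else mean(ll)
      if (is.finite(loss) && loss < best_loss - 1e-6) {
        best_loss <- loss
        best <- net
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
    structure(list(W = best$W, b = best$b, sizes = sizes, loss = best_loss),
              class = "mlp")
  })
}

#' Predict with a fitted perceptron
#'
#' @param object An `mlp` from [mlp_fit()].
#' @param x Feature matrix (same standardization as training).
#' @param ... Unused.
#' @return Numeric vector of sigmoid outputs in \[0, 1\].
#' @export
predict.mlp <- function(object, x, ...) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  mlp_forward(object, x)[[length(object$W) + 1]][, 1]
}
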