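# Small feed-forward regression network trained by full-batch Adam.
#
# This is the regression engine behind both planners: tabular inputs are tiny
# (hundreds of rows, 8 columns), so full-batch matrix operations in base R are
# both fast and exactly reproducible. Weights use Glorot-normal seeded
# initialization; hidden layers are rectified, the output layer is linear;
# the loss is mean squared error. Training early-stops on a held-out
# validation slice and restores the best validation weights.

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      sd <- sqrt(2 / (fan_in + fan_out))
      list(W = matrix(stats::rnorm(fan_in * fan_out, 0, sd), fan_in, fan_out),
           b = rep(0, fan_out))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < n_l) pmax(z, 0) else z
  }
  acts
}

mlp_predict <- function(layers, X) {
  mlp_forward(layers, X)[[length(layers) + 1L]]
}

# gradient of mean squared error w.r.t. all weights (backprop)
mlp_grad <- function(layers, acts, Y) {
  n <- nrow(Y)
  n_l <- length(layers)
  grads <- vector("list", n_l)
  delta <- 2 * (acts[[n_l + 1L]] - Y) / (n * ncol(Y))
  for (l in rev(seq_len(n_l))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

mlp_loss <- function(layers, X, Y) {
  mean((mlp_predict(layers, X) - Y)^2)
}

#' @noRd
mlp_train <- function(X, Y, hidden = c(16L, 8L), seed = 1L,
                      lr = 0.01, max_epochs = 2000L, patience = 50L,
                      val_frac = 0.1, weight_decay = 1e-4) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, ncol(Y))
  layers <- mlp_init(sizes, seed)

  idx <- with_seed(derive_seed(seed, "valsplit"), sample.int(n))
  n_val <- max(1L, floor(val_frac * n))
  val <- idx[seq_len(n_val)]
  tr <- if (n > n_val) idx[-seq_len(n_val)] else idx
  Xt <- X[tr, , drop = FALSE]; Yt <- Y[tr, , drop = FALSE]
  Xv <- X[val, , drop = FALSE]; Yv <- Y[val, , drop = FALSE]

  # Adam state
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  # early stopping with plateau-based rate reduction: when the validation
  # loss stalls for `patience` epochs, restore the best weights and quarter
  # the learning rate; stop once the rate has been cut 6 times (or at
  # max_epochs). Adam's unit-scale steps otherwise floor the loss at ~lr^2.
  best <- layers; best_val <- Inf; wait <- 0L; cuts <- 0L
  curve <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    acts <- mlp_forward(layers, Xt)
    grads <- mlp_grad(layers, acts, Yt)
    for (l in seq_along(layers)) {
      for (p in c("W", "b")) {
        g <- grads[[l]][[p]]
        # L2 penalty on weights only; regularizes extrapolation between
        # training points
        if (p == "W") g <- g + 2 * weight_decay * layers[[l]]$W
        m[[l]][[p]] <- b1 * m[[l]][[p]] + (1 - b1) * g
        v[[l]][[p]] <- b2 * v[[l]][[p]] + (1 - b2) * g^2
        mhat <- m[[l]][[p]] / (1 - b1^epoch)
        vhat <- v[[l]][[p]] / (1 - b2^epoch)
        layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    vl <- mlp_loss(layers, Xv, Yv)
    if (!is.finite(vl))
      stop("training diverged: non-finite validation loss at epoch ", epoch,
           call. = FALSE)
    curve[epoch] <- vl
    if (vl < best_val - 1e-9) {
      best_val <- vl; best <- layers; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        if (cuts >= 6L) break
        layers <- best
        lr <- lr / 4
        cuts <- cuts + 1L
        wait <- 0L
      }
    }
  }
  list(layers = best, val_loss = best_val, epochs = length(curve),
       loss_curve = curve)
}
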