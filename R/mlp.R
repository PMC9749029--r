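#' @title Feed-forward neural network
#' @description A multilayer perceptron regressor in plain matrix
#' arithmetic: ReLU hidden layers of equal width, linear output, Adam
#' optimizer, mini-batches of 64, early stopping (patience 10) on an
#' internal 10% validation split, at most 500 epochs. Deterministic for a
#' given seed.
#' @name mlp
#' @keywords internal
NULL

.mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                   sd = sqrt(2 / fan_in)),
                      fan_in, sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
}

.mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  for (l in seq_along(layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < length(layers)) pmax(z, 0) else z
  }
  acts
}

#' Fit the MLP regressor
#'
#' @param x training matrix.
#' @param y numeric response.
#' @param lr Adam learning rate.
#' @param n_hidden hidden width.
#' @param n_layers number of hidden layers.
#' @param seed seed for initialization, batching and the validation split.
#' @param max_epochs,patience,batch_size training-control settings.
#' @return list of class `cliff_mlp`.
#' @export
mlp_fit <- function(x, y, lr = 5e-4, n_hidden = 256L, n_layers = 1L,
                    seed = 1L, max_epochs = 500L, patience = 10L,
                    batch_size = 64L) {
  x <- as.matrix(x)
  n <- nrow(x)
  sizes <- c(ncol(x), rep(n_hidden, n_layers), 1L)
  layers <- .mlp_init(sizes, seed)
  # Adam state
  mom <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L

  n_val <- max(1L, floor(0.1 * n))
  with_seed(derive_seed(seed, "val"), {
    vidx <- sample.int(n, n_val)
  })
  tidx <- setdiff(seq_len(n), vidx)
  if (!length(tidx)) { tidx <- vidx }
  xv <- x[vidx, , drop = FALSE]; yv <- y[vidx]
  xt <- x[tidx, , drop = FALSE]; yt <- y[tidx]

  best <- list(layers = layers, val = Inf, epoch = 0L)
  wait <- 0L
  with_seed(derive_seed(seed, "batches"), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(nrow(xt))
      starts <- seq(1L, nrow(xt), by = batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1L, nrow(xt))]
        xb <- xt[rows, , drop = FALSE]
        yb <- yt[rows]
        acts <- .mlp_forward(layers, xb)
        pred <- acts[[length(acts)]][, 1L]
        delta <- matrix((pred - yb) * (2 / length(yb)), ncol = 1L)
        for (l in rev(seq_along(layers))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
          }
          t <- t + 1L
          mom[[l]]$W <- beta1 * mom[[l]]$W + (1 - beta1) * gW
          mom[[l]]$b <- beta1 * mom[[l]]$b + (1 - beta1) * gb
          vel[[l]]$W <- beta2 * vel[[l]]$W + (1 - beta2) * gW^2
          vel[[l]]$b <- beta2 * vel[[l]]$b + (1 - beta2) * gb^2
          mhW <- mom[[l]]$W / (1 - beta1^t)
          mhb <- mom[[l]]$b / (1 - beta1^t)
          vhW <- vel[[l]]$W / (1 - beta2^t)
          vhb <- vel[[l]]$b / (1 - beta2^t)
          layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
          layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
        }
      }
      val <- sqrt(mean((.mlp_forward(layers, xv)[[length(layers) + 1L]][, 1L]
                        - yv)^2))
      if (is.finite(val) && val < best$val - 1e-6) {
        best <- list(layers = layers, val = val, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  structure(list(layers = best$layers, val_rmse = best$val,
                 epochs = best$epoch, lr = lr, n_hidden = n_hidden,
                 n_layers = n_layers, seed = as.integer(seed)),
            class = "cliff_mlp")
}

#' @rdname mlp_fit
#' @param fit a `cliff_mlp`.
#' @export
mlp_predict <- function(fit, x) {
  acts <- .mlp_forward(fit$layers, as.matrix(x))
  as.numeric(acts[[length(acts)]][, 1L])
}
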