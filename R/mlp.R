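# Minimal fully-connected feed-forward regression network (pyramid MLP).
#
# The estimator the selection pipeline searches over is a small
# fully-connected network with rectifier hidden units and a single linear
# output, trained by mini-batch Adam on mean squared error with early
# stopping on an inner 10% holdout. Everything is plain vectorised R: the
# per-step cost is a handful of BLAS matrix products on (batch x width)
# matrices, which is fast at the widths used here (<= 30 nodes).
#
# Training is deterministic given `seed`: weight initialisation, the inner
# holdout split and every epoch's batch shuffle all come from one seeded RNG
# stream. After training the output intercept is recentred so the mean
# residual on the training partition is exactly zero (a standard output bias
# correction; it uses training data only).

#' Training controls for the network estimator
#'
#' @param max_epochs Hard cap on training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without improvement of the
#'   inner-holdout MSE).
#' @param val_fraction Fraction of the training data held out internally for
#'   early stopping.
#' @param lr_decay Per-epoch learning-rate decay: the step size at epoch t
#'   is `learning_rate / (1 + lr_decay * (t - 1))`. Zero keeps the rate
#'   constant; a value around 0.05 anneals the optimiser into the minimum,
#'   which matters when the target accuracy is well below the noise level
#'   the early-stopping holdout can resolve.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   weight matrices each step, in standardised units. Zero disables it;
#'   with noisy targets a moderate value (~0.1) trims the estimation
#'   variance of the wider candidates without hurting the smooth functions
#'   fitted here.
#' @return A list of class `mlp_control`.
#' @export
mlp_control <- function(max_epochs = 150, batch_size = 1024,
                        learning_rate = 0.003, patience = 8,
                        val_fraction = 0.1, lr_decay = 0,
                        weight_decay = 0) {
  stopifnot(max_epochs >= 1, batch_size >= 1,
            learning_rate > 0, patience >= 1,
            val_fraction >= 0, val_fraction < 1, lr_decay >= 0,
            weight_decay >= 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 lr_decay = lr_decay,
                 weight_decay = weight_decay),
            class = "mlp_control")
}

relu <- function(z) (z + abs(z)) / 2

mlp_forward <- function(W, b, x) {
  a <- x
  L <- length(W)
  for (l in seq_len(L - 1L)) {
    a <- relu(sweep(a %*% W[[l]], 2, b[[l]], `+`))
  }
  drop(sweep(a %*% W[[L]], 2, b[[L]], `+`))
}

# One forward+backward pass on a batch; returns gradients and the
# activations are not retained beyond the call.
mlp_grad <- function(W, b, x, y) {
  L <- length(W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1]] <- x
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) relu(Z[[l]]) else Z[[l]]
  }
  nb <- nrow(x)
  dZ <- (A[[L + 1L]] - y) * (2 / nb)
  dW <- vector("list", L); db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    if (l > 1L) {
      dZ <- (dZ %*% t(W[[l]])) * (Z[[l - 1L]] > 0)
    }
  }
  list(dW = dW, db = db)
}

# Fit the network on a numeric matrix x and response y (original scale).
mlp_fit <- function(x, y, widths, seed, control = mlp_control()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2) abort("need at least two records to fit", class = "ldlbench_validation_error")
  widths <- as.integer(widths)
  if (any(widths < 1)) abort("hidden-layer widths must be positive",
                             class = "ldlbench_config_error")

  x_center <- colMeans(x)
  x_scale <- apply(x, 2, sd)
  x_scale[!is.finite(x_scale) | x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  xs <- sweep(sweep(x, 2, x_center), 2, x_scale, `/`)
  ys <- (y - y_center) / y_scale

  dims <- c(ncol(x), widths, 1L)
  L <- length(dims) - 1L

  fit <- withr::with_seed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], 0,
                             sqrt(2 / dims[l])), dims[l], dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb

    perm <- sample.int(n)
    n_val <- if (control$val_fraction > 0) floor(n * control$val_fraction) else 0L
    n_val <- min(n_val, n - 1L)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- if (n_val > 0) perm[-seq_len(n_val)] else perm
    xtr <- xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
    xval <- xs[val_idx, , drop = FALSE]; yval <- ys[val_idx]

    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr0 <- control$learning_rate
    decay <- control$lr_decay %||% 0
    wd <- control$weight_decay %||% 0
    step <- 0L
    best <- list(W = W, b = b, mse = Inf)
    stall <- 0L
    ntr <- length(tr_idx)
    bs <- min(control$batch_size, ntr)
    epochs_run <- 0L

    for (epoch in seq_len(control$max_epochs)) {
      lr <- lr0 / (1 + decay * (epoch - 1))
      ord <- sample.int(ntr)
      for (start in seq(1L, ntr, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, ntr)]
        g <- mlp_grad(W, b, xtr[idx, , drop = FALSE], ytr[idx])
        step <- step + 1L
        c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$dW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$dW[[l]]^2
          W[[l]] <- W[[l]] * (1 - lr * wd) -
            lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$db[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$db[[l]]^2
          b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
        }
      }
      epochs_run <- epoch
      if (n_val > 0) {
        vm <- mean((mlp_forward(W, b, xval) - yval)^2)
        if (vm < best$mse - 1e-12) {
          best <- list(W = W, b = b, mse = vm)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= control$patience) break
        }
      }
    }
    if (n_val > 0 && is.finite(best$mse)) {
      W <- best$W; b <- best$b
    }
    # recentre the output intercept on the training partition
    resid <- ytr - mlp_forward(W, b, xtr)
    b[[L]] <- b[[L]] + mean(resid)
    list(W = W, b = b, epochs_run = epochs_run,
         holdout_mse = if (n_val > 0) best$mse * y_scale^2 else NA_real_)
  })

  structure(list(widths = widths,
                 W = fit$W, b = fit$b,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 seed = as.integer(seed),
                 epochs_run = fit$epochs_run,
                 holdout_mse = fit$holdout_mse,
                 control = control),
            class = "mlp_fit")
}

mlp_predict <- function(fit, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  xs <- sweep(sweep(x, 2, fit$x_center), 2, fit$x_scale, `/`)
  mlp_forward(fit$W, fit$b, xs) * fit$y_scale + fit$y_center
}

# total trainable parameter count of a width sequence for d inputs
mlp_n_params <- function(widths, d) {
  dims <- c(d, widths, 1L)
  sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
}
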