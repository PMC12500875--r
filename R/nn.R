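# Minimal feedforward network engine: dense layers, ReLU hidden units,
# linear output, minibatch Adam, L2 penalty on weights (not biases),
# optional early stopping on a validation set with best-weight restore.
# Sized for the small tabular problems this package targets (hundreds of
# rows, a handful of features); everything is plain vectorized R.

.mlp_init <- function(sizes, seed) {
  set.seed(seed)
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for ReLU stacks
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

.mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% par$W[[l]]
    Z <- sweep(Z, 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

.mlp_grad <- function(par, X, Y, l2) {
  L <- length(par$W)
  A <- .mlp_forward(par, X)
  nb <- nrow(X)
  delta <- 2 * (A[[L + 1]] - Y) / (nb * ncol(Y))
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta) + 2 * l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

.mse <- function(pred, Y) mean((pred - Y)^2)
.mae <- function(pred, Y) mean(abs(pred - Y))

# Fit a multilayer perceptron.  X, Y are matrices (Y may have several
# columns, as in the autoencoder).  When `val` (list with X, Y) is given,
# training stops after `patience` epochs without validation-MSE improvement
# and the best weights are restored.
.mlp_fit <- function(X, Y, hidden, lr = 1e-3, l2 = 1e-4, epochs = 1000,
                     batch_size = 32, patience = 50, val = NULL, seed = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  sizes <- c(ncol(X), hidden, ncol(Y))
  par <- .mlp_init(sizes, seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; epsadam <- 1e-8
  t_step <- 0
  n <- nrow(X)
  trace <- data.frame(epoch = integer(0), train_mse = numeric(0),
                      train_mae = numeric(0), val_mse = numeric(0),
                      val_mae = numeric(0))
  best <- list(val = Inf, par = par, epoch = 0)
  wait <- 0
  diverged <- FALSE
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      g <- .mlp_grad(par, X[idx, , drop = FALSE], Y[idx, , drop = FALSE], l2)
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
        par$W[[l]] <- par$W[[l]] -
          lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + epsadam)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
        par$b[[l]] <- par$b[[l]] -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + epsadam)
      }
    }
    pred <- .mlp_forward(par, X)[[L + 1]]
    tr_mse <- .mse(pred, Y); tr_mae <- .mae(pred, Y)
    if (!is.finite(tr_mse)) { diverged <- TRUE; break }
    va_mse <- NA_real_; va_mae <- NA_real_
    if (!is.null(val)) {
      vp <- .mlp_forward(par, as.matrix(val$X))[[L + 1]]
      va_mse <- .mse(vp, as.matrix(val$Y)); va_mae <- .mae(vp, as.matrix(val$Y))
      if (va_mse < best$val - 1e-12) {
        best <- list(val = va_mse, par = par, epoch = ep)
        wait <- 0
      } else {
        wait <- wait + 1
      }
    }
    trace[nrow(trace) + 1, ] <- list(ep, tr_mse, tr_mae, va_mse, va_mae)
    if (!is.null(val) && wait >= patience) break
  }
  if (!is.null(val) && is.finite(best$val)) par <- best$par
  structure(list(par = par, trace = trace, diverged = diverged,
                 best_epoch = if (is.null(val)) nrow(trace) else best$epoch,
                 hidden = hidden, seed = seed),
            class = "buckpi_mlp")
}

.mlp_predict_mat <- function(net, X) {
  .mlp_forward(net$par, as.matrix(X))[[length(net$par$W) + 1]]
}

# Activations at a given hidden layer (1-based), used as autoencoder
# latent features.
.mlp_activations <- function(net, X, layer) {
  .mlp_forward(net$par, as.matrix(X))[[layer + 1]]
}
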