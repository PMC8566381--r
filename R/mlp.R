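# Small fully-connected feed-forward network for binary nodal polarity:
# ReLU hidden layers, 2-way softmax output, cross-entropy loss, full-batch
# Adam, early stopping on validation loss. Sized for 4-9 input features and
# a few thousand rows; plain matrix arithmetic keeps it dependency-free and
# deterministic under set.seed().

mlp_fit <- function(x, y, x_val, y_val,
                    hidden = c(64L, 64L, 32L),
                    lr = 0.01, max_epochs = 400L, patience = 20L,
                    seed = 1L) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  set.seed(seed)
  sizes <- c(ncol(x), hidden, 2L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for the rectified layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  onehot <- function(y) cbind(1 - y, y)  # column 2 = class 1 (axon)
  Y <- onehot(y)

  forward <- function(W, b, x) {
    a <- vector("list", L + 1L)
    a[[1L]] <- x
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], "+")
      a[[l + 1L]] <- if (l < L) pmax(z, 0) else z
    }
    a
  }
  softmax <- function(z) {
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  }
  xent <- function(p, Y) -mean(rowSums(Y * log(pmax(p, 1e-12))))

  best <- list(W = W, b = b, loss = Inf, epoch = 0L)
  Yv <- onehot(y_val)
  wait <- 0L; t <- 0
  history <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    a <- forward(W, b, x)
    p <- softmax(a[[L + 1L]])
    delta <- (p - Y) / nrow(x)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(a[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
    }
    t <- t + 1
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - beta1^t)) /
        (sqrt(vW[[l]] / (1 - beta2^t)) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - beta1^t)) /
        (sqrt(vb[[l]] / (1 - beta2^t)) + eps)
    }
    pv <- softmax(forward(W, b, x_val)[[L + 1L]])
    vloss <- xent(pv, Yv)
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(W = W, b = b, loss = vloss, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  structure(
    list(W = best$W, b = best$b, hidden = hidden,
         best_epoch = best$epoch, val_loss = best$loss,
         history = history),
    class = "npin_mlp"
  )
}

mlp_predict <- function(fit, x) {
  W <- fit$W; b <- fit$b
  L <- length(W)
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% W[[l]], 2L, b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  z <- a - apply(a, 1L, max)
  e <- exp(z)
  (e / rowSums(e))[, 2L]  # probability of class 1 (axon)
}
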