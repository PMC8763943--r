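# Fully connected feedforward network: ReLU hidden layers, softmax output,
# categorical cross-entropy, Adam. Dense matrix algebra only; row = sample.

mlp_init <- function(d_in, hidden, n_out) {
  sizes <- c(d_in, hidden, n_out)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    limit <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
    W[[l]] <- matrix(
      runif(fan_in * fan_out, -limit, limit),
      nrow = fan_in, ncol = fan_out
    )
    b[[l]] <- rep(0, fan_out)
  }
  list(W = W, b = b, sizes = sizes)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# returns hidden activations (list, post-ReLU) and output probabilities
mlp_forward <- function(params, X) {
  L <- length(params$W)
  A <- vector("list", L - 1L)
  a <- X
  for (l in seq_len(L - 1L)) {
    a <- pmax(a %*% params$W[[l]] + rep(params$b[[l]], each = nrow(a)), 0)
    A[[l]] <- a
  }
  z_out <- a %*% params$W[[L]] + rep(params$b[[L]], each = nrow(a))
  list(hidden = A, probs = softmax_rows(z_out))
}

mlp_grad <- function(params, X, Y) {
  L <- length(params$W)
  fw <- mlp_forward(params, X)
  acts <- c(list(X), fw$hidden)
  n <- nrow(X)
  delta <- (fw$probs - Y) / n  # d(mean CE)/d(z_out)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * (acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb, loss = -mean(rowSums(Y * log(pmax(fw$probs, 1e-12)))))
}

adam_init <- function(params) {
  zero_like <- function(x) {
    lapply(x, function(p) if (is.matrix(p)) 0 * p else rep(0, length(p)))
  }
  list(
    mW = zero_like(params$W), vW = zero_like(params$W),
    mb = zero_like(params$b), vb = zero_like(params$b),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# seed-deterministic minibatch training; X rows samples, Y one-hot.
# Weight init and per-epoch permutations are drawn from R's RNG under the
# seed; the epoch/batch loop itself runs in compiled code.
mlp_train <- function(X, Y, hidden, epochs, batch_size, learning_rate,
                      beta1, beta2, seed) {
  stopifnot(nrow(X) == nrow(Y))
  withr::with_seed(seed, {
    params <- mlp_init(ncol(X), hidden, ncol(Y))
    n <- nrow(X)
    perms <- t(vapply(seq_len(epochs), function(ep) sample.int(n), integer(n)))
    fit <- .cpp_mlp_train(
      params$W, params$b, X, Y, perms, as.integer(batch_size),
      learning_rate, beta1, beta2
    )
    list(
      W = fit$W, b = map(fit$b, as.numeric), sizes = params$sizes,
      loss_history = as.numeric(fit$loss_history)
    )
  })
}

mlp_predict_proba <- function(params, X) {
  mlp_forward(params, X)$probs
}

mlp_embedding <- function(params, X) {
  fw <- mlp_forward(params, X)
  fw$hidden[[length(fw$hidden)]]
}
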