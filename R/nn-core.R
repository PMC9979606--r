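# Shared dense-network machinery for the deep models: plain matrix-based
# multilayer perceptrons (tanh hidden layers, linear output), reverse-mode
# gradients, and first-order optimizers with deterministic, seeded state.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    s <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -s, s),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  # only trainable arrays live here: the list is flattened into the
  # optimizer's parameter vector and must mirror the gradient structure
  list(W = W, b = b)
}

mlp_forward <- function(net, X, activation = "tanh") {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))   # cheap bias broadcast
    A[[l + 1]] <- if (l < L && activation == "tanh") tanh(Z) else Z
  }
  list(out = A[[L + 1]], A = A, activation = activation)
}

# dOut: gradient of the loss w.r.t. the network output (n x out_dim).
# Returns parameter gradients and the gradient w.r.t. the input matrix.
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L && fw$activation == "tanh")
      delta <- delta * (1 - fw$A[[l + 1]]^2)
    dW[[l]] <- crossprod(fw$A[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = delta)
}

# Flatten/unflatten helpers let optimizers treat heterogeneous parameter
# collections (lists of matrices/vectors, arbitrarily nested) uniformly.
flatten_params <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

unflatten_params <- function(template, v) {
  pos <- 0L
  rebuild <- function(p) {
    if (is.numeric(p)) {
      n <- length(p)
      out <- v[pos + seq_len(n)]
      pos <<- pos + n
      if (is.matrix(p)) dim(out) <- dim(p)
      return(out)
    }
    lapply(p, rebuild)
  }
  rebuild(template)
}

opt_init <- function(theta, method = c("adam", "momentum"), lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     momentum = 0.9) {
  method <- match.arg(method)
  n <- length(theta)
  list(method = method, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       momentum = momentum, m = numeric(n), v = numeric(n), t = 0L)
}

opt_step <- function(state, theta, grad) {
  state$t <- state$t + 1L
  if (state$method == "adam") {
    state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
    state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
    mhat <- state$m / (1 - state$beta1^state$t)
    vhat <- state$v / (1 - state$beta2^state$t)
    theta <- theta - state$lr * mhat / (sqrt(vhat) + state$eps)
  } else {
    state$m <- state$momentum * state$m - state$lr * grad
    theta <- theta + state$m
  }
  list(state = state, theta = theta)
}

# Derive a child seed from a master seed; kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1009 * as.numeric(k)) %%
               2147483587)
}

rmse_of <- function(x) sqrt(mean(x^2))

split_indices <- function(ds) {
  if (!"split" %in% names(ds))
    stop("dataset needs a 'split' column (see split_dataset)", call. = FALSE)
  list(train = which(ds$split == "train"),
       validation = which(ds$split == "validation"),
       test = which(ds$split == "test"))
}

# kcal/mol RMSE report on the three splits, given scaled residual vectors and
# the energy half-range in Hartree.
split_rmse_report <- function(res_scaled, idx, half_range) {
  out <- vapply(idx, function(ii) {
    if (!length(ii)) return(NA_real_)
    hartree_to_kcalmol(rmse_of(res_scaled[ii]) * half_range)
  }, numeric(1))
  names(out) <- names(idx)
  out
}
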