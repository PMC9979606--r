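#' Atom-decomposed symmetry-function network
#'
#' The molecular energy is decomposed into a sum of effective atomic
#' energies, `E = sum_i E_i`, with equal weight; each `E_i` is produced by a
#' feed-forward network of the atom's element applied to that atom's
#' symmetry-function feature vector, so the model inherits invariance under
#' rigid motions and permutations of identical elements from the
#' descriptors. Features are standardized (zero mean, unit variance on the
#' training split) and energies min-max scaled to \[-1, 1\] before fitting.
#' Training is first-order gradient descent (Adam by default, classic
#' momentum available) with validation-based checkpointing: the returned
#' weights are those of the best validation epoch.
#'
#' @param data labeled-dataset data frame with a `split` column (see
#'   [split_dataset]); energies in Hartree.
#' @param hidden hidden-layer widths of the heavy-atom (C, N, O) networks.
#' @param hidden_h hidden-layer widths of the H network (defaults to
#'   `hidden`).
#' @param descriptors a `descriptor_set`; the default grids are used when
#'   omitted.
#' @param rc cutoff radius used when building the default descriptor set.
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param optimizer `"adam"` or `"momentum"`.
#' @param activation hidden-layer activation: `"tanh"` (default) or
#'   `"linear"` (identity; the network collapses to a linear model, useful
#'   for diagnostics and linear targets).
#' @param batch mini-batch size; batches larger than the training set fall
#'   back to full-batch training.
#' @param eval_every validation-checkpoint interval in epochs.
#' @param seed master seed.
#' @return object of class `bpnn` with `$rmse` (kcal/mol per split),
#'   `$descriptors`, per-element networks and scalers.
#' @export
bpnn <- function(data, hidden = c(64, 64, 64, 64), hidden_h = NULL,
                 descriptors = NULL, rc = 3.5, epochs = 2000, lr = 3e-3,
                 optimizer = c("adam", "momentum"),
                 activation = c("tanh", "linear"), batch = 2000,
                 eval_every = 10, seed = 1) {
  optimizer <- match.arg(optimizer)
  activation <- match.arg(activation)
  if (is.null(descriptors)) descriptors <- build_descriptor_set(rc = rc)
  if (is.null(hidden_h)) hidden_h <- hidden
  if (anyNA(data$energy)) stop("all energies must be set", call. = FALSE)
  idx <- split_indices(data)
  feats <- featurize_dataset(data, descriptors)
  elements <- names(feats)
  scalers <- lapply(feats, function(F) {
    mu <- colMeans(F[idx$train, , drop = FALSE])
    sd <- apply(F[idx$train, , drop = FALSE], 2, stats::sd)
    list(mu = mu, sd = ifelse(sd < 1e-12, 1, sd))
  })
  Fs <- mapply(function(F, s) sweep(sweep(F, 2, s$mu), 2, s$sd, "/"),
               feats, scalers, SIMPLIFY = FALSE)
  sc_e <- scaling_params(data$energy[idx$train], allow_constant = TRUE)
  y <- scale_minmax(data$energy, sc_e)
  set.seed(derive_seed(seed, 1))
  nf <- ncol(Fs[[1]])
  nets <- lapply(elements, function(e) {
    h <- if (e == "H") hidden_h else hidden
    mlp_init(c(nf, h, 1))
  })
  names(nets) <- elements

  fwd_sum <- function(nets, rows) {
    fws <- lapply(elements, function(e)
      mlp_forward(nets[[e]], Fs[[e]][rows, , drop = FALSE], activation))
    names(fws) <- elements
    yhat <- Reduce(`+`, lapply(fws, function(f) as.vector(f$out)))
    list(yhat = yhat, fws = fws)
  }
  grad_fn <- function(nets, rows) {
    f <- fwd_sum(nets, rows)
    r <- f$yhat - y[rows]
    dOut <- matrix(2 * r / length(rows), ncol = 1)
    g <- lapply(elements, function(e)
      mlp_backward(nets[[e]], f$fws[[e]], dOut)[c("dW", "db")])
    names(g) <- elements
    list(grad = g, loss = mean(r^2))
  }
  fit <- train_checkpointed(
    params = nets, grad_fn = grad_fn,
    train_rows = idx$train, val_rows = idx$validation,
    predict_rows = function(nets, rows) fwd_sum(nets, rows)$yhat,
    y = y, epochs = epochs, lr = lr, optimizer = optimizer,
    batch = batch, eval_every = eval_every, seed = derive_seed(seed, 2))
  nets <- fit$params
  # the molecular energy is linear in every output layer, so the readout
  # admits an exact ridge refit; kept only when validation agrees
  nets <- refit_linear_readout(
    nets, design_fn = function(nets, rows) {
      do.call(cbind, lapply(elements, function(e) {
        fw <- mlp_forward(nets[[e]], Fs[[e]][rows, , drop = FALSE],
                          activation)
        cbind(fw$A[[length(nets[[e]]$W)]], 1)
      }))
    },
    set_fn = function(nets, beta) {
      off <- 0L
      for (e in elements) {
        L <- length(nets[[e]]$W)
        h <- nrow(nets[[e]]$W[[L]])
        nets[[e]]$W[[L]] <- matrix(beta[off + seq_len(h)], h, 1)
        nets[[e]]$b[[L]] <- beta[off + h + 1]
        off <- off + h + 1L
      }
      nets
    },
    predict_rows = function(nets, rows) fwd_sum(nets, rows)$yhat,
    y = y, idx = idx)
  res_all <- fwd_sum(nets, seq_len(nrow(data)))$yhat - y
  half_range <- (sc_e$x_max - sc_e$x_min) / 2
  structure(list(descriptors = descriptors, nets = nets,
                 feature_scalers = scalers,
                 scaling = list(energy = sc_e),
                 hidden = hidden, hidden_h = hidden_h,
                 activation = activation,
                 rmse = split_rmse_report(res_all, idx, half_range),
                 residuals_hartree = res_all * half_range,
                 split = data$split,
                 history = fit$history, seed = seed,
                 dataset_hash = dataset_hash(data),
                 n = stats::setNames(lengths(idx), names(idx)),
                 call = match.call()),
            class = "bpnn")
}

# Exact ridge least-squares refit of the linear readout (all output-layer
# weights and biases jointly); the update is kept only if it does not hurt
# the validation RMSE.
refit_linear_readout <- function(params, design_fn, set_fn, predict_rows,
                                 y, idx, ridge = 1e-8) {
  X <- design_fn(params, idx$train)
  yt <- y[idx$train]
  beta <- tryCatch({
    A <- crossprod(X) + ridge * diag(ncol(X))
    as.vector(solve(A, crossprod(X, yt)))
  }, error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) return(params)
  cand <- set_fn(params, beta)
  vr <- if (length(idx$validation)) idx$validation else idx$train
  v_old <- rmse_of(predict_rows(params, vr) - y[vr])
  v_new <- rmse_of(predict_rows(cand, vr) - y[vr])
  if (is.finite(v_new) && v_new <= v_old) cand else params
}

# Shared gradient-descent driver with validation checkpointing and
# halve-the-step recovery from non-finite losses.
train_checkpointed <- function(params, grad_fn, train_rows, val_rows,
                               predict_rows, y, epochs, lr, optimizer,
                               batch, eval_every, seed) {
  theta <- flatten_params(params)
  state <- opt_init(theta, optimizer, lr = lr)
  set.seed(seed)
  best_theta <- theta
  best_val <- Inf
  history <- numeric(0)
  blowups <- 0L
  full_batch <- batch >= length(train_rows)
  for (epoch in seq_len(epochs)) {
    # step decay sharpens the late-stage fit without a tuned schedule
    if (epoch == ceiling(epochs / 2) || epoch == ceiling(3 * epochs / 4))
      state$lr <- state$lr * 0.3
    rows <- if (full_batch) train_rows
            else sample(train_rows, batch)
    g <- grad_fn(unflatten_params(params, theta), rows)
    if (!is.finite(g$loss)) {
      blowups <- blowups + 1L
      if (blowups > 25L)
        stop(errorCondition(
          paste0("training diverged: persistent non-finite loss (epoch ",
                 epoch, ")"),
          class = c("hcnopes_numerical_error", "error")))
      state$lr <- state$lr / 2
      theta <- best_theta
      state$m[] <- 0; state$v[] <- 0
      next
    }
    upd <- opt_step(state, theta, flatten_params(g$grad))
    state <- upd$state
    theta <- upd$theta
    if (epoch %% eval_every == 0 || epoch == epochs) {
      vr <- if (length(val_rows)) val_rows else train_rows
      yh <- predict_rows(unflatten_params(params, theta), vr)
      v <- rmse_of(yh - y[vr])
      history <- c(history, v)
      if (is.finite(v) && v < best_val) {
        best_val <- v
        best_theta <- theta
      }
    }
  }
  list(params = unflatten_params(params, best_theta), history = history,
       best_val = best_val)
}

bpnn_atomic_scaled <- function(object, feats) {
  elements <- names(object$nets)
  vapply(elements, function(e) {
    s <- object$feature_scalers[[e]]
    Fz <- sweep(sweep(feats[[e]], 2, s$mu), 2, s$sd, "/")
    as.vector(mlp_forward(object$nets[[e]], Fz,
                          object$activation %||% "tanh")$out)
  }, numeric(nrow(feats[[1]])))
}

#' Predict energies from a fitted atom-decomposed network
#'
#' @param object a fitted `bpnn`.
#' @param newdata an ic frame, a single `mol_geometry`, or a list of
#'   geometries. Geometries may contain repeated elements; every atom is
#'   routed through the network of its element.
#' @param peratom if `TRUE`, attach the per-atom energy matrix (Hartree,
#'   equal split of the scaling offset) as attribute `"peratom"`.
#' @param ... unused.
#' @return energies in Hartree.
#' @export
predict.bpnn <- function(object, newdata, peratom = FALSE, ...) {
  sc_e <- object$scaling$energy
  half <- (sc_e$x_max - sc_e$x_min) / 2
  if (inherits(newdata, "mol_geometry")) newdata <- list(newdata)
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, TRUE, "mol_geometry"))) {
    per <- t(vapply(newdata, function(g) {
      fm <- featurize_structure(g, object$descriptors)
      vapply(seq_len(nrow(fm)), function(k) {
        e <- g$elements[k]
        if (is.null(object$nets[[e]]))
          stop("no network for element ", e, call. = FALSE)
        s <- object$feature_scalers[[e]]
        fz <- (fm[k, ] - s$mu) / s$sd
        as.vector(mlp_forward(object$nets[[e]], matrix(fz, 1),
                              object$activation %||% "tanh")$out)
      }, numeric(1))
    }, numeric(4)))
  } else {
    feats <- featurize_dataset(newdata, object$descriptors)
    per <- bpnn_atomic_scaled(object, feats)
    per <- matrix(per, ncol = length(object$nets),
                  dimnames = list(NULL, names(object$nets)))
  }
  tot <- unscale_minmax(rowSums(per), sc_e)
  if (peratom) {
    off <- (sc_e$x_min + half) / ncol(per)
    attr(tot, "peratom") <- per * half + off
  }
  tot
}

#' @export
print.bpnn <- function(x, ...) {
  cat("Atom-decomposed symmetry-function PES (",
      descriptor_counts(x$descriptors)["total"],
      " features/atom; heavy-atom nets ",
      paste(x$hidden, collapse = "x"), ")\n", sep = "")
  cat("RMSE (kcal/mol):",
      paste(names(x$rmse), format(x$rmse, digits = 4), collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
summary.bpnn <- function(object, ...) {
  print(object)
  print(object$descriptors)
  cat("points: ", paste(names(object$n), object$n, collapse = "  "), "\n")
  cat("validation-RMSE history (scaled units), last 5:\n")
  print(utils::tail(round(object$history, 6), 5))
  invisible(object)
}

#' @export
residuals.bpnn <- function(object, ...) {
  object$residuals_hartree
}

#' @export
plot.bpnn <- function(x, ...) {
  graphics::plot(seq_along(x$history) , x$history,
                 type = "l", log = "y", xlab = "checkpoint",
                 ylab = "validation RMSE (scaled)",
                 main = "BPNN training history", ...)
  invisible(x)
}
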