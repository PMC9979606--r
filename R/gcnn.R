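#' Gaussian radial basis with smooth cutoff
#'
#' Expands a distance into `n_basis` Gaussians with centers uniformly
#' spanning `(0, R_c]`, widths chosen so adjacent Gaussians cross at half
#' maximum, each multiplied by [cutoff_fn]; all components vanish beyond the
#' cutoff and are continuous across it.
#'
#' @param r distances (Angstrom, >= 0).
#' @param rc cutoff radius (Angstrom).
#' @param n_basis number of basis functions (>= 2).
#' @return `length(r) x n_basis` matrix.
#' @export
radial_basis <- function(r, rc, n_basis) {
  stopifnot(rc > 0, n_basis >= 2)
  centers <- rc * seq_len(n_basis) / n_basis
  delta <- rc / n_basis
  eta <- 4 * log(2) / delta^2
  fc <- cutoff_fn(r, rc)
  out <- vapply(centers, function(ct) exp(-eta * (r - ct)^2) * fc,
                numeric(length(r)))
  matrix(out, nrow = length(r))
}

# 12 ordered pairs (i, j), i != j, among the four atoms of one molecule.
local_pairs <- function() {
  g <- expand.grid(i = 1:4, j = 1:4)
  g[g$i != g$j, ]
}

# n x 12 matrix of pair distances for an ic frame (columns follow
# local_pairs() order; atom order H, N, C, O).
pair_distance_matrix <- function(ics) {
  pos <- batch_positions(ics)
  lp <- local_pairs()
  out <- vapply(seq_len(nrow(lp)), function(p) {
    sqrt(rowSums((pos[[lp$i[p]]] - pos[[lp$j[p]]])^2))
  }, numeric(nrow(pos[[1]])))
  matrix(out, nrow = nrow(pos[[1]]))
}

gcnn_init_params <- function(cfg) {
  w <- cfg$width
  list(
    emb = matrix(stats::runif(4 * w, -0.5, 0.5), 4, w,
                 dimnames = list(c("H", "N", "C", "O"), NULL)),
    blocks = lapply(seq_len(cfg$depth), function(t) list(
      pi = mlp_init(c(2 * w, cfg$pi_hidden, w * cfg$n_basis)),
      pp = mlp_init(c(w, cfg$pp_hidden, w)),
      ii = mlp_init(c(w, cfg$ii_hidden, w)))),
    en = mlp_init(c(w, cfg$en_hidden, 1)))
}

# Forward pass over ns molecules. Dp: ns x 12 pair distances; elem_idx:
# embedding row (1..4) per atom, molecule-major. Returns scaled energies and
# (optionally) all caches needed for the backward pass.
gcnn_forward <- function(params, cfg, Dp, elem_idx, keep_cache = FALSE) {
  ns <- nrow(Dp)
  w <- cfg$width
  natom <- 4L * ns
  lp <- local_pairs()
  npair <- nrow(lp) * ns
  ia <- unlist(lapply(lp$i, function(i) (seq_len(ns) - 1L) * 4L + i))
  ja <- unlist(lapply(lp$j, function(j) (seq_len(ns) - 1L) * 4L + j))
  B <- radial_basis(as.vector(Dp), cfg$rc, cfg$n_basis)
  P <- params$emb[elem_idx, , drop = FALSE]
  cache <- list(ia = ia, ja = ja, B = B, blocks = vector("list", cfg$depth))
  for (t in seq_len(cfg$depth)) {
    blk <- params$blocks[[t]]
    U <- cbind(P[ia, , drop = FALSE], P[ja, , drop = FALSE])
    fpi <- mlp_forward(blk$pi, U)
    H <- fpi$out                        # npair x (w * n_basis), basis-major
    M <- matrix(0, npair, w)
    for (b in seq_len(cfg$n_basis))
      M <- M + H[, (b - 1L) * w + seq_len(w), drop = FALSE] * B[, b]
    S <- rowsum(M, ia, reorder = TRUE)  # natom x w (all atoms present)
    fpp <- mlp_forward(blk$pp, S)
    fii <- mlp_forward(blk$ii, fpp$out)
    Pn <- P + fii$out
    if (keep_cache)
      cache$blocks[[t]] <- list(fpi = fpi, fpp = fpp, fii = fii)
    P <- Pn
  }
  fen <- mlp_forward(params$en, P)
  peratom <- as.vector(fen$out)
  yhat <- as.vector(rowsum(peratom, rep(seq_len(ns), each = 4L)))
  if (keep_cache) {
    cache$fen <- fen
    cache$elem_idx <- elem_idx
  }
  list(yhat = yhat, peratom = peratom, cache = if (keep_cache) cache)
}

# Reverse-mode gradient; dy is d(loss)/d(yhat) per molecule. Returns a
# gradient structure mirroring the parameter structure exactly.
gcnn_backward <- function(params, cfg, cache, dy) {
  ns <- length(dy)
  w <- cfg$width
  dPer <- matrix(rep(dy, each = 4L), ncol = 1)
  ben <- mlp_backward(params$en, cache$fen, dPer)
  dP <- ben$dX
  gblocks <- vector("list", cfg$depth)
  for (t in rev(seq_len(cfg$depth))) {
    blk <- params$blocks[[t]]
    cb <- cache$blocks[[t]]
    bii <- mlp_backward(blk$ii, cb$fii, dP)
    bpp <- mlp_backward(blk$pp, cb$fpp, bii$dX)
    dM <- bpp$dX[cache$ia, , drop = FALSE]     # unpool: gather per pair
    dH <- matrix(0, nrow(dM), w * cfg$n_basis)
    for (b in seq_len(cfg$n_basis))
      dH[, (b - 1L) * w + seq_len(w)] <- dM * cache$B[, b]
    bpi <- mlp_backward(blk$pi, cb$fpi, dH)
    dP <- dP +
      rowsum(bpi$dX[, seq_len(w), drop = FALSE], cache$ia,
             reorder = TRUE) +
      rowsum(bpi$dX[, w + seq_len(w), drop = FALSE], cache$ja,
             reorder = TRUE)
    gblocks[[t]] <- list(pi = bpi[c("dW", "db")],
                         pp = bpp[c("dW", "db")],
                         ii = bii[c("dW", "db")])
  }
  demb <- rowsum(dP, cache$elem_idx, reorder = TRUE)
  if (nrow(demb) < 4) {                 # elements absent from this batch
    full <- matrix(0, 4, w)
    full[as.integer(rownames(demb)), ] <- demb
    demb <- full
  }
  list(emb = demb, blocks = gblocks, en = ben[c("dW", "db")])
}

#' Graph-convolutional atomic network
#'
#' A learnable-radial-filter message-passing model: atoms start from a
#' per-element embedding; each of `depth` interaction blocks builds pairwise
#' interactions from the two endpoint node features (pi-network), contracts
#' them with the radial-basis expansion of the pair distance, sum-pools the
#' result back onto atoms, and updates node features through the pooling
#' (pp) and interaction-to-interaction (ii) networks with a residual
#' connection. Per-atom output (en) networks are summed into the molecular
#' energy, so predictions are invariant under rigid motions and relabeling
#' of identical elements, and the pooling makes them independent of neighbor
#' enumeration order. Energies are min-max scaled to \[-1, 1\] on the
#' training split; training is gradient descent with validation-based
#' checkpointing.
#'
#' @param data labeled-dataset data frame with a `split` column.
#' @param width node-feature dimension.
#' @param depth number of interaction blocks (>= 1).
#' @param n_basis number of radial basis functions (>= 2).
#' @param rc cutoff radius (Angstrom).
#' @param pi_hidden,pp_hidden,ii_hidden,en_hidden hidden-layer widths of the
#'   four subnetworks (empty vector = single linear layer).
#' @param epochs,lr,optimizer,batch,eval_every,seed as in [bpnn].
#' @return object of class `gcnn`.
#' @export
gcnn <- function(data, width = 32, depth = 2, n_basis = 10, rc = 5,
                 pi_hidden = width, pp_hidden = integer(),
                 ii_hidden = integer(), en_hidden = width,
                 epochs = 2000, lr = 3e-3,
                 optimizer = c("adam", "momentum"), batch = 2000,
                 eval_every = 10, seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(depth >= 1, n_basis >= 2, width >= 1)
  if (anyNA(data$energy)) stop("all energies must be set", call. = FALSE)
  cfg <- list(width = width, depth = depth, n_basis = n_basis, rc = rc,
              pi_hidden = pi_hidden, pp_hidden = pp_hidden,
              ii_hidden = ii_hidden, en_hidden = en_hidden)
  idx <- split_indices(data)
  Dp <- pair_distance_matrix(data)
  sc_e <- scaling_params(data$energy[idx$train], allow_constant = TRUE)
  y <- scale_minmax(data$energy, sc_e)
  set.seed(derive_seed(seed, 11))
  params <- gcnn_init_params(cfg)
  elem_for <- function(rows) rep(1:4, times = length(rows))
  grad_fn <- function(params, rows) {
    f <- gcnn_forward(params, cfg, Dp[rows, , drop = FALSE],
                      elem_for(rows), keep_cache = TRUE)
    r <- f$yhat - y[rows]
    g <- gcnn_backward(params, cfg, f$cache, 2 * r / length(rows))
    list(grad = g, loss = mean(r^2))
  }
  fit <- train_checkpointed(
    params = params, grad_fn = grad_fn,
    train_rows = idx$train, val_rows = idx$validation,
    predict_rows = function(params, rows)
      gcnn_forward(params, cfg, Dp[rows, , drop = FALSE],
                   elem_for(rows))$yhat,
    y = y, epochs = epochs, lr = lr, optimizer = optimizer,
    batch = batch, eval_every = eval_every, seed = derive_seed(seed, 12))
  params <- fit$params
  # the energy is linear in the atomic output layer: exact ridge refit,
  # kept only when validation agrees
  params <- refit_linear_readout(
    params, design_fn = function(params, rows) {
      f <- gcnn_forward(params, cfg, Dp[rows, , drop = FALSE],
                        elem_for(rows), keep_cache = TRUE)
      L <- length(params$en$W)
      A <- f$cache$fen$A[[L]]
      cbind(rowsum(A, rep(seq_along(rows), each = 4L)), 4)
    },
    set_fn = function(params, beta) {
      L <- length(params$en$W)
      h <- nrow(params$en$W[[L]])
      params$en$W[[L]] <- matrix(beta[seq_len(h)], h, 1)
      params$en$b[[L]] <- beta[h + 1]
      params
    },
    predict_rows = function(params, rows)
      gcnn_forward(params, cfg, Dp[rows, , drop = FALSE],
                   elem_for(rows))$yhat,
    y = y, idx = idx)
  res_all <- gcnn_forward(params, cfg, Dp, elem_for(seq_len(nrow(Dp))))$yhat -
    y
  half_range <- (sc_e$x_max - sc_e$x_min) / 2
  structure(list(config = cfg, params = params,
                 scaling = list(energy = sc_e),
                 rmse = split_rmse_report(res_all, idx, half_range),
                 residuals_hartree = res_all * half_range,
                 split = data$split,
                 history = fit$history, seed = seed,
                 dataset_hash = dataset_hash(data),
                 n = stats::setNames(lengths(idx), names(idx)),
                 call = match.call()),
            class = "gcnn")
}

#' Predict energies from a fitted graph-convolutional network
#'
#' @param object a fitted `gcnn`.
#' @param newdata ic frame, single `mol_geometry`, or list of geometries.
#' @param peratom attach the per-atom energy matrix as attribute
#'   `"peratom"` (Hartree, equal split of the scaling offset).
#' @param ... unused.
#' @return energies in Hartree.
#' @export
predict.gcnn <- function(object, newdata, peratom = FALSE, ...) {
  cfg <- object$config
  if (inherits(newdata, "mol_geometry")) newdata <- list(newdata)
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, TRUE, "mol_geometry"))) {
    lp <- local_pairs()
    Dp <- t(vapply(newdata, function(g) {
      d <- pairwise_distances(g)
      d[cbind(lp$i, lp$j)]
    }, numeric(nrow(lp))))
    elem_idx <- unlist(lapply(newdata, function(g) {
      m <- match(g$elements, c("H", "N", "C", "O"))
      if (anyNA(m))
        stop("no embedding for element(s): ",
             paste(unique(g$elements[is.na(m)]), collapse = ", "),
             call. = FALSE)
      m
    }))
  } else {
    Dp <- pair_distance_matrix(newdata)
    elem_idx <- rep(1:4, times = nrow(Dp))
  }
  f <- gcnn_forward(object$params, cfg, Dp, elem_idx)
  sc_e <- object$scaling$energy
  tot <- unscale_minmax(f$yhat, sc_e)
  if (peratom) {
    half <- (sc_e$x_max - sc_e$x_min) / 2
    off <- (sc_e$x_min + half) / 4
    attr(tot, "peratom") <- matrix(f$peratom * half + off, ncol = 4,
                                   byrow = TRUE)
  }
  tot
}

#' @export
print.gcnn <- function(x, ...) {
  cfg <- x$config
  cat("Graph-convolutional atomic PES (width ", cfg$width, ", depth ",
      cfg$depth, ", ", cfg$n_basis, " basis, Rc = ", cfg$rc, ")\n",
      sep = "")
  cat("RMSE (kcal/mol):",
      paste(names(x$rmse), format(x$rmse, digits = 4), collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
summary.gcnn <- function(object, ...) {
  print(object)
  cat("points: ", paste(names(object$n), object$n, collapse = "  "), "\n")
  cat("parameters:", length(flatten_params(object$params)), "\n")
  cat("validation-RMSE history (scaled units), last 5:\n")
  print(utils::tail(round(object$history, 6), 5))
  invisible(object)
}

#' @export
residuals.gcnn <- function(object, ...) {
  object$residuals_hartree
}

#' @export
plot.gcnn <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l", log = "y",
                 xlab = "checkpoint", ylab = "validation RMSE (scaled)",
                 main = "GCNN training history", ...)
  invisible(x)
}
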