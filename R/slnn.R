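#' Molecular single-layer sum-of-products network
#'
#' Fits the scaled energy as
#' `E_scaled(x) = c0 + sum_k c_k exp(b_k + W_k . x)`
#' over the six scaled internal coordinates. The exponential activation makes
#' the fitted surface a sum of products of one-dimensional exponentials
#' (`exp(b + sum_i w_i x_i) = e^b prod_i e^{w_i x_i}`), the form favored for
#' quantum-dynamics applications. Coordinates and energies are min-max scaled
#' to \[-1, 1\] on the training split before fitting; parameters are
#' determined by the Levenberg-Marquardt algorithm with validation-based
#' checkpointing.
#'
#' With `restarts > 1`, the fit is repeated with a fresh random
#' train/validation/test partition and fresh weight initialization per
#' restart (child seeds derived from `seed`), and the model with the lowest
#' validation RMSE is returned together with the full per-restart report.
#'
#' @param data labeled-dataset data frame (six coordinate columns plus
#'   `energy` in Hartree). An existing `split` column is honored when
#'   `restarts = 1`; otherwise fresh splits are drawn.
#' @param neurons number of exponential neurons.
#' @param epochs maximum number of Levenberg-Marquardt iterations.
#' @param restarts number of random-restart fits (default 5 for production;
#'   1 reduces to a single fit).
#' @param seed master seed; all child randomness derives from it.
#' @param fractions split fractions used when drawing fresh splits.
#' @param lambda0 initial Levenberg-Marquardt damping.
#' @param lambda_factor damping adaptation factor (multiply on rejected
#'   step, divide on accepted).
#' @param lambda_max stop once damping exceeds this.
#' @param grad_tol stop once the gradient norm falls below this.
#' @param patience epochs without validation improvement before stopping
#'   early (default `Inf`: run the full epoch budget, still returning the
#'   best-validation parameters).
#' @param init_range weights initialized uniformly in
#'   `[-init_range, init_range]`.
#' @return object of class `slnn` with weights, scaling parameters, the
#'   kcal/mol RMSE report per split (`$rmse`), and per-restart diagnostics
#'   (`$restart_report`).
#' @seealso [predict.slnn], [optimize_neurons]
#' @export
slnn <- function(data, neurons = 20, epochs = 500, restarts = 1, seed = 1,
                 fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                 lambda0 = 1e-2, lambda_factor = 10, lambda_max = 1e10,
                 grad_tol = 1e-10, patience = Inf, init_range = 0.5) {
  data <- cbind(as_ic_frame(data), data[setdiff(names(data), ic_names)])
  if (anyNA(data$energy)) stop("all energies must be set", call. = FALSE)
  if (nrow(data) < 10 * neurons)
    warning("fewer than 10 training points per neuron", call. = FALSE)
  cl <- match.call()
  fits <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    ds <- data
    if (restarts > 1 || !"split" %in% names(ds))
      ds <- split_dataset(ds, fractions, seed = derive_seed(seed, r))
    fits[[r]] <- slnn_fit_once(ds, neurons, epochs,
                               seed = derive_seed(seed, 1000 + r),
                               lambda0, lambda_factor, lambda_max,
                               grad_tol, patience, init_range)
  }
  val <- vapply(fits, function(f) f$rmse[["validation"]], numeric(1))
  if (all(!is.finite(val)))
    stop(errorCondition(
      paste0("all restarts diverged; per-restart RMSEs: ",
             paste(format(val), collapse = ", ")),
      class = c("hcnopes_numerical_error", "error")))
  best <- which.min(ifelse(is.finite(val), val, Inf))
  model <- fits[[best]]
  model$restart_report <- data.frame(
    restart = seq_len(restarts),
    train = vapply(fits, function(f) f$rmse[["train"]], numeric(1)),
    validation = val,
    test = vapply(fits, function(f) f$rmse[["test"]], numeric(1)))
  model$seed <- seed
  model$dataset_hash <- dataset_hash(data)
  model$call <- cl
  model
}

slnn_fit_once <- function(ds, neurons, epochs, seed, lambda0, lambda_factor,
                          lambda_max, grad_tol, patience, init_range) {
  idx <- split_indices(ds)
  coords <- as.matrix(ds[ic_names])
  sc_x <- scaling_params(coords[idx$train, , drop = FALSE],
                         allow_constant = TRUE)
  sc_e <- scaling_params(ds$energy[idx$train], allow_constant = TRUE)
  X <- scale_minmax(coords, sc_x)
  y <- scale_minmax(ds$energy, sc_e)
  m <- neurons
  set.seed(seed)
  theta <- c(stats::runif(1 + 2 * m + 6 * m, -init_range, init_range))
  # random (b, W); output layer (c0, c) from linear least squares, which
  # starts each restart at the best model linear in the drawn neurons
  e0 <- exp(scale_minmax(coords[idx$train, , drop = FALSE], sc_x) %*%
              t(matrix(theta[(2 + 2 * m):(1 + 8 * m)], m, 6)) +
            matrix(theta[(2 + m):(1 + 2 * m)],
                   length(idx$train), m, byrow = TRUE))
  cf <- tryCatch(qr.coef(qr(cbind(1, e0)),
                         scale_minmax(ds$energy[idx$train], sc_e)),
                 error = function(e) NULL)
  if (!is.null(cf) && all(is.finite(cf))) theta[1:(1 + m)] <- cf
  # theta layout: c0 | c (m) | b (m) | W by input dimension (6 blocks of m)
  fwd <- function(theta, X) {
    W <- matrix(theta[(2 + 2 * m):(1 + 8 * m)], m, 6)
    z <- X %*% t(W) + matrix(theta[(2 + m):(1 + 2 * m)], nrow(X), m,
                             byrow = TRUE)
    e <- exp(z)
    list(yhat = theta[1] + as.vector(e %*% theta[2:(1 + m)]), e = e)
  }
  Xt <- X[idx$train, , drop = FALSE]
  yt <- y[idx$train]
  lambda <- lambda0
  f <- fwd(theta, Xt)
  res <- f$yhat - yt
  sse <- sum(res^2)
  if (!is.finite(sse)) stop("non-finite initial loss", call. = FALSE)
  best_theta <- theta
  best_val <- Inf
  stall <- 0L
  val_rmse <- function(theta) {
    if (!length(idx$validation)) return(NA_real_)
    yh <- fwd(theta, X[idx$validation, , drop = FALSE])$yhat
    rmse_of(yh - y[idx$validation])
  }
  for (epoch in seq_len(epochs)) {
    cvec <- theta[2:(1 + m)]
    J <- cbind(1, f$e, f$e * matrix(cvec, nrow(Xt), m, byrow = TRUE))
    for (i in 1:6)
      J <- cbind(J, Xt[, i] * f$e * matrix(cvec, nrow(Xt), m, byrow = TRUE))
    g <- crossprod(J, res)
    if (sqrt(sum(g^2)) < grad_tol) break
    H <- crossprod(J)
    # parameters whose Jacobian column vanishes (e.g. weights of a
    # coordinate held constant in the scan) are frozen: keeping them in the
    # normal equations makes the damped system hopelessly ill-conditioned
    act <- diag(H) > 1e-12 * max(diag(H))
    Ha <- H[act, act, drop = FALSE]
    dH <- pmax(diag(Ha), 1e-12)
    accepted <- FALSE
    while (!accepted && lambda <= lambda_max) {
      step_a <- tryCatch(
        solve(Ha + lambda * diag(dH, nrow = length(dH)), -g[act]),
        error = function(e) NULL)
      step <- if (is.null(step_a)) NULL else {
        s <- numeric(length(theta)); s[act] <- step_a; s
      }
      if (!is.null(step)) {
        cand <- theta + as.vector(step)
        fc <- tryCatch(fwd(cand, Xt), error = function(e) NULL)
        if (!is.null(fc)) {
          rc <- fc$yhat - yt
          sc <- sum(rc^2)
          if (is.finite(sc) && sc < sse) {
            theta <- cand; f <- fc; res <- rc; sse <- sc
            lambda <- lambda / lambda_factor
            accepted <- TRUE
          }
        }
      }
      if (!accepted) lambda <- lambda * lambda_factor
    }
    if (!accepted) break
    v <- val_rmse(theta)
    if (is.na(v) || v < best_val - 1e-15) {
      best_val <- if (is.na(v)) best_val else v
      best_theta <- theta
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  theta <- best_theta
  res_all <- fwd(theta, X)$yhat - y
  half_range <- (sc_e$x_max - sc_e$x_min) / 2
  model <- list(n_neurons = m,
                c0 = theta[1],
                c = theta[2:(1 + m)],
                b = theta[(2 + m):(1 + 2 * m)],
                W = matrix(theta[(2 + 2 * m):(1 + 8 * m)], m, 6,
                           dimnames = list(NULL, ic_names)),
                scaling = list(coords = sc_x, energy = sc_e),
                rmse = split_rmse_report(res_all, idx, half_range),
                residuals_hartree = res_all * half_range,
                split = ds$split,
                n = stats::setNames(lengths(idx), names(idx)))
  class(model) <- "slnn"
  model
}

slnn_forward_scaled <- function(object, Xs) {
  z <- Xs %*% t(object$W) +
    matrix(object$b, nrow(Xs), object$n_neurons, byrow = TRUE)
  object$c0 + as.vector(exp(z) %*% object$c)
}

#' Predict energies from a fitted SLNN
#'
#' @param object a fitted `slnn`.
#' @param newdata coordinates: anything [as_ic_frame] accepts.
#' @param ... unused.
#' @return energies in Hartree. Inputs outside the training scaling range
#'   trigger an extrapolation warning (never an error).
#' @export
predict.slnn <- function(object, newdata, ...) {
  X <- as.matrix(as_ic_frame(newdata))
  warn_extrapolation(X, object$scaling$coords)
  ys <- slnn_forward_scaled(object, scale_minmax(X, object$scaling$coords))
  unscale_minmax(ys, object$scaling$energy)
}

warn_extrapolation <- function(X, sc) {
  lo <- matrix(sc$x_min, nrow(X), ncol(X), byrow = TRUE)
  hi <- matrix(sc$x_max, nrow(X), ncol(X), byrow = TRUE)
  n_out <- sum(apply(X < lo | X > hi, 1, any))
  if (n_out > 0)
    warning(n_out, " point(s) outside the training range (extrapolation)",
            call. = FALSE)
  invisible(n_out)
}

#' @export
print.slnn <- function(x, ...) {
  cat("Single-layer sum-of-products PES (", x$n_neurons, " neurons)\n",
      sep = "")
  cat("RMSE (kcal/mol):",
      paste(names(x$rmse), format(x$rmse, digits = 4), collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
summary.slnn <- function(object, ...) {
  cat("Single-layer sum-of-products potential energy surface\n")
  cat("neurons:", object$n_neurons, "  parameters:",
      1 + 8 * object$n_neurons, "\n")
  cat("points: ", paste(names(object$n), object$n, collapse = "  "), "\n")
  cat("RMSE (kcal/mol):\n")
  print(round(object$rmse, 5))
  if (!is.null(object$restart_report) && nrow(object$restart_report) > 1) {
    cat("restarts:\n")
    print(round(object$restart_report, 5))
  }
  invisible(object)
}

#' @export
coef.slnn <- function(object, ...) {
  list(c0 = object$c0, c = object$c, b = object$b, W = object$W)
}

#' @export
residuals.slnn <- function(object, ...) {
  object$residuals_hartree
}

#' @export
plot.slnn <- function(x, ...) {
  graphics::plot(x$residuals_hartree * .hartree_kcalmol,
                 col = factor(x$split),
                 xlab = "point", ylab = "residual (kcal/mol)",
                 main = "SLNN fit residuals", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Optimize the neuron count of the SLNN
#'
#' Runs the multi-restart fit for each candidate neuron count and selects
#' the one minimizing validation RMSE; the whole RMSE curve is retained.
#'
#' @param data labeled-dataset data frame.
#' @param candidates integer vector of neuron counts (length >= 1).
#' @param ... passed on to [slnn] (e.g. `restarts`, `epochs`, `seed`).
#' @return list with `best_neurons`, `model` (the winning fit) and `curve`
#'   (data frame of per-candidate split RMSEs in kcal/mol).
#' @export
optimize_neurons <- function(data, candidates, ...) {
  stopifnot(length(candidates) >= 1)
  models <- lapply(candidates, function(m) slnn(data, neurons = m, ...))
  curve <- data.frame(
    neurons = candidates,
    train = vapply(models, function(f) f$rmse[["train"]], numeric(1)),
    validation = vapply(models, function(f) f$rmse[["validation"]],
                        numeric(1)),
    test = vapply(models, function(f) f$rmse[["test"]], numeric(1)))
  best <- which.min(curve$validation)
  list(best_neurons = candidates[best], model = models[[best]],
       curve = curve)
}
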