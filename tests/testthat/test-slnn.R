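test_that("a single exponential neuron is a product of one-dimensional
           exponentials", {
  set.seed(301)
  w <- runif(6, -1, 1); b <- 0.3
  x <- runif(6, -1, 1)
  sum_form <- exp(b + sum(w * x))
  prod_form <- exp(b) * prod(exp(w * x))
  expect_equal(sum_form, prod_form, tolerance = 1e-12)
})

test_that("zero output weights give a constant surface", {
  ds <- random_ic(60, seed = 302)
  ds$energy <- runif(60, -168.6, -168.4); ds$source <- "x"
  fit <- suppressWarnings(slnn(ds, neurons = 3, epochs = 2, seed = 1))
  fit$c[] <- 0
  pred <- suppressWarnings(predict(fit, ds))
  expect_equal(stats::sd(pred), 0)
  expect_equal(unique(pred), unscale_minmax(fit$c0, fit$scaling$energy))
})

test_that("the analytic Jacobian matches finite differences", {
  set.seed(303)
  m <- 3; n <- 12
  X <- matrix(runif(n * 6, -1, 1), n, 6)
  theta <- runif(1 + 8 * m, -0.5, 0.5)
  fwd <- function(theta) {
    W <- matrix(theta[(2 + 2 * m):(1 + 8 * m)], m, 6)
    e <- exp(X %*% t(W) + matrix(theta[(2 + m):(1 + 2 * m)], n, m,
                                 byrow = TRUE))
    theta[1] + as.vector(e %*% theta[2:(1 + m)])
  }
  W <- matrix(theta[(2 + 2 * m):(1 + 8 * m)], m, 6)
  e <- exp(X %*% t(W) + matrix(theta[(2 + m):(1 + 2 * m)], n, m,
                               byrow = TRUE))
  cvec <- theta[2:(1 + m)]
  J <- cbind(1, e, e * matrix(cvec, n, m, byrow = TRUE))
  for (i in 1:6)
    J <- cbind(J, X[, i] * e * matrix(cvec, n, m, byrow = TRUE))
  h <- 1e-6
  for (p in seq_along(theta)) {
    up <- theta; up[p] <- up[p] + h
    dn <- theta; dn[p] <- dn[p] - h
    fd <- (fwd(up) - fwd(dn)) / (2 * h)
    expect_lt(max(abs(fd - J[, p])) / (1 + max(abs(J[, p]))), 1e-6)
  }
})

test_that("a constant-energy dataset is fitted exactly", {
  ds <- random_ic(80, seed = 304)
  ds$energy <- -168.42; ds$source <- "x"
  fit <- suppressWarnings(slnn(ds, neurons = 2, epochs = 50, seed = 2))
  expect_lt(fit$rmse[["train"]], 1e-8)
})

test_that("one neuron recovers y = exp(1.7 x) to numerical precision", {
  x <- seq(-1, 1, length.out = 50)
  ds <- data.frame(r1 = x + 2, r2 = 1.2, r3 = 1.2, theta1 = 100,
                   theta2 = 100, phi = 10, energy = exp(1.7 * x),
                   source = "toy")
  fit <- slnn(ds, neurons = 1, epochs = 500, restarts = 10, seed = 5)
  expect_lt(fit$rmse[["train"]], 1e-6)
})

test_that("restart selection returns the best validation model,
           deterministically", {
  ds <- basin_slice_dataset()
  f1 <- suppressWarnings(slnn(ds, neurons = 8, epochs = 60, restarts = 3,
                              seed = 17))
  f2 <- suppressWarnings(slnn(ds, neurons = 8, epochs = 60, restarts = 3,
                              seed = 17))
  expect_identical(coef(f1), coef(f2))
  expect_equal(f1$rmse[["validation"]],
               min(f1$restart_report$validation))
  expect_equal(nrow(f1$restart_report), 3)
})

test_that("training on kcal/mol-converted energies matches Hartree
           training after conversion", {
  ds <- basin_slice_dataset()
  f_ha <- suppressWarnings(slnn(ds, neurons = 6, epochs = 80, seed = 23))
  ds_kc <- ds
  ds_kc$energy <- hartree_to_kcalmol(ds$energy)
  f_kc <- suppressWarnings(slnn(ds_kc, neurons = 6, epochs = 80, seed = 23))
  p_ha <- suppressWarnings(predict(f_ha, ds))
  p_kc <- kcalmol_to_hartree(suppressWarnings(predict(f_kc, ds)))
  expect_lt(max(abs(p_ha - p_kc)) / max(abs(p_ha)), 1e-8)
})

test_that("the held-out error on a single-basin 2-D slice is chemically
           negligible", {
  ds <- basin_slice_dataset()
  fit <- suppressWarnings(slnn(ds, neurons = 20, epochs = 500,
                               restarts = 3, seed = 11))
  expect_lt(fit$rmse[["test"]], 0.5)
})

test_that("neuron-count optimization returns the full RMSE curve", {
  ds <- basin_slice_dataset()
  res <- suppressWarnings(optimize_neurons(ds, c(4, 12), epochs = 60,
                                           seed = 3))
  expect_equal(nrow(res$curve), 2)
  expect_true(res$best_neurons %in% c(4, 12))
  expect_equal(res$curve$validation[res$curve$neurons == res$best_neurons],
               res$model$rmse[["validation"]])
})

test_that("our Levenberg-Marquardt fit matches minpack's on a solvable
           problem", {
  skip_if_not_installed("minpack.lm")
  x <- seq(-1, 1, length.out = 50)
  y <- exp(1.7 * x)
  ds <- data.frame(r1 = x + 2, r2 = 1.2, r3 = 1.2, theta1 = 100,
                   theta2 = 100, phi = 10, energy = y, source = "toy")
  fit <- slnn(ds, neurons = 1, epochs = 500, restarts = 10, seed = 9)
  # independent multistart optimizer on the same scaled model class
  sc_e <- fit$scaling$energy
  ys <- scale_minmax(y, sc_e)
  resid_fn <- function(th) th[1] + th[2] * exp(th[3] + th[4] * x) - ys
  set.seed(1)
  best <- Inf
  for (k in 1:10) {
    th0 <- runif(4, -0.5, 0.5)
    # same least-squares output-layer initialization as the package
    th0[1:2] <- stats::coef(stats::lm(ys ~ exp(th0[3] + th0[4] * x)))
    r <- minpack.lm::nls.lm(th0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000))
    best <- min(best, sqrt(mean(r$fvec^2)))
  }
  half <- (sc_e$x_max - sc_e$x_min) / 2
  oracle_kcal <- hartree_to_kcalmol(best * half)
  expect_lt(oracle_kcal, 1e-6)          # the oracle solves it ...
  expect_lt(fit$rmse[["train"]], 1e-6)  # ... and so do we
  expect_lt(abs(fit$rmse[["train"]] - oracle_kcal), 1e-6)
})

test_that("prediction warns on extrapolation instead of failing", {
  ds <- basin_slice_dataset()
  fit <- suppressWarnings(slnn(ds, neurons = 5, epochs = 50, seed = 31))
  outside <- as_ic_frame(ds[1, ])
  outside$r1 <- 3.4
  expect_warning(predict(fit, outside), "extrapolation")
})
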