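small_gcnn_data <- function(seed = 501) {
  ds <- random_ic(120, seed = seed)
  ds$energy <- surrogate_energy(ds)
  ds$source <- "x"
  split_dataset(ds, seed = 1)
}

test_that("the radial basis has compact support, peaked centers, and is
           continuous across the cutoff", {
  rc <- 4; nb <- 8
  expect_true(all(radial_basis(rc + 0.01, rc, nb) == 0))
  centers <- rc * seq_len(nb) / nb
  for (b in seq_len(nb - 1)) {          # last center sits on the cutoff
    v <- radial_basis(centers[b], rc, nb)
    expect_equal(which.max(v), b)
  }
  eps <- 1e-7
  expect_lt(max(abs(radial_basis(rc - eps, rc, nb) -
                      radial_basis(rc + eps, rc, nb))), 1e-5)
})

test_that("node features are permutation-equivariant and the energy
           permutation-invariant", {
  ds <- small_gcnn_data()
  fit <- gcnn(ds, width = 8, depth = 2, n_basis = 5, epochs = 20, seed = 3)
  xyz <- rbind(c(0.2, 0, 0.9), c(0, 0, 0), c(0, 0, 1.25),
               c(1.1, 0.3, 1.9))
  g1 <- molecular_geometry(c("H", "N", "N", "O"), xyz)
  g2 <- molecular_geometry(c("H", "N", "N", "O"), xyz[c(1, 3, 2, 4), ])
  expect_equal(predict(fit, g1), predict(fit, g2), tolerance = 1e-12)
  g3 <- molecular_geometry(c("O", "N", "C", "H"), xyz[c(4, 2, 3, 1), ])
  g4 <- molecular_geometry(c("H", "C", "N", "O"), xyz[c(1, 3, 2, 4), ])
  expect_equal(predict(fit, g3), predict(fit, g4), tolerance = 1e-12)
})

test_that("rigid motions leave the prediction unchanged", {
  ds <- small_gcnn_data()
  fit <- gcnn(ds, width = 8, depth = 2, n_basis = 5, epochs = 20, seed = 3)
  set.seed(13)
  for (k in 1:10) {
    g <- internal_to_cartesian(ds[k, ])
    expect_lt(abs(predict(fit, g) - predict(fit, rigid_motion(g))), 1e-10)
  }
})

test_that("with every pair beyond the cutoff, pooling contributes nothing
           and per-atom energies still sum to the total", {
  ds <- small_gcnn_data()
  fit <- gcnn(ds, width = 8, depth = 2, n_basis = 5, rc = 2.0, epochs = 20,
              seed = 3)
  iso <- molecular_geometry(c("H", "N", "C", "O"),
                            rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0),
                                  c(6, 6, 4)))
  pred <- predict(fit, iso, peratom = TRUE)
  per <- attr(pred, "peratom")
  expect_equal(unname(rowSums(per)), as.vector(pred), tolerance = 1e-10)
  # with empty neighborhoods the energy is a sum of per-element constants
  iso2 <- molecular_geometry(c("H", "N", "C", "O"),
                             rbind(c(0, 0, 0), c(9, 0, 0), c(0, 9, 0),
                                   c(9, 9, 7)))
  expect_equal(as.vector(pred), as.vector(predict(fit, iso2)),
               tolerance = 1e-10)
})

test_that("a depth-1 model equals one manually composed interaction block
           plus output network", {
  ds <- small_gcnn_data()
  fit <- gcnn(ds, width = 6, depth = 1, n_basis = 4, epochs = 5, seed = 7)
  cfg <- fit$config
  row <- ds[3, ]
  Dp <- hcnopes:::pair_distance_matrix(row)
  # manual composition from the stored weights
  lp <- hcnopes:::local_pairs()
  P <- fit$params$emb[rep(1:4, 1), ]
  B <- radial_basis(as.vector(Dp), cfg$rc, cfg$n_basis)
  blk <- fit$params$blocks[[1]]
  U <- cbind(P[lp$i, ], P[lp$j, ])
  H <- hcnopes:::mlp_forward(blk$pi, U)$out
  M <- matrix(0, nrow(lp), cfg$width)
  for (b in seq_len(cfg$n_basis))
    M <- M + H[, (b - 1) * cfg$width + seq_len(cfg$width)] * B[, b]
  S <- rowsum(M, lp$i, reorder = TRUE)
  G <- hcnopes:::mlp_forward(blk$pp, S)$out
  D <- hcnopes:::mlp_forward(blk$ii, G)$out
  Pn <- P + D
  atom_e <- hcnopes:::mlp_forward(fit$params$en, Pn)$out
  manual <- unscale_minmax(sum(atom_e), fit$scaling$energy)
  expect_equal(as.vector(predict(fit, row)), manual, tolerance = 1e-12)
})

test_that("the full network gradient matches finite differences", {
  ds <- small_gcnn_data()
  cfg <- list(width = 5, depth = 2, n_basis = 4, rc = 4,
              pi_hidden = 5, pp_hidden = integer(), ii_hidden = integer(),
              en_hidden = 5)
  set.seed(502)
  params <- hcnopes:::gcnn_init_params(cfg)
  Dp <- hcnopes:::pair_distance_matrix(ds[1:6, ])
  y <- scale_minmax(ds$energy[1:6],
                    scaling_params(ds$energy[1:6]))
  elem <- rep(1:4, 6)
  loss <- function(params) {
    f <- hcnopes:::gcnn_forward(params, cfg, Dp, elem)
    mean((f$yhat - y)^2)
  }
  f <- hcnopes:::gcnn_forward(params, cfg, Dp, elem, keep_cache = TRUE)
  g <- hcnopes:::gcnn_backward(params, cfg, f$cache,
                               2 * (f$yhat - y) / 6)
  th <- hcnopes:::flatten_params(params)
  gth <- hcnopes:::flatten_params(g)
  expect_equal(length(th), length(gth))
  h <- 1e-6
  set.seed(503)
  for (p in sample(length(th), 25)) {
    up <- th; up[p] <- up[p] + h
    dn <- th; dn[p] <- dn[p] - h
    fd <- (loss(hcnopes:::unflatten_params(params, up)) -
             loss(hcnopes:::unflatten_params(params, dn))) / (2 * h)
    expect_lt(abs(fd - gth[p]) / max(abs(gth[p]), 1e-6), 1e-4)
  }
})

test_that("training is deterministic under a fixed seed and constant
           energies are fitted", {
  ds <- small_gcnn_data()
  f1 <- gcnn(ds, width = 6, depth = 1, n_basis = 4, epochs = 30, seed = 21)
  f2 <- gcnn(ds, width = 6, depth = 1, n_basis = 4, epochs = 30, seed = 21)
  expect_identical(f1$params, f2$params)
  dsc <- ds; dsc$energy <- -168.4
  fc <- gcnn(dsc, width = 6, depth = 1, n_basis = 4, epochs = 200,
             lr = 1e-2, seed = 2)
  expect_lt(fc$rmse[["train"]], 1e-3)
})

test_that("a single-basin model stays finite when extrapolated into a
           second basin", {
  sp <- default_surrogate()
  sets <- transfer_sets(sp)
  dsa <- split_dataset(sets$a, seed = 3)
  fit <- gcnn(dsa, width = 8, depth = 2, n_basis = 6, epochs = 50, seed = 5)
  pred_b <- predict(fit, sets$b)
  expect_true(all(is.finite(pred_b)))
})

test_that("energy is continuous as a pair crosses the cutoff", {
  ds <- small_gcnn_data()
  fit <- gcnn(ds, width = 8, depth = 2, n_basis = 5, rc = 3.0, epochs = 20,
              seed = 3)
  eps <- 1e-7
  near <- as_ic_frame(ds[1, ]); near$r1 <- 3.0 - eps
  far <- as_ic_frame(ds[1, ]); far$r1 <- 3.0 + eps
  expect_lt(abs(predict(fit, near) - predict(fit, far)), 1e-4)
})
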