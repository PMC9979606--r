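test_that("the cutoff function has the right values and support", {
  expect_equal(cutoff_fn(0, 3), 1)
  expect_equal(cutoff_fn(3, 3), 0)
  expect_equal(cutoff_fn(3.0001, 3), 0)
  expect_equal(cutoff_fn(1.5, 3), 0.5)
  # C1 at the cutoff: slope tends to zero from the left
  h <- 1e-6
  expect_lt(abs(cutoff_fn(3 - h, 3) - cutoff_fn(3, 3)) / h, 1e-5)
})

test_that("vectorized symmetry functions equal the explicit-loop oracle on
           random geometries", {
  set.seed(201)
  params <- list(
    sym_function("G2", eta = 0.5, rs = 0, rc = 3.0),
    sym_function("G2", eta = 2.0, rs = "min_rij", rc = 2.5),
    sym_function("G2", eta = 8, rs = 1.1, rc = 3.5),
    sym_function("G3", eta = 0.07, zeta = 1, gamma = 1, rc = 3.0),
    sym_function("G3", eta = 0.2, zeta = 4, gamma = -1, rc = 2.5),
    sym_function("G4", eta = 0.03, zeta = 4, gamma = 1, rc = 3.0),
    sym_function("G4", eta = 0.4, zeta = 1, gamma = -1, rc = 4.0))
  for (k in 1:100) {
    g <- random_geometry()
    for (p in params) {
      for (i in 1:4) {
        got <- if (p$kind == "G2") g2_value(g, i, p)
               else g_angular_value(g, i, p)
        expect_lt(abs(got - loop_descriptor(g, i, p)), 1e-14)
      }
    }
  }
})

test_that("features are invariant under random rigid motions", {
  dset <- build_descriptor_set(rc = 3.5, n_intervals = 4)
  set.seed(202)
  g <- internal_to_cartesian(internal_coords(1, 1.2, 1.2, 110, 150, 70))
  f0 <- featurize_structure(g, dset)
  for (k in 1:100) {
    fk <- featurize_structure(rigid_motion(g), dset)
    expect_lt(max(abs(fk - f0)), 1e-10)
  }
})

test_that("G2 at a single neighbor placed exactly at r_s equals fc(r_s)", {
  g <- molecular_geometry(c("H", "N", "C", "O"),
                          rbind(c(0, 0, 0), c(1.3, 0, 0),
                                c(9, 9, 0), c(-9, 9, 0)))
  p <- sym_function("G2", eta = 4, rs = 1.3, rc = 2.0)
  expect_equal(g2_value(g, 1, p), cutoff_fn(1.3, 2.0))
})

test_that("angular functions vanish for gamma=+1 at 180 degrees and match
           hand values at 60 degrees", {
  r <- 1.2
  lin <- molecular_geometry(c("H", "N", "C", "O"),
                            rbind(c(-r, 0, 0), c(0, 0, 0), c(r, 0, 0),
                                  c(0, 9, 9)))
  p <- sym_function("G3", eta = 0.1, zeta = 2, gamma = 1, rc = 3)
  # center N: only the H,C pair is inside the cutoff and it is collinear
  expect_equal(g_angular_value(lin, 2, p), 0, tolerance = 1e-14)
  # equilateral triple at 60 degrees, fourth atom far away
  eq <- molecular_geometry(c("H", "N", "C", "O"),
                           rbind(c(r, 0, 0),
                                 c(0, 0, 0),
                                 c(r / 2, r * sqrt(3) / 2, 0),
                                 c(20, 20, 20)))
  eta <- 0.05; rc <- 3
  p3 <- sym_function("G3", eta = eta, zeta = 1, gamma = 1, rc = rc)
  expect_equal(g_angular_value(eq, 2, p3),
               1.5 * exp(-eta * 3 * r^2) * cutoff_fn(r, rc)^3,
               tolerance = 1e-12)
  p4 <- sym_function("G4", eta = eta, zeta = 1, gamma = 1, rc = rc)
  expect_equal(g_angular_value(eq, 2, p4),
               1.5 * exp(-eta * 2 * r^2) * cutoff_fn(r, rc)^2,
               tolerance = 1e-12)
})

test_that("isolated atoms have all-zero feature vectors", {
  dset <- build_descriptor_set(rc = 2.0, n_intervals = 4)
  g <- molecular_geometry(c("H", "N", "C", "O"),
                          rbind(c(0, 0, 0), c(5, 0, 0),
                                c(0, 5, 0), c(5, 5, 3)))
  expect_true(all(featurize_structure(g, dset) == 0))
})

test_that("default grids give 35-45 radial and 60-80 total functions", {
  ct <- descriptor_counts(build_descriptor_set())
  expect_gte(ct[["g2"]], 35); expect_lte(ct[["g2"]], 45)
  expect_gte(ct[["total"]], 60); expect_lte(ct[["total"]], 80)
  # enumeration equals the product-of-grid-sizes bookkeeping
  ds2 <- build_descriptor_set(n_intervals = 9, zeta = c(1, 2, 4))
  expect_equal(unname(descriptor_counts(ds2)[["total"]]),
               5 + 5 + 10 + 3 * 2 * 5 + 3 * 2 * 4)
})

test_that("batched dataset featurization equals per-structure loops", {
  dset <- build_descriptor_set(rc = 3.5, n_intervals = 4)
  ics <- random_ic(25, seed = 203)
  batch <- featurize_dataset(ics, dset)
  for (i in seq_len(nrow(ics))) {
    g <- internal_to_cartesian(ics[i, ])
    single <- featurize_structure(g, dset)
    for (el in c("H", "N", "C", "O"))
      expect_equal(unname(batch[[el]][i, ]), unname(single[el, ]),
                   tolerance = 1e-12)
  }
})

test_that("features are continuous across the cutoff radius", {
  dset <- build_descriptor_set(rc = 3.0, n_intervals = 4)
  eps <- 1e-7
  mk <- function(r1) internal_to_cartesian(
    internal_coords(r1, 1.2, 1.2, 110, 150, 70))
  f_in <- featurize_structure(mk(3.0 - eps), dset)
  f_out <- featurize_structure(mk(3.0 + eps), dset)
  expect_lt(max(abs(f_in - f_out)), 1e-5)
})
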