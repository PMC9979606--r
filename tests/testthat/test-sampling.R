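center6 <- internal_coords(1.0, 1.21, 1.17, 124, 172, 180)

test_that("mesh-grid point counts match the analytic formula and a brute
           force enumeration", {
  ms1 <- mesh_spec(center6, vary = list(r1 = c(0.8, 1.8, 0.1)))
  expect_equal(nrow(generate_rmg(ms1)), 11)
  ms2 <- mesh_spec(center6, vary = list(phi = c(0, 360, 20),
                                        theta1 = c(40, 160, 20)))
  expect_equal(nrow(generate_rmg(ms2)), 18 * 7)
  set.seed(31)
  for (k in 1:30) {
    nvar <- sample(1:5, 1)
    coords <- sample(setdiff(hcnopes:::ic_names, "phi"), nvar)
    vary <- lapply(coords, function(nm) {
      lo <- runif(1, 1, 2); c(lo, lo + runif(1, 0.3, 2), runif(1, .1, .5))
    })
    names(vary) <- coords
    ms <- mesh_spec(internal_coords(1.5, 1.5, 1.5, 90, 90, 10), vary)
    grid <- generate_rmg(ms)
    oracle <- 1L
    for (v in vary) oracle <- oracle * length(seq(v[1], v[2], by = v[3]))
    expect_equal(nrow(grid), oracle)
    expect_false(anyDuplicated(grid[hcnopes:::ic_names]) > 0)
  }
})

test_that("oversized grids are refused with a size estimate", {
  ms <- mesh_spec(center6, vary = list(r1 = c(0.8, 3.0, 0.001),
                                       r2 = c(0.9, 3.0, 0.001)),
                  size_cap = 1e5)
  expect_error(generate_rmg(ms), "size cap")
})

test_that("filters drop the documented points and report per rule", {
  base <- data.frame(r1 = 1, r2 = 1.2, r3 = 1.2, theta1 = 120,
                     theta2 = 170, phi = 90, energy = -168.4,
                     source = "S1")
  ds <- base[rep(1, 5), ]
  ds$energy[2] <- -167.80               # above the -167.85 au ceiling
  ds$r1[3] <- 0.7                       # inside the N-H repulsive wall
  ds$r1[4] <- 0.85                      # close to the wall but retained
  ds$r2[5] <- 3.9                       # dissociating
  out <- apply_filters(ds, filter_config())
  rep_ <- attr(out, "removal_report")
  expect_equal(nrow(out), 2)            # rows 1 and 4 survive
  expect_true(all(out$r1 >= 0.8))
  expect_equal(unname(rep_["energy"]), 1)
  expect_equal(unname(rep_["r1_min"]), 1)
  expect_equal(unname(rep_["r_max"]), 1)
  ds_phi <- base; ds_phi$phi <- 270
  out_phi <- suppressWarnings(apply_filters(ds_phi, filter_config()))
  expect_equal(nrow(out_phi), 0)
})

test_that("filtering is idempotent, reports sum to removals, and matches a
           brute-force oracle on random fixtures", {
  set.seed(57)
  cfg <- filter_config()
  for (k in 1:40) {
    n <- sample(20:60, 1)
    ds <- data.frame(r1 = runif(n, 0.5, 4), r2 = runif(n, 0.5, 4),
                     r3 = runif(n, 0.5, 4), theta1 = runif(n, 0, 180),
                     theta2 = runif(n, 0, 180), phi = runif(n, 0, 360),
                     energy = runif(n, -168.6, -167.6), source = "x")
    out <- suppressWarnings(apply_filters(ds, cfg))
    rep_ <- attr(out, "removal_report")
    expect_equal(sum(rep_), nrow(ds) - nrow(out))
    keep <- ds$energy <= cfg$energy_ceiling & ds$r1 >= cfg$r1_min &
      ds$r2 >= cfg$r23_min & ds$r3 >= cfg$r23_min &
      ds$r1 <= cfg$r_max & ds$r2 <= cfg$r_max & ds$r3 <= cfg$r_max &
      ds$phi >= 0 & ds$phi <= 180
    expect_equal(nrow(out), sum(keep))
    again <- suppressWarnings(apply_filters(out, cfg))
    expect_equal(nrow(again), nrow(out))
    expect_equal(sum(attr(again, "removal_report")), 0)
  }
})

test_that("an all-pass dataset comes back unchanged with a zero report", {
  ds <- data.frame(r1 = runif(10, 1, 2), r2 = runif(10, 1, 2),
                   r3 = runif(10, 1, 2), theta1 = 100, theta2 = 150,
                   phi = 90, energy = -168.3, source = "S1")
  out <- apply_filters(ds, filter_config())
  expect_equal(out[names(ds)], ds, ignore_attr = TRUE)
  expect_true(all(attr(out, "removal_report") == 0))
})

test_that("min-max scaling hits the endpoints and inverts exactly", {
  p <- scaling_params(c(2, 10))
  expect_equal(scale_minmax(c(2, 6, 10), p), c(-1, 0, 1))
  set.seed(5)
  x <- matrix(runif(3000, -4, 9), ncol = 3)
  p2 <- scaling_params(x)
  expect_lt(max(abs(unscale_minmax(scale_minmax(x, p2), p2) - x)), 1e-12)
  expect_true(all(scale_minmax(x, p2) >= -1 & scale_minmax(x, p2) <= 1))
  expect_error(scaling_params(rep(3, 5)), "degenerate")
})

test_that("dataset splits have the right sizes, are deterministic, and
           partition the data", {
  ds <- random_ic(100)
  ds$energy <- 0; ds$source <- "x"
  s1 <- split_dataset(ds, seed = 9)
  expect_equal(unname(table(s1$split)[c("train", "validation", "test")]),
               c(80L, 10L, 10L), ignore_attr = TRUE)
  s2 <- split_dataset(ds, seed = 9)
  expect_identical(s1$split, s2$split)
  expect_equal(sort(unique(s1$split)), c("test", "train", "validation"))
  # remainder goes to train
  s3 <- split_dataset(ds[1:7, ], c(train = 0.8, validation = 0.1,
                                   test = 0.1), seed = 1)
  expect_equal(sum(s3$split == "train"), 7 - 0 - 0)
  expect_error(split_dataset(ds[1:2, ], seed = 1), "smaller")
})

test_that("stratified splits preserve per-tag fractions within one point", {
  ds <- random_ic(200)
  ds$energy <- 0
  ds$source <- rep(c("S1", "S5"), each = 100)
  s <- split_dataset(ds, seed = 4, stratify_by = "source")
  for (tag in c("S1", "S5")) {
    n_tr <- sum(s$split == "train" & s$source == tag)
    expect_lte(abs(n_tr - 80), 1)
  }
})

test_that("merging is a deduplicating union that preserves provenance", {
  a <- random_ic(50, seed = 61); a$energy <- -168.3; a$source <- "S1"
  b <- random_ic(50, seed = 62); b$energy <- -168.2; b$source <- "S5"
  ts <- random_ic(10, seed = 63); ts$energy <- -168.1; ts$source <- "TS-path"
  m <- merge_unified(list(a, b), ts, cfg = NULL)
  expect_equal(nrow(m), 110)
  expect_setequal(unique(m$source), c("S1", "S5", "TS-path"))
  m2 <- merge_unified(list(a, a), cfg = NULL)
  expect_equal(nrow(m2), 50)
  # brute-force union oracle with filters
  cfg <- filter_config(energy_ceiling = -167.0)
  m3 <- merge_unified(list(a, b, a), ts, cfg = cfg)
  all_pts <- rbind(a, b, ts)
  key <- hcnopes:::ic_key(all_pts)
  uni <- all_pts[!duplicated(key), ]
  keep <- uni$phi <= 180 & uni$r1 >= 0.8 & uni$r2 >= 0.9 & uni$r3 >= 0.9 &
    uni$r1 <= 3.5 & uni$r2 <= 3.5 & uni$r3 <= 3.5
  expect_equal(nrow(m3), sum(keep))
})

test_that("duplicate geometries with conflicting energies keep the lower", {
  a <- random_ic(5, seed = 71); a$energy <- -168.1; a$source <- "S1"
  b <- a; b$energy <- -168.3; b$source <- "S2"
  expect_warning(m <- merge_unified(list(a, b), cfg = NULL), "conflicting")
  expect_equal(nrow(m), 5)
  expect_true(all(m$energy == -168.3))
})

test_that("dihedral augmentation leaves 18 or windowed phi values", {
  ctr <- internal_coords(1, 1.2, 1.2, 120, 170, 0)
  aug <- augment_dihedral_scans(list(ctr),
                                second = list(theta1 = c(100, 140, 20)),
                                phi_step = 20, exclude_halfwidth = 0)
  expect_equal(length(unique(aug$phi)), 18)
  expect_equal(nrow(aug), 18 * 3)
  aug2 <- augment_dihedral_scans(list(ctr),
                                 second = list(theta1 = c(100, 140, 20)),
                                 phi_step = 20, exclude_halfwidth = 30)
  expect_equal(length(unique(aug2$phi)), 15)   # +/-30 window drops 3 of 18
  expect_true(all(aug2$source == "dihedral-augmentation"))
  expect_warning(
    augment_dihedral_scans(list(ctr),
                           second = list(theta1 = c(100, 140, 20)),
                           exclude_halfwidth = 180),
    "full circle")
})

test_that("transition paths interpolate between centers", {
  a <- internal_coords(1, 1.2, 1.2, 120, 170, 350)
  b <- internal_coords(1.4, 1.3, 1.2, 60, 100, 20)
  p <- ts_path(a, b, n = 9)
  expect_equal(nrow(p), 9)
  expect_true(all(p$source == "TS-path"))
  expect_true(all(p$r1 > 1 & p$r1 < 1.4))
  # dihedral takes the short arc through 0, never the long way round
  expect_true(all(p$phi > 340 | p$phi < 25))
})

test_that("dataset CSV round trip preserves content and records the seed", {
  ds <- random_ic(20, seed = 81)
  ds$energy <- runif(20); ds$source <- "S1"
  tf <- tempfile(fileext = ".csv")
  write_dataset(ds, tf, seed = 42)
  expect_match(readLines(tf, n = 1), "seed=42")
  back <- read_dataset(tf)
  expect_equal(back$energy, ds$energy, tolerance = 1e-12)
  expect_equal(back$source, ds$source)
})
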