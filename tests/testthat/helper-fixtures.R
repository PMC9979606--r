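# Shared fixtures: all data is generated in code, at test time.

random_ic <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(r1 = runif(n, 0.85, 2.6), r2 = runif(n, 0.95, 2.6),
             r3 = runif(n, 0.95, 2.6), theta1 = runif(n, 10, 170),
             theta2 = runif(n, 10, 170), phi = runif(n, 0, 360))
}

random_geometry <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    xyz <- matrix(runif(12, -1.5, 1.5), 4, 3)
    d <- as.matrix(dist(xyz))
    if (min(d[upper.tri(d)]) > 0.5) break
  }
  molecular_geometry(c("H", "N", "C", "O"), xyz)
}

rigid_motion <- function(geom, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(th[3]), 0, sin(th[3])), c(0, 1, 0),
              c(-sin(th[3]), 0, cos(th[3])))
  shift <- matrix(runif(3, -5, 5), 4, 3, byrow = TRUE)
  molecular_geometry(geom$elements, geom$xyz %*% (Rx %*% Rz %*% Ry) + shift)
}

# A modest single-basin 2-D slice through the deep basin of the default
# surrogate: the standard small fitting problem for the SLNN.
basin_slice_dataset <- function(spec = default_surrogate()) {
  ctr <- spec$basins[[1]]$center
  ms <- mesh_spec(ctr, vary = list(theta1 = c(84, 164, 4),
                                   theta2 = c(136, 180, 5)))
  sample_labeled_dataset(ms, spec, source = "S1")
}

# Two-basin (deep S1 + shallow S5) 3-D grids, about a thousand points: the
# standard fitting problem for the deep models.
two_basin_dataset <- function(spec = default_surrogate()) {
  mk <- function(ctr, tag) {
    ms <- mesh_spec(ctr, vary = list(
      r2 = c(ctr$r2 - 0.21, ctr$r2 + 0.21, 0.06),
      theta1 = c(ctr$theta1 - 28, ctr$theta1 + 28, 8),
      theta2 = c(ctr$theta2 - 28, min(180, ctr$theta2 + 28), 8)))
    sample_labeled_dataset(ms, spec, source = tag)
  }
  rbind(mk(spec$basins[[1]]$center, "S1"),
        mk(spec$basins[[5]]$center, "S5"))
}

# 2-D angular grids around the S1 and S5 centers, used by the cross-basin
# transfer experiment.
transfer_sets <- function(spec = default_surrogate()) {
  mk <- function(ctr, tag) {
    ms <- mesh_spec(ctr, vary = list(
      theta1 = c(ctr$theta1 - 30, ctr$theta1 + 30, 5),
      theta2 = c(ctr$theta2 - 30, min(180, ctr$theta2 + 30), 5)))
    sample_labeled_dataset(ms, spec, source = tag)
  }
  list(a = mk(spec$basins[[1]]$center, "S1"),
       b = mk(spec$basins[[5]]$center, "S5"))
}
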