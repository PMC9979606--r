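#' Smooth cosine cutoff function
#'
#' `0.5 (cos(pi r / R_c) + 1)` for `r <= R_c` and exactly 0 beyond, which is
#' continuous with a continuous first derivative at the cutoff.
#'
#' @param r distance(s), Angstrom, >= 0.
#' @param rc cutoff radius, Angstrom, > 0.
#' @return dimensionless values in \[0, 1\].
#' @export
cutoff_fn <- function(r, rc) {
  stopifnot(rc > 0)
  ifelse(r > rc, 0, 0.5 * (cos(pi * r / rc) + 1))
}

#' One atom-centered symmetry function parameterization
#'
#' Radial (`G2`) functions sum Gaussian-weighted cutoff terms over neighbors:
#' `sum_j exp(-eta (r_ij - r_s)^2) fc(r_ij)`. Angular functions sum over
#' neighbor pairs:
#' `2^(1-zeta) sum_{j<k} (1 + gamma cos(theta_ijk))^zeta
#'  exp(-eta (r_ij^2 + r_ik^2 [+ r_jk^2])) fc(r_ij) fc(r_ik) [fc(r_jk)]`,
#' where `G3` includes the bracketed `r_jk` factors and `G4` omits them.
#' `gamma` (elsewhere often written lambda) takes values -1 or +1.
#'
#' @param kind one of "G2", "G3", "G4".
#' @param eta Gaussian width parameter (1/Angstrom^2, >= 0).
#' @param rs radial shift for G2 (Angstrom), or the string `"min_rij"` to use
#'   the minimum observed pair distance of each structure.
#' @param zeta angular sharpness (>= 1; angular kinds only).
#' @param gamma angular parity, -1 or +1 (angular kinds only).
#' @param rc cutoff radius (Angstrom).
#' @return object of class `sym_function`.
#' @export
sym_function <- function(kind = c("G2", "G3", "G4"), eta, rs = 0,
                         zeta = 1, gamma = 1, rc) {
  kind <- match.arg(kind)
  stopifnot(eta >= 0, rc > 0)
  if (kind != "G2") stopifnot(zeta >= 1, gamma %in% c(-1, 1))
  structure(list(kind = kind, eta = eta, rs = rs, zeta = zeta,
                 gamma = gamma, rc = rc), class = "sym_function")
}

#' Default symmetry-function grids
#'
#' Enumerates the descriptor set from the standard parameter grids: two
#' origin-centered G2 families (`rs = 0` and `rs = min r_ij`), one
#' shifted-center G2 family with centers uniformly spanning `(0, R_c]` and
#' widths chosen so adjacent Gaussians cross at half maximum, plus G3 and G4
#' angular families over the `zeta x gamma x eta` grids. The defaults give
#' 35 radial and 36 angular functions (71 per atom), in line with the
#' customary "around 70 per structure" budget, of which 35-45 are radial.
#'
#' @param rc cutoff radius (Angstrom).
#' @param eta_g2_origin eta grid for the `rs = 0` G2 family.
#' @param eta_g2_minrs eta grid for the `rs = min r_ij` G2 family.
#' @param n_intervals number of intervals dividing `(0, R_c]` for the
#'   shifted-center G2 family (centers `m = 0..n`).
#' @param eta_g3,eta_g4 eta grids for the two angular families.
#' @param zeta,gamma angular grids.
#' @return object of class `descriptor_set`: an ordered list of
#'   `sym_function`s applied identically to every element species.
#' @export
build_descriptor_set <- function(rc = 3.5,
                                 eta_g2_origin = c(0.0005, 0.005, 0.0015,
                                                   0.003, 0.01),
                                 eta_g2_minrs = c(0.07, 0.015, 0.03,
                                                  0.75, 1.5),
                                 n_intervals = 24,
                                 eta_g3 = c(0.01, 0.03, 0.07, 0.20, 0.4),
                                 eta_g4 = c(6.0613, 12.1227, 18.1840,
                                            24.2454),
                                 zeta = c(1, 4), gamma = c(-1, 1)) {
  fns <- list()
  add <- function(f) fns[[length(fns) + 1L]] <<- f
  for (e in eta_g2_origin) add(sym_function("G2", e, rs = 0, rc = rc))
  for (e in eta_g2_minrs) add(sym_function("G2", e, rs = "min_rij", rc = rc))
  centers <- rc * seq_len(n_intervals + 1) / (n_intervals + 1)
  delta <- rc / (n_intervals + 1)
  eta_s <- 4 * log(2) / delta^2      # adjacent Gaussians cross at half max
  for (ct in centers) add(sym_function("G2", eta_s, rs = ct, rc = rc))
  for (z in zeta) for (g in gamma) for (e in eta_g3)
    add(sym_function("G3", e, zeta = z, gamma = g, rc = rc))
  for (z in zeta) for (g in gamma) for (e in eta_g4)
    add(sym_function("G4", e, zeta = z, gamma = g, rc = rc))
  if (!length(fns)) stop("empty descriptor enumeration", call. = FALSE)
  structure(list(functions = fns, rc = rc,
                 elements = c("H", "N", "C", "O")),
            class = "descriptor_set")
}

#' @rdname build_descriptor_set
#' @param dset a `descriptor_set`.
#' @export
descriptor_counts <- function(dset) {
  kinds <- vapply(dset$functions, `[[`, "", "kind")
  c(g2 = sum(kinds == "G2"), angular = sum(kinds != "G2"),
    total = length(kinds))
}

#' @export
print.descriptor_set <- function(x, ...) {
  ct <- descriptor_counts(x)
  cat("Descriptor set: ", ct["total"], " symmetry functions per atom (",
      ct["g2"], " radial G2, ", ct["angular"], " angular G3/G4), Rc = ",
      x$rc, " Angstrom\n", sep = "")
  invisible(x)
}

# Batched positions for an ic frame, atoms ordered H, N, C, O; the same
# body-fixed construction as internal_to_cartesian, vectorized over rows.
batch_positions <- function(ics) {
  ics <- as_ic_frame(ics)
  t1 <- .deg2rad(ics$theta1); t2 <- .deg2rad(ics$theta2)
  ph <- .deg2rad(ics$phi %% 360)
  zero <- numeric(nrow(ics))
  list(H = cbind(ics$r1 * sin(t1), zero, ics$r1 * cos(t1)),
       N = cbind(zero, zero, zero),
       C = cbind(zero, zero, ics$r2),
       O = cbind(ics$r3 * sin(t2) * cos(ph), -ics$r3 * sin(t2) * sin(ph),
                 ics$r2 - ics$r3 * cos(t2)))
}

# pos: list of four n x 3 matrices (atom order H, N, C, O).
# Returns, per atom, an n x n_feat matrix.
featurize_positions <- function(pos, dset) {
  n <- nrow(pos[[1]])
  dist2 <- function(a, b) sqrt(rowSums((pos[[a]] - pos[[b]])^2))
  pr <- list()                          # pairwise distances, keyed "i.j"
  for (i in 1:3) for (j in (i + 1):4)
    pr[[paste(i, j)]] <- dist2(i, j)
  rget <- function(i, j) pr[[paste(min(i, j), max(i, j))]]
  rmin <- do.call(pmin, pr)
  out <- vector("list", 4)
  for (i in 1:4) {
    nb <- setdiff(1:4, i)
    rij_list <- lapply(nb, function(j) rget(i, j))
    pairs <- utils::combn(nb, 2)
    tri <- lapply(seq_len(ncol(pairs)), function(p) {
      j <- pairs[1, p]; k <- pairs[2, p]
      rij <- rget(i, j); rik <- rget(i, k); rjk <- rget(j, k)
      u <- pos[[j]] - pos[[i]]; v <- pos[[k]] - pos[[i]]
      cosang <- rowSums(u * v) / (rij * rik)
      list(rij = rij, rik = rik, rjk = rjk,
           cosang = pmin(1, pmax(-1, cosang)))
    })
    feats <- matrix(0, n, length(dset$functions))
    for (f in seq_along(dset$functions)) {
      p <- dset$functions[[f]]
      if (p$kind == "G2") {
        rs <- if (identical(p$rs, "min_rij")) rmin else p$rs
        acc <- 0
        for (rij in rij_list)
          acc <- acc + exp(-p$eta * (rij - rs)^2) * cutoff_fn(rij, p$rc)
        feats[, f] <- acc
      } else {
        acc <- 0
        for (tp in tri) {
          ang <- pmax(0, 1 + p$gamma * tp$cosang)^p$zeta
          if (p$kind == "G3") {
            term <- ang *
              exp(-p$eta * (tp$rij^2 + tp$rik^2 + tp$rjk^2)) *
              cutoff_fn(tp$rij, p$rc) * cutoff_fn(tp$rik, p$rc) *
              cutoff_fn(tp$rjk, p$rc)
          } else {
            term <- ang * exp(-p$eta * (tp$rij^2 + tp$rik^2)) *
              cutoff_fn(tp$rij, p$rc) * cutoff_fn(tp$rik, p$rc)
          }
          acc <- acc + term
        }
        feats[, f] <- 2^(1 - p$zeta) * acc
      }
    }
    out[[i]] <- feats
  }
  names(out) <- c("H", "N", "C", "O")
  out
}

#' Per-atom symmetry-function features for one structure
#'
#' @param geom a `mol_geometry`.
#' @param dset a `descriptor_set`.
#' @return matrix with one row per atom (rownames the element symbols) and
#'   one column per symmetry function, in `descriptor_set` order. Features
#'   are invariant under rigid motions by construction.
#' @export
featurize_structure <- function(geom, dset) {
  stopifnot(inherits(geom, "mol_geometry"), inherits(dset, "descriptor_set"))
  pos <- lapply(1:4, function(k) matrix(geom$xyz[k, ], 1, 3))
  fl <- featurize_positions(pos, dset)
  m <- do.call(rbind, fl)
  rownames(m) <- geom$elements
  m
}

#' Per-atom features for a whole dataset of internal coordinates
#'
#' @param ics anything [as_ic_frame] accepts.
#' @param dset a `descriptor_set`.
#' @return named list (`H`, `N`, `C`, `O`) of `n x n_feat` feature matrices.
#' @export
featurize_dataset <- function(ics, dset) {
  stopifnot(inherits(dset, "descriptor_set"))
  featurize_positions(batch_positions(ics), dset)
}

#' Single symmetry-function values (reference entry points)
#'
#' Direct per-function evaluation for one center atom of one geometry;
#' useful for inspection and cross-checks of the batched featurizer.
#'
#' @param geom a `mol_geometry`.
#' @param i center-atom index (1-4).
#' @param params a `sym_function` of the matching kind.
#' @return a single numeric value.
#' @export
g2_value <- function(geom, i, params) {
  stopifnot(params$kind == "G2")
  .single_value(geom, i, params)
}

#' @rdname g2_value
#' @export
g_angular_value <- function(geom, i, params) {
  stopifnot(params$kind %in% c("G3", "G4"))
  .single_value(geom, i, params)
}

.single_value <- function(geom, i, params) {
  dset <- structure(list(functions = list(params), rc = params$rc,
                         elements = geom$elements),
                    class = "descriptor_set")
  unname(featurize_structure(geom, dset)[i, 1])
}
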