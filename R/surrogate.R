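#' Analytic multi-basin surrogate potential energy surface
#'
#' A cheap, smooth (C1) stand-in for coupled-cluster reference energies, so
#' that every piece of the fitting machinery is testable with controllable
#' ground truth. Each basin contributes
#' `offset - depth + sum_i Morse(r_i) + sum_j k_theta (1 - cos(theta - theta0))
#'  + A (1 - cos(phi - phi0))`
#' with `Morse(r) = D_e (1 - exp(-a (r - r0)))^2`; basins are blended with a
#' smooth minimum (log-sum-exp with smoothness `s`, in Hartree), which tends
#' to the pointwise basin minimum as `s -> 0`. With the default per-channel
#' well depths `D_e = depth/3`, the energy rises to the `offset`-level
#' dissociation plateau as any distance grows.
#'
#' @param basins list of basins from [surrogate_basin].
#' @param offset global absolute-energy offset in Hartree; the default keeps
#'   basin minima below the default preprocessing energy ceiling.
#' @param smoothness basin-coupling smoothness parameter in Hartree.
#' @return object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(basins, offset = -168.5, smoothness = 0.005) {
  stopifnot(length(basins) >= 1, smoothness > 0)
  for (b in basins) stopifnot(inherits(b, "surrogate_basin"))
  structure(list(basins = basins, offset = offset, smoothness = smoothness),
            class = "surrogate_spec")
}

#' @rdname surrogate_spec
#' @param label basin label (free-form; registered alongside S1..S8).
#' @param center an `internal_coords` basin center.
#' @param depth well depth in Hartree (> 0); the basin minimum sits at
#'   `offset - depth`.
#' @param de Morse well depths per distance channel (length 3, Hartree);
#'   default `depth/3` each so the dissociation plateau sits at `offset`.
#' @param a Morse range parameters per distance channel (1/Angstrom).
#' @param k_theta angular force amplitudes per angle channel (Hartree).
#' @param a_phi dihedral cosine amplitude (Hartree).
#' @export
surrogate_basin <- function(label, center, depth, de = NULL,
                            a = c(2, 2, 2), k_theta = c(0.1, 0.1),
                            a_phi = 0.02) {
  stopifnot(depth > 0, length(a) == 3, length(k_theta) == 2)
  center <- as_ic_frame(center)
  if (is.null(de)) de <- rep(depth / 3, 3)
  stopifnot(length(de) == 3, all(de > 0))
  structure(list(label = label, center = center, depth = depth, de = de,
                 a = a, k_theta = k_theta, a_phi = a_phi),
            class = "surrogate_basin")
}

#' Default eight-basin surrogate surface
#'
#' Ships with eight basins labelled S1..S8 at distinct internal-coordinate
#' centers, loosely echoing the topology of the real isomer family: one deep
#' global basin (S1) and one shallow basin (S5) in a remote angular region
#' provide the pair used by the cross-basin transfer experiment. All
#' parameters are user-overridable via [surrogate_spec].
#'
#' @return a `surrogate_spec`.
#' @export
default_surrogate <- function() {
  b <- function(label, r1, r2, r3, t1, t2, ph, depth)
    surrogate_basin(label, internal_coords(r1, r2, r3, t1, t2, ph), depth)
  surrogate_spec(list(
    b("S1", 1.00, 1.21, 1.17, 124, 172, 180, 0.25),
    b("S2", 0.97, 1.30, 1.29, 110, 176,   0, 0.20),
    b("S3", 1.90, 1.17, 1.20, 150, 160, 180, 0.18),
    b("S4", 0.98, 1.40, 1.35, 105, 110,  90, 0.16),
    b("S5", 1.05, 1.32, 1.22,  30,  35, 180, 0.10),
    b("S6", 1.85, 1.25, 1.30,  60,  70, 180, 0.14),
    b("S7", 1.02, 1.45, 1.25,  95, 150,   0, 0.15),
    b("S8", 1.80, 1.35, 1.20,  45, 120,  90, 0.12)))
}

basin_energy <- function(basin, ics) {
  ct <- basin$center
  e <- rep(-basin$depth, nrow(ics))
  for (i in 1:3) {
    nm <- ic_names[i]
    e <- e + basin$de[i] *
      (1 - exp(-basin$a[i] * (ics[[nm]] - ct[[nm]])))^2
  }
  for (j in 1:2) {
    nm <- ic_names[3 + j]
    e <- e + basin$k_theta[j] *
      (1 - cos(.deg2rad(ics[[nm]] - ct[[nm]])))
  }
  e + basin$a_phi * (1 - cos(.deg2rad(ics$phi - ct$phi)))
}

#' Evaluate the surrogate surface
#'
#' @param ic coordinates: anything [as_ic_frame] accepts (vectorized over
#'   rows).
#' @param spec a `surrogate_spec`.
#' @return energies in Hartree (one per row).
#' @export
surrogate_energy <- function(ic, spec = default_surrogate()) {
  stopifnot(inherits(spec, "surrogate_spec"))
  ics <- as_ic_frame(ic)
  em <- vapply(spec$basins, basin_energy, numeric(nrow(ics)), ics = ics)
  em <- matrix(em, nrow = nrow(ics))
  s <- spec$smoothness
  m <- apply(em, 1, min)
  spec$offset + m - s * log(rowSums(exp(-(em - m) / s)))
}

#' Turn a surrogate (or any energy function) into a reference backend
#'
#' A reference-energy backend is the plug-in contract abstracting an ab
#' initio workflow: a deterministic callable mapping internal coordinates to
#' Hartree energies plus a metadata label. Real electronic-structure codes
#' can be attached by wrapping their drivers with [reference_backend].
#'
#' @param fun function taking an ic frame and returning a numeric energy
#'   vector (Hartree).
#' @param label metadata label describing the backend.
#' @return object of class `reference_backend`.
#' @export
reference_backend <- function(fun, label) {
  stopifnot(is.function(fun), is.character(label))
  structure(list(fun = fun, label = label), class = "reference_backend")
}

#' @rdname reference_backend
#' @param spec a `surrogate_spec`.
#' @export
surrogate_backend <- function(spec = default_surrogate()) {
  force(spec)
  reference_backend(function(ic) surrogate_energy(ic, spec),
                    label = "analytic multi-basin surrogate")
}

#' Label a mesh grid with reference energies
#'
#' @param mesh a [mesh_spec].
#' @param backend a `reference_backend` (or a `surrogate_spec`, wrapped
#'   automatically).
#' @param source provenance tag.
#' @return labeled-dataset data frame with energies set; deterministic.
#' @export
sample_labeled_dataset <- function(mesh, backend = default_surrogate(),
                                   source = "RMG") {
  if (inherits(backend, "surrogate_spec")) backend <- surrogate_backend(backend)
  stopifnot(inherits(backend, "reference_backend"))
  ds <- generate_rmg(mesh, source = source)
  ds$energy <- backend$fun(ds)
  ds
}

#' Covalent radii table (Angstrom)
#'
#' @return named numeric vector of single-bond covalent radii.
#' @export
covalent_radii <- function() {
  c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)
}

#' Distance-based connectivity screen
#'
#' Declares a bond between atoms `i` and `j` when
#' `r_ij <= tolerance * (radius_i + radius_j)` and passes a structure iff the
#' resulting bond graph is connected, i.e. no fragment has dissociated. This
#' plays the preprocessing role of a wavefunction-based bond-order screen
#' without any quantum-chemistry dependency; a stricter screen can be
#' injected wherever a pass/fail function over geometries is accepted.
#'
#' @param geom a `mol_geometry`.
#' @param radii named covalent-radius table (Angstrom).
#' @param tolerance bond-declaration multiplier.
#' @return list with `pass` (logical) and `bonds` (two-column matrix of
#'   bonded atom index pairs).
#' @export
connectivity_check <- function(geom, radii = covalent_radii(),
                               tolerance = 1.3) {
  stopifnot(inherits(geom, "mol_geometry"))
  unknown <- setdiff(geom$elements, names(radii))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d <- pairwise_distances(geom)
  r <- radii[geom$elements]
  thresh <- tolerance * outer(r, r, "+")
  adj <- d <= thresh & upper.tri(d)
  bonds <- which(adj, arr.ind = TRUE)
  colnames(bonds) <- c("i", "j")
  n <- length(geom$elements)
  amat <- (d <= thresh) & !diag(TRUE, n)
  reach <- logical(n); reach[1] <- TRUE
  repeat {
    new <- reach | apply(amat[, reach, drop = FALSE], 1, any)
    if (identical(new, reach)) break
    reach <- new
  }
  list(pass = all(reach), bonds = bonds)
}
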