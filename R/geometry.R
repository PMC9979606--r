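#' Six internal coordinates of the four-atom [H,C,N,O] system
#'
#' All isomers share one coordinate set: the N-H, C-N and C-O bond distances
#' (`r1`, `r2`, `r3`, in Angstrom), the H-N-C and N-C-O bond angles (`theta1`,
#' `theta2`, degrees in \[0,180\]) and the dihedral angle `phi` between the HNC
#' and NCO planes (degrees, stored modulo 360). Distances must be positive.
#'
#' @param r1,r2,r3 bond distances in Angstrom, all > 0.
#' @param theta1,theta2 bond angles in degrees, within \[0, 180\].
#' @param phi dihedral angle in degrees; reduced modulo 360.
#' @return a named numeric vector of class `internal_coords`.
#' @examples
#' internal_coords(1.0, 1.21, 1.17, 124, 172, 180)
#' @export
internal_coords <- function(r1, r2, r3, theta1, theta2, phi) {
  ic <- c(r1 = r1, r2 = r2, r3 = r3,
          theta1 = theta1, theta2 = theta2, phi = phi %% 360)
  validate_internal_coords(ic)
  class(ic) <- "internal_coords"
  ic
}

validate_internal_coords <- function(ic) {
  if (any(!is.finite(ic)))
    stop("internal coordinates must be finite", call. = FALSE)
  if (any(ic[c("r1", "r2", "r3")] <= 0))
    stop("bond distances must be positive", call. = FALSE)
  th <- ic[c("theta1", "theta2")]
  if (any(th < 0 | th > 180))
    stop("bond angles must lie in [0, 180] degrees", call. = FALSE)
  invisible(ic)
}

#' @export
print.internal_coords <- function(x, digits = 6, ...) {
  cat("Internal coordinates (Angstrom / degrees):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

ic_names <- c("r1", "r2", "r3", "theta1", "theta2", "phi")

#' Coerce to a data frame of internal coordinates
#'
#' Accepts a single `internal_coords` vector, a numeric matrix, or any data
#' frame containing the six coordinate columns, and returns a data frame with
#' exactly the columns `r1, r2, r3, theta1, theta2, phi`.
#'
#' @param x coordinates in any accepted representation.
#' @return data frame with the six coordinate columns.
#' @export
as_ic_frame <- function(x) {
  if (inherits(x, "internal_coords"))
    return(as.data.frame(as.list(unclass(x))))
  if (is.matrix(x)) {
    colnames(x) <- colnames(x) %||% ic_names
    x <- as.data.frame(x)
  }
  if (!is.data.frame(x) || !all(ic_names %in% names(x)))
    stop("need columns ", paste(ic_names, collapse = ", "), call. = FALSE)
  x[ic_names]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Four-atom molecular geometry
#'
#' Cartesian representation of one [H,C,N,O] structure: exactly four atoms,
#' with no two atoms coincident.
#'
#' @param elements character vector of four element symbols.
#' @param xyz 4 x 3 numeric matrix of Cartesian positions in Angstrom.
#' @param energy optional energy label in Hartree.
#' @return object of class `mol_geometry`.
#' @export
molecular_geometry <- function(elements, xyz, energy = NULL) {
  xyz <- as.matrix(xyz)
  if (length(elements) != 4 || nrow(xyz) != 4 || ncol(xyz) != 3)
    stop("a molecular geometry has exactly 4 atoms with 3 coordinates",
         call. = FALSE)
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  d <- as.matrix(stats::dist(xyz))
  if (any(d[upper.tri(d)] < 1e-10))
    stop("coincident atoms", call. = FALSE)
  dimnames(xyz) <- list(elements, c("x", "y", "z"))
  structure(list(elements = as.character(elements), xyz = xyz,
                 energy = energy),
            class = "mol_geometry")
}

#' @export
print.mol_geometry <- function(x, ...) {
  cat("Molecular geometry (", paste(x$elements, collapse = ""), ")\n", sep = "")
  print(round(x$xyz, 6))
  if (!is.null(x$energy)) cat("energy:", format(x$energy), "Hartree\n")
  invisible(x)
}

#' Pairwise distance matrix of a geometry
#'
#' @param geom a `mol_geometry`.
#' @return symmetric 4 x 4 matrix of Euclidean distances (Angstrom) with zero
#'   diagonal, row/column names the element symbols.
#' @export
pairwise_distances <- function(geom) {
  stopifnot(inherits(geom, "mol_geometry"))
  d <- as.matrix(stats::dist(geom$xyz))
  dimnames(d) <- list(geom$elements, geom$elements)
  d
}

#' Build Cartesian coordinates from internal coordinates
#'
#' Uses a body-fixed frame: N at the origin, C on the +z axis at distance
#' `r2`, H in the xz half-plane (x >= 0) at distance `r1` making angle
#' `theta1` with the N->C axis, and O placed off C by `r3`, `theta2` and the
#' dihedral `phi` (right-hand rule about the N->C axis; `phi = 0` is the cis
#' arrangement with H and O on the same side). Any self-consistent frame
#' serves, since every downstream feature is a function of the internal
#' coordinates only.
#'
#' @param ic an `internal_coords` object (or anything `as_ic_frame` accepts,
#'   single row).
#' @return a `mol_geometry` with atoms ordered H, N, C, O.
#' @export
internal_to_cartesian <- function(ic) {
  row <- as_ic_frame(ic)
  if (nrow(row) != 1) stop("one set of internal coordinates expected")
  r1 <- row$r1; r2 <- row$r2; r3 <- row$r3
  t1 <- .deg2rad(row$theta1); t2 <- .deg2rad(row$theta2)
  ph <- .deg2rad(row$phi %% 360)
  if ((row$theta1 %in% c(0, 180) || row$theta2 %in% c(0, 180)) &&
      abs(sin(ph)) > 1e-12)
    warning("degenerate geometry: dihedral undefined at a collinear angle",
            call. = FALSE)
  n <- c(0, 0, 0)
  cc <- c(0, 0, r2)
  h <- c(r1 * sin(t1), 0, r1 * cos(t1))
  o <- c(r3 * sin(t2) * cos(ph), -r3 * sin(t2) * sin(ph), r2 - r3 * cos(t2))
  molecular_geometry(c("H", "N", "C", "O"), rbind(h, n, cc, o))
}

#' Recover internal coordinates from Cartesian coordinates
#'
#' Distances come from the Euclidean metric, angles from arccos of normalized
#' dot products, and the dihedral from the signed-angle (atan2) convention
#' about the N->C axis, normalized to \[0,360). When the HNC or NCO triple is
#' collinear the dihedral is undefined: `phi` is returned as `NA` and the
#' result carries attribute `dihedral_defined = FALSE`.
#'
#' @param geom a `mol_geometry` with atoms ordered H, N, C, O.
#' @return an `internal_coords` vector.
#' @export
cartesian_to_internal <- function(geom) {
  stopifnot(inherits(geom, "mol_geometry"))
  x <- geom$xyz
  h <- x[1, ]; n <- x[2, ]; cc <- x[3, ]; o <- x[4, ]
  vnorm <- function(v) sqrt(sum(v^2))
  r1 <- vnorm(h - n); r2 <- vnorm(cc - n); r3 <- vnorm(o - cc)
  ang <- function(u, v) {
    ct <- sum(u * v) / (vnorm(u) * vnorm(v))
    .rad2deg(acos(pmin(1, pmax(-1, ct))))
  }
  theta1 <- ang(h - n, cc - n)
  theta2 <- ang(n - cc, o - cc)
  b1 <- n - h; b2 <- cc - n; b3 <- o - cc
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  defined <- vnorm(n1) > 1e-10 && vnorm(n2) > 1e-10
  if (defined) {
    m1 <- .cross(n1, b2 / vnorm(b2))
    phi <- .rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))) %% 360
  } else {
    phi <- NA_real_
  }
  ic <- c(r1 = r1, r2 = r2, r3 = r3, theta1 = theta1, theta2 = theta2,
          phi = phi)
  class(ic) <- "internal_coords"
  attr(ic, "dihedral_defined") <- defined
  ic
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convert a frame of internal coordinates to geometries
#'
#' @param ics anything `as_ic_frame` accepts.
#' @return list of `mol_geometry` objects.
#' @export
ic_frame_to_geometries <- function(ics) {
  ics <- as_ic_frame(ics)
  lapply(seq_len(nrow(ics)), function(i) internal_to_cartesian(ics[i, ]))
}

#' Registry of isomer labels
#'
#' The eight stable-isomer tags S1..S8, the transition-state path tag and the
#' dihedral-augmentation tag are always valid; surrogate basins may register
#' free-form labels.
#'
#' @param extra additional labels to admit.
#' @return character vector of valid tags.
#' @export
isomer_labels <- function(extra = character()) {
  c(paste0("S", 1:8), "TS-path", "dihedral-augmentation", extra)
}
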