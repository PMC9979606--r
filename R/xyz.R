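#' Read geometries from an XYZ file
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` record per atom, repeated for multiple frames. An
#' extended-XYZ `energy=<value>` key in the comment line is honored and
#' attached in Hartree. Parse failures name the offending line.
#'
#' @param path file path.
#' @return list of `mol_geometry` objects (with `$energy` set when present).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  geoms <- list()
  i <- 1L
  known <- names(covalent_radii())
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat))
      stop("malformed atom-count line ", i, ": '", lines[i], "'", call. = FALSE)
    if (i + 1L + nat > length(lines))
      stop("truncated frame: expected ", nat, " atom records after line ",
           i + 1L, call. = FALSE)
    comment <- lines[i + 1L]
    energy <- NULL
    m <- regmatches(comment,
                    regexpr("energy=\\s*[-+0-9.eE]+", comment))
    if (length(m) == 1)
      energy <- as.numeric(sub("energy=\\s*", "", m))
    el <- character(nat)
    xyz <- matrix(NA_real_, nat, 3)
    for (k in seq_len(nat)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4)
        stop("malformed atom record at line ", ln, call. = FALSE)
      if (!(tok[1] %in% known))
        stop("unknown element '", tok[1], "' at line ", ln, call. = FALSE)
      el[k] <- tok[1]
      xyz[k, ] <- as.numeric(tok[2:4])
      if (any(is.na(xyz[k, ])))
        stop("non-numeric coordinate at line ", ln, call. = FALSE)
    }
    geoms[[length(geoms) + 1L]] <- molecular_geometry(el, xyz, energy = energy)
    i <- i + 2L + nat
  }
  geoms
}

#' Write geometries to an XYZ file
#'
#' Coordinates are written with 8 decimal places (1e-8 Angstrom), which makes
#' the write/read round trip lossless at printed precision. Energies, when
#' present on a geometry, go into the comment line as `energy=<Hartree>`.
#'
#' @param geoms a `mol_geometry` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geoms, path) {
  if (inherits(geoms, "mol_geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geoms) {
    writeLines(as.character(length(g$elements)), con)
    cmt <- if (!is.null(g$energy))
      sprintf("energy=%.12f", g$energy) else ""
    writeLines(cmt, con)
    for (k in seq_along(g$elements))
      writeLines(sprintf("%-2s %15.8f %15.8f %15.8f", g$elements[k],
                         g$xyz[k, 1], g$xyz[k, 2], g$xyz[k, 3]), con)
  }
  invisible(path)
}
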