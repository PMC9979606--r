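#' Regular mesh-grid specification
#'
#' A mesh spec names which of the six internal coordinates vary, each with a
#' `(min, max, step)` triple, around a center geometry; non-varying
#' coordinates are held at the center values. The dihedral axis is treated as
#' periodic: grid values that coincide modulo 360 degrees are emitted once,
#' so a scan `phi` in \[0, 360\] with step 20 yields 18 points, not 19.
#'
#' @param center an `internal_coords` (or single-row coercible) center point.
#' @param vary named list; each element `c(min, max, step)` for one of
#'   `r1, r2, r3, theta1, theta2, phi`.
#' @param size_cap refuse to materialize grids larger than this many points.
#' @return object of class `mesh_spec`.
#' @examples
#' ms <- mesh_spec(internal_coords(1, 1.2, 1.2, 120, 170, 0),
#'                 vary = list(r1 = c(0.8, 1.8, 0.1)))
#' nrow(generate_rmg(ms))  # 11
#' @export
mesh_spec <- function(center, vary, size_cap = 1e6) {
  center <- as_ic_frame(center)
  stopifnot(nrow(center) == 1, is.list(vary), length(vary) >= 1)
  bad <- setdiff(names(vary), ic_names)
  if (length(bad)) stop("unknown coordinates: ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(vary))) stop("duplicate varying coordinates")
  for (nm in names(vary)) {
    v <- vary[[nm]]
    if (length(v) != 3 || v[3] <= 0 || v[1] >= v[2])
      stop("axis '", nm, "' needs c(min, max, step) with step > 0, min < max")
  }
  structure(list(center = center, vary = vary, size_cap = size_cap),
            class = "mesh_spec")
}

mesh_axis_values <- function(nm, v) {
  vals <- seq(v[1], v[1] + floor((v[2] - v[1]) / v[3] + 1e-9) * v[3],
              by = v[3])
  if (nm == "phi") vals <- vals[!duplicated(round(vals %% 360, 9))]
  vals
}

#' Generate a regular mesh-grid dataset (energies unset)
#'
#' Takes the Cartesian product of the per-axis grids of a [mesh_spec] with
#' all other coordinates fixed at the center. Point count is the product of
#' per-axis counts `floor((max - min)/step) + 1` (dihedral axes deduplicated
#' modulo 360).
#'
#' @param spec a `mesh_spec`.
#' @param source provenance tag attached to every point.
#' @return labeled-dataset data frame (`energy` column all `NA`).
#' @export
generate_rmg <- function(spec, source = "RMG") {
  stopifnot(inherits(spec, "mesh_spec"))
  axes <- lapply(names(spec$vary),
                 function(nm) mesh_axis_values(nm, spec$vary[[nm]]))
  names(axes) <- names(spec$vary)
  n <- prod(vapply(axes, length, 1L))
  if (n > spec$size_cap)
    stop("grid of ", n, " points exceeds size cap ", spec$size_cap,
         call. = FALSE)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  ds <- spec$center[rep(1L, n), , drop = FALSE]
  for (nm in names(axes)) ds[[nm]] <- grid[[nm]]
  ds$phi <- ds$phi %% 360
  ds$energy <- NA_real_
  ds$source <- source
  rownames(ds) <- NULL
  ds
}

#' Preprocessing filter configuration
#'
#' Defaults follow the unified-training-set construction: points above the
#' energy ceiling of -167.85 Hartree are dropped (repulsive branch), as are
#' points with N-H distance below 0.8 Angstrom, C-N or C-O distance below
#' 0.9 Angstrom, any distance above 3.5 Angstrom (dissociation branch), or a
#' dihedral outside \[0, 180\] degrees (out-of-plane redundancy).
#'
#' @param energy_ceiling maximum retained energy, Hartree.
#' @param r1_min minimum N-H distance, Angstrom.
#' @param r23_min minimum C-N / C-O distance, Angstrom.
#' @param r_max maximum retained distance for all three channels, Angstrom.
#' @param dihedral_range retained dihedral interval in degrees, or `NULL` to
#'   keep the full circle.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(energy_ceiling = -167.85, r1_min = 0.8,
                          r23_min = 0.9, r_max = 3.5,
                          dihedral_range = c(0, 180)) {
  stopifnot(r1_min < r_max, r23_min < r_max)
  structure(list(energy_ceiling = energy_ceiling, r1_min = r1_min,
                 r23_min = r23_min, r_max = r_max,
                 dihedral_range = dihedral_range),
            class = "filter_config")
}

#' Apply the preprocessing filters to a labeled dataset
#'
#' Rules are checked in the fixed order energy ceiling, minimum N-H distance,
#' minimum C-N/C-O distance, maximum distance, dihedral window; each removed
#' point is attributed to the first rule it violates, so the removal report
#' sums to the number of dropped points. All energies must be set. An empty
#' result triggers an explicit warning.
#'
#' @param ds labeled-dataset data frame with all `energy` values set.
#' @param cfg a [filter_config].
#' @return the retained subset, with attribute `removal_report` (named
#'   integer vector of per-rule removal counts).
#' @export
apply_filters <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!"energy" %in% names(ds) || anyNA(ds$energy))
    stop("apply_filters needs a fully labeled dataset", call. = FALSE)
  fail_energy <- ds$energy > cfg$energy_ceiling
  fail_r1 <- ds$r1 < cfg$r1_min
  fail_r23 <- ds$r2 < cfg$r23_min | ds$r3 < cfg$r23_min
  fail_rmax <- ds$r1 > cfg$r_max | ds$r2 > cfg$r_max | ds$r3 > cfg$r_max
  if (is.null(cfg$dihedral_range)) {
    fail_phi <- rep(FALSE, nrow(ds))
  } else {
    ph <- ds$phi %% 360
    fail_phi <- ph < cfg$dihedral_range[1] | ph > cfg$dihedral_range[2]
  }
  first_fail <- function(...) {
    fails <- list(...)
    taken <- rep(FALSE, nrow(ds))
    counts <- integer(length(fails))
    for (k in seq_along(fails)) {
      hit <- fails[[k]] & !taken
      counts[k] <- sum(hit)
      taken <- taken | fails[[k]]
    }
    list(counts = counts, any = taken)
  }
  ff <- first_fail(fail_energy, fail_r1, fail_r23, fail_rmax, fail_phi)
  report <- stats::setNames(ff$counts,
                            c("energy", "r1_min", "r23_min", "r_max",
                              "dihedral"))
  out <- ds[!ff$any, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("all points removed by filters", call. = FALSE)
  attr(out, "removal_report") <- report
  out
}

#' Min-max scaling to [-1, 1]
#'
#' `scale_minmax` maps each channel linearly so that `x_min -> -1` and
#' `x_max -> +1` (`X_scaled = -1 + 2 (X - x_min) / (x_max - x_min)`);
#' `unscale_minmax` is its exact inverse. Channels with `x_max == x_min`
#' are rejected as degenerate.
#'
#' @param x numeric vector, matrix or data frame of values.
#' @param params a `scaling_params` object (from [scaling_params]).
#' @return scaled (or unscaled) values, same shape as `x`.
#' @export
scale_minmax <- function(x, params) {
  .apply_minmax(x, params, forward = TRUE)
}

#' @rdname scale_minmax
#' @export
unscale_minmax <- function(x, params) {
  .apply_minmax(x, params, forward = FALSE)
}

#' @rdname scale_minmax
#' @param data numeric vector, matrix or data frame whose per-channel ranges
#'   define the scaling.
#' @param allow_constant constant channels are normally rejected as
#'   degenerate; with `allow_constant = TRUE` they are padded to a unit
#'   interval around the constant (so they scale to 0), which is what the
#'   model-fitting functions use for coordinates held fixed in a scan.
#' @export
scaling_params <- function(data, allow_constant = FALSE) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as.matrix(data)
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("non-finite values in scaling data", call. = FALSE)
  flat <- hi <= lo
  if (any(flat)) {
    if (!allow_constant)
      stop("degenerate channel: x_max must exceed x_min", call. = FALSE)
    lo[flat] <- lo[flat] - 0.5
    hi[flat] <- hi[flat] + 0.5
  }
  structure(list(x_min = lo, x_max = hi), class = "scaling_params")
}

.apply_minmax <- function(x, params, forward) {
  stopifnot(inherits(params, "scaling_params"))
  vec <- is.null(dim(x)) && !is.data.frame(x)
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (ncol(xm) != length(params$x_min))
    stop("channel count mismatch with scaling params", call. = FALSE)
  lo <- matrix(params$x_min, nrow(xm), ncol(xm), byrow = TRUE)
  hi <- matrix(params$x_max, nrow(xm), ncol(xm), byrow = TRUE)
  out <- if (forward) -1 + 2 * (xm - lo) / (hi - lo)
         else lo + (xm + 1) * (hi - lo) / 2
  if (vec) as.vector(out) else out
}

#' Random train/validation/test split
#'
#' Reproducible under `seed`; per-split sizes follow the fractions with the
#' rounding remainder assigned to the training split. With `stratify_by`, the
#' partition is drawn independently within each stratum so per-tag fractions
#' are preserved to within one point.
#'
#' @param ds labeled-dataset data frame.
#' @param fractions named numeric vector summing to 1; names become split
#'   labels (first entry receives the remainder).
#' @param seed integer seed.
#' @param stratify_by optional column name to stratify on (e.g. `"source"`).
#' @return `ds` with a `split` column.
#' @export
split_dataset <- function(ds, fractions = c(train = 0.8, validation = 0.1,
                                            test = 0.1),
                          seed = 1, stratify_by = NULL) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-9)
  if (nrow(ds) < length(fractions))
    stop("dataset smaller than number of splits", call. = FALSE)
  assign_one <- function(n, rng_offset) {
    sizes <- floor(fractions * n)
    sizes[1] <- sizes[1] + n - sum(sizes)
    set.seed(seed + rng_offset)
    sample(rep(names(fractions), times = sizes))
  }
  if (is.null(stratify_by)) {
    ds$split <- assign_one(nrow(ds), 0L)
  } else {
    ds$split <- NA_character_
    tags <- unique(ds[[stratify_by]])
    for (k in seq_along(tags)) {
      idx <- which(ds[[stratify_by]] == tags[k])
      ds$split[idx] <- assign_one(length(idx), k)
    }
  }
  ds
}

ic_key <- function(ds, tol = 1e-9) {
  do.call(paste, c(lapply(ds[ic_names],
                          function(v) sprintf("%.14g", round(v / tol) * tol)),
                   sep = "|"))
}

#' Merge per-isomer datasets into a unified training set
#'
#' Concatenates the per-basin datasets and any transition-state path points,
#' removes duplicate geometries (internal coordinates identical to within
#' `tol`), then applies the preprocessing filters. When duplicates disagree
#' in energy by more than 1e-8 Hartree the lower energy is kept and the
#' conflict reported. Provenance tags are preserved.
#'
#' @param datasets list of labeled-dataset data frames.
#' @param ts_points optional data frame of transition-state path points.
#' @param cfg a [filter_config] (or `NULL` to skip filtering).
#' @param tol duplicate tolerance on internal coordinates.
#' @return merged data frame; attributes `removal_report` (from the filters)
#'   and `duplicate_conflicts` (count of energy-conflicting duplicates).
#' @export
merge_unified <- function(datasets, ts_points = NULL, cfg = filter_config(),
                          tol = 1e-9) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  all_ds <- do.call(rbind, c(datasets, if (!is.null(ts_points))
    list(ts_points)))
  rownames(all_ds) <- NULL
  key <- ic_key(all_ds, tol)
  ord <- order(all_ds$energy)          # lower energy wins among duplicates
  keep_first <- !duplicated(key[ord])
  kept_idx <- sort(ord[keep_first])
  conflicts <- 0L
  if (anyDuplicated(key)) {
    sp <- split(all_ds$energy, key)
    conflicts <- sum(vapply(sp, function(e) diff(range(e)) > 1e-8, TRUE))
    if (conflicts > 0)
      warning(conflicts, " duplicate geometries with conflicting energies; ",
              "keeping the lower energy", call. = FALSE)
  }
  merged <- all_ds[kept_idx, , drop = FALSE]
  rownames(merged) <- NULL
  if (!is.null(cfg)) merged <- apply_filters(merged, cfg)
  attr(merged, "duplicate_conflicts") <- conflicts
  merged
}

#' Dihedral-scan augmentation grids
#'
#' For each reference center, builds a 2-D grid crossing the dihedral angle
#' (full circle, fixed step) with one other coordinate, excluding a window
#' around the center's equilibrium dihedral; the retained far-from-equilibrium
#' points are tagged `"dihedral-augmentation"`. An exclusion window covering
#' the whole circle yields an empty augmentation with a warning.
#'
#' @param centers list of `internal_coords` (or single-row frames).
#' @param second named list with one element `c(min, max, step)`: the second
#'   varying coordinate.
#' @param phi_step dihedral step in degrees (default 20).
#' @param exclude_halfwidth half-width in degrees of the excluded window
#'   around each center's equilibrium dihedral (default 30, i.e. +/- 30).
#' @return labeled-dataset data frame (energies unset).
#' @export
augment_dihedral_scans <- function(centers, second, phi_step = 20,
                                   exclude_halfwidth = 30) {
  if (inherits(centers, "internal_coords") || is.data.frame(centers))
    centers <- list(centers)
  stopifnot(length(second) == 1, names(second) %in%
              setdiff(ic_names, "phi"))
  if (exclude_halfwidth >= 180) {
    warning("exclusion window covers the full circle; empty augmentation",
            call. = FALSE)
    return(NULL)
  }
  out <- list()
  for (ct in centers) {
    ctf <- as_ic_frame(ct)
    phis <- seq(0, 360 - phi_step, by = phi_step)
    if (exclude_halfwidth > 0) {
      dist_to_eq <- abs(((phis - ctf$phi + 180) %% 360) - 180)
      phis <- phis[dist_to_eq > exclude_halfwidth + 1e-9]
    }
    if (!length(phis)) next
    sp <- mesh_spec(ctf, vary = c(list(phi = c(0, 360, phi_step)),
                                  second))
    grid <- generate_rmg(sp, source = "dihedral-augmentation")
    grid <- grid[round(grid$phi, 9) %in% round(phis, 9), , drop = FALSE]
    out[[length(out) + 1L]] <- grid
  }
  if (!length(out)) {
    warning("augmentation produced no points", call. = FALSE)
    return(NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Straight-line transition-path points in internal coordinates
#'
#' Places `n` points along the linear interpolation between two basin centers
#' (the dihedral interpolated along the shorter arc), a cheap stand-in for
#' relaxed-scan isomerization paths; points are tagged `"TS-path"`.
#'
#' @param ic_a,ic_b path endpoints.
#' @param n number of points, endpoints excluded.
#' @return labeled-dataset data frame (energies unset).
#' @export
ts_path <- function(ic_a, ic_b, n = 20) {
  a <- as_ic_frame(ic_a); b <- as_ic_frame(ic_b)
  t <- seq_len(n) / (n + 1)
  out <- as.data.frame(lapply(ic_names, function(nm) {
    if (nm == "phi") {
      d <- ((b$phi - a$phi + 180) %% 360) - 180
      (a$phi + t * d) %% 360
    } else a[[nm]] + t * (b[[nm]] - a[[nm]])
  }))
  names(out) <- ic_names
  out$energy <- NA_real_
  out$source <- "TS-path"
  out
}

#' Write / read a labeled dataset as CSV
#'
#' The header records the package version and the seed (when known) so every
#' artifact is replayable; comment lines start with `#`.
#'
#' @param ds labeled-dataset data frame.
#' @param path file path.
#' @param seed optional seed to record in the header.
#' @return `path` (write) or the data frame (read).
#' @export
write_dataset <- function(ds, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hcnopes dataset v%s seed=%s",
                     as.character(utils::packageVersion("hcnopes")),
                     if (is.null(seed)) "NA" else format(seed)), con)
  utils::write.csv(ds, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
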