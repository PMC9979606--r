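#' Root-mean-squared and mean-absolute error in kcal/mol
#'
#' Inputs are energies in Hartree; results are reported in kcal/mol using
#' the fixed conversion factor 627.5095.
#'
#' @param pred,truth equal-length numeric vectors (Hartree), length >= 1.
#' @return a single value in kcal/mol.
#' @export
rmse <- function(pred, truth) {
  .check_pair(pred, truth)
  hartree_to_kcalmol(sqrt(mean((pred - truth)^2)))
}

#' @rdname rmse
#' @export
mae <- function(pred, truth) {
  .check_pair(pred, truth)
  hartree_to_kcalmol(mean(abs(pred - truth)))
}

.check_pair <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("pred and truth must be equal-length, non-empty", call. = FALSE)
}

#' Content hash of a labeled dataset
#'
#' MD5 of the printed CSV content; used in reports and model containers to
#' tie artifacts to the exact data they came from.
#'
#' @param ds data frame.
#' @return hex digest string.
#' @export
dataset_hash <- function(ds) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  utils::write.csv(ds, tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

#' Evaluation report for a fitted model on a labeled dataset
#'
#' @param model fitted `slnn`, `bpnn` or `gcnn` (anything with a `predict`
#'   method accepting an ic frame and returning Hartree).
#' @param ds labeled-dataset data frame; a `split` column, if present,
#'   yields per-split metrics, otherwise the whole set is reported as one.
#' @param label model identifier recorded in the report.
#' @return object of class `evaluation_report`: per-split RMSE and MAE in
#'   kcal/mol and Hartree, point counts, dataset hash, seed, conversion
#'   factor.
#' @export
evaluation_report <- function(model, ds, label = class(model)[1]) {
  pred <- suppressWarnings(predict(model, ds))
  groups <- if ("split" %in% names(ds)) split(seq_len(nrow(ds)), ds$split)
            else list(all = seq_len(nrow(ds)))
  metrics <- lapply(groups, function(ii) {
    r <- rmse(pred[ii], ds$energy[ii])
    m <- mae(pred[ii], ds$energy[ii])
    stopifnot(r >= m - 1e-12)           # RMSE >= MAE always
    list(rmse_kcalmol = r, mae_kcalmol = m,
         rmse_hartree = kcalmol_to_hartree(r),
         mae_hartree = kcalmol_to_hartree(m), n = length(ii))
  })
  structure(list(model = label, metrics = metrics,
                 n_total = nrow(ds), dataset_hash = dataset_hash(ds),
                 seed = model$seed,
                 kcalmol_per_hartree = .hartree_kcalmol),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation of", x$model, "on", x$n_total, "points\n")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-11s n=%-5d RMSE %8.4f kcal/mol   MAE %8.4f kcal/mol\n",
                nm, m$n, m$rmse_kcalmol, m$mae_kcalmol))
  }
  invisible(x)
}

#' Two-dimensional contour slice through a model or reference surface
#'
#' Evaluates the surface on a regular 2-D grid over two internal
#' coordinates, the remaining four held at `center`. With
#' `symmetry_complete = TRUE`, an angular axis scanned over \[0, 180\] is
#' mirrored to cover the full circle (`E(360 - v) = E(v)`), the presentation
#' device used for angular contour maps; it is off by default.
#'
#' @param surface a fitted model (predict method), a `reference_backend`, a
#'   `surrogate_spec`, or a function mapping an ic frame to energies.
#' @param axes character vector of two distinct coordinate names.
#' @param center an `internal_coords` fixing the other coordinates.
#' @param ranges list of two `c(min, max)` pairs, in `axes` order.
#' @param steps grid steps for the two axes.
#' @param symmetry_complete mirror an angular \[0, 180\] axis to \[0, 360\).
#' @return object of class `pes_contour`: `x`, `y` axis vectors and energy
#'   matrix `z` (Hartree, `length(x)` rows).
#' @export
contour_grid <- function(surface, axes, center, ranges, steps,
                         symmetry_complete = FALSE) {
  stopifnot(length(axes) == 2, !anyDuplicated(axes),
            all(axes %in% ic_names))
  f <- surface_fn(surface)
  xv <- mesh_axis_values(axes[1], c(ranges[[1]], steps[1]))
  yv <- mesh_axis_values(axes[2], c(ranges[[2]], steps[2]))
  grid <- expand.grid(x = xv, y = yv)
  ctf <- as_ic_frame(center)
  ics <- ctf[rep(1, nrow(grid)), , drop = FALSE]
  ics[[axes[1]]] <- grid$x
  ics[[axes[2]]] <- grid$y
  z <- matrix(suppressWarnings(f(ics)), length(xv), length(yv))
  out <- list(axes = axes, x = xv, y = yv, z = z, center = ctf)
  if (symmetry_complete) {
    for (d in 1:2) {
      v <- if (d == 1) out$x else out$y
      if (grepl("^(theta|phi)", axes[d]) && max(v) <= 180 && min(v) >= 0) {
        mirror <- 360 - rev(v[v > 0 & v < 180])
        if (d == 1) {
          out$x <- c(v, mirror)
          out$z <- rbind(out$z,
                         out$z[rev(which(v > 0 & v < 180)), , drop = FALSE])
        } else {
          out$y <- c(v, mirror)
          out$z <- cbind(out$z,
                         out$z[, rev(which(v > 0 & v < 180)), drop = FALSE])
        }
      }
    }
  }
  class(out) <- "pes_contour"
  out
}

surface_fn <- function(surface) {
  if (inherits(surface, "surrogate_spec"))
    return(function(ic) surrogate_energy(ic, surface))
  if (inherits(surface, "reference_backend")) return(surface$fun)
  if (is.function(surface)) return(surface)
  function(ic) predict(surface, ic)
}

#' @export
print.pes_contour <- function(x, ...) {
  cat("PES contour slice over", x$axes[1], "x", x$axes[2], ":",
      length(x$x), "x", length(x$y), "grid, energies",
      format(min(x$z), digits = 6), "to", format(max(x$z), digits = 6),
      "Hartree\n")
  invisible(x)
}

#' @export
plot.pes_contour <- function(x, nlevels = 20, ...) {
  graphics::contour(x$x, x$y, x$z, nlevels = nlevels, xlab = x$axes[1],
                    ylab = x$axes[2], ...)
  invisible(x)
}

#' Write a contour slice as CSV (axis header row and column)
#'
#' @param ct a `pes_contour`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(ct, path) {
  m <- cbind(ct$x, ct$z)
  colnames(m) <- c(paste(ct$axes[1], ct$axes[2], sep = "/"),
                   format(ct$y, trim = TRUE))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Cross-basin transfer experiment
#'
#' Quantifies the failure mode of single-basin training: a model trained
#' only on basin A is evaluated, alongside a model trained on the union, on
#' basin-A points, basin-B points and their union (2 models x 3 sets = 6
#' RMSE cells). The expected ordering - the unified model beats the
#' single-basin model on the union - is asserted-and-reported, not silently
#' assumed.
#'
#' @param model_a model trained on basin A only.
#' @param model_u model trained on the union.
#' @param set_a,set_b labeled evaluation sets for the two basins.
#' @param train_a optional training set of `model_a`, used to warn about
#'   train/eval overlap (count of shared geometries).
#' @return object of class `transfer_result`: data frame `table` with the
#'   six RMSE cells (kcal/mol) and flag `ordering_holds`
#'   (`RMSE_U(union) < RMSE_A(union)`).
#' @export
transfer_experiment <- function(model_a, model_u, set_a, set_b,
                                train_a = NULL) {
  union_set <- rbind(set_a[c(ic_names, "energy")],
                     set_b[c(ic_names, "energy")])
  if (!is.null(train_a)) {
    ov <- sum(ic_key(union_set) %in% ic_key(as_ic_frame(train_a)))
    if (ov > 0)
      warning(ov, " evaluation point(s) overlap the basin-A training set",
              call. = FALSE)
  }
  sets <- list(basin_a = set_a, basin_b = set_b, union = union_set)
  cell <- function(model, ds)
    rmse(suppressWarnings(predict(model, ds)), ds$energy)
  tab <- expand.grid(model = c("basin_a_only", "unified"),
                     eval_set = names(sets), stringsAsFactors = FALSE)
  tab$rmse_kcalmol <- mapply(function(mo, se) {
    cell(if (mo == "basin_a_only") model_a else model_u, sets[[se]])
  }, tab$model, tab$eval_set)
  ru <- tab$rmse_kcalmol[tab$model == "unified" & tab$eval_set == "union"]
  ra <- tab$rmse_kcalmol[tab$model == "basin_a_only" &
                           tab$eval_set == "union"]
  structure(list(table = tab, ordering_holds = ru < ra + 1e-12,
                 union_rmse_basin_only = ra, union_rmse_unified = ru),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("Cross-basin transfer experiment (RMSE, kcal/mol):\n")
  print(x$table, row.names = FALSE)
  cat(if (x$ordering_holds)
    "unified model is better on the union set\n"
    else "WARNING: unified model is NOT better on the union set\n")
  invisible(x)
}
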