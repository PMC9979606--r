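#' Unified / improved-unified training workflow
#'
#' Orchestrates the full pipeline behind the unified multi-basin surface:
#' label a regular mesh grid per basin with the reference backend, add
#' transition-path points, merge with duplicate removal and the
#' preprocessing filters into the unified set (U); optionally append the
#' far-from-equilibrium dihedral-scan augmentation (the improved unified
#' set, IU; the augmentation deliberately bypasses the dihedral filter,
#' which exists precisely to remove out-of-plane redundancy that the
#' augmentation reinstates in a controlled way); split, train the requested
#' architecture, and evaluate. Every artifact carries provenance, and all
#' randomness derives from `seed`, so two runs with the same inputs are
#' bit-identical.
#'
#' @param basin_meshes named list of [mesh_spec]s, one per basin; names
#'   become provenance tags.
#' @param ts_pairs optional list of center pairs
#'   (`list(ic_a, ic_b)`), each expanded into a straight transition path
#'   via [ts_path].
#' @param backend a `reference_backend` or `surrogate_spec` labeling all
#'   generated points.
#' @param model architecture to train.
#' @param improved build the IU set (dihedral-scan augmentation).
#' @param cfg preprocessing [filter_config].
#' @param fractions split fractions.
#' @param ts_n points per transition path.
#' @param augment arguments for [augment_dihedral_scans]: a list with
#'   elements `second`, `phi_step`, `exclude_halfwidth`.
#' @param model_args extra arguments passed to the model fitting function.
#' @param seed master seed.
#' @param outdir optional directory: writes `dataset.csv`, `model.json`,
#'   `report.json` and `manifest.json`; partial results are still written
#'   if training fails.
#' @return list with `model`, `dataset`, `report` (an
#'   [evaluation_report]) and `manifest`.
#' @export
run_unified_workflow <- function(basin_meshes, ts_pairs = NULL,
                                 backend = default_surrogate(),
                                 model = c("slnn", "bpnn", "gcnn"),
                                 improved = FALSE, cfg = filter_config(),
                                 fractions = c(train = 0.8,
                                               validation = 0.1,
                                               test = 0.1),
                                 ts_n = 40,
                                 augment = list(
                                   second = list(theta1 = c(60, 160, 20)),
                                   phi_step = 20, exclude_halfwidth = 30),
                                 model_args = list(), seed = 1,
                                 outdir = NULL) {
  model <- match.arg(model)
  if (inherits(backend, "surrogate_spec")) backend <- surrogate_backend(backend)
  if (is.null(names(basin_meshes)))
    names(basin_meshes) <- paste0("S", seq_along(basin_meshes))
  basins <- lapply(names(basin_meshes), function(nm)
    sample_labeled_dataset(basin_meshes[[nm]], backend, source = nm))
  ts_points <- NULL
  if (!is.null(ts_pairs) && length(ts_pairs)) {
    ts_points <- do.call(rbind, lapply(ts_pairs, function(pr) {
      p <- ts_path(pr[[1]], pr[[2]], n = ts_n)
      p$energy <- backend$fun(p)
      p
    }))
  }
  merged <- merge_unified(basins, ts_points, cfg)
  removal <- attr(merged, "removal_report")
  n_aug <- 0L
  if (improved) {
    aug <- augment_dihedral_scans(
      centers = lapply(basin_meshes, `[[`, "center"),
      second = augment$second,
      phi_step = augment$phi_step %||% 20,
      exclude_halfwidth = augment$exclude_halfwidth %||% 30)
    if (!is.null(aug)) {
      aug$energy <- backend$fun(aug)
      cfg_aug <- cfg
      cfg_aug$dihedral_range <- NULL    # full-circle scans are the point
      aug <- apply_filters(aug, cfg_aug)
      n_aug <- nrow(aug)
      merged <- merge_unified(list(merged, aug), cfg = NULL)
    }
  }
  ds <- split_dataset(merged, fractions, seed = derive_seed(seed, 101))
  if (!is.null(outdir)) {               # dataset persists even if the fit dies
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(ds, file.path(outdir, "dataset.csv"), seed = seed)
  }
  fit <- do.call(model, c(list(data = ds, seed = derive_seed(seed, 202)),
                          model_args))
  report <- evaluation_report(fit, ds,
                              label = paste0(if (improved) "IU-" else "U-",
                                             model))
  manifest <- list(
    workflow = if (improved) "improved-unified" else "unified",
    model = model, seed = seed,
    package_version = as.character(utils::packageVersion("hcnopes")),
    backend = backend$label,
    filters = unclass(cfg),
    fractions = as.list(fractions),
    n_per_basin = stats::setNames(vapply(basins, nrow, 1L),
                                  names(basin_meshes)),
    n_ts = if (is.null(ts_points)) 0L else nrow(ts_points),
    n_augmentation = n_aug,
    removal_report = as.list(removal),
    n_unified = nrow(ds),
    dataset_hash = dataset_hash(ds),
    rmse_kcalmol = as.list(fit$rmse))
  if (!is.null(outdir)) {
    save_model(fit, file.path(outdir, "model.json"))
    writeLines(jsonlite::toJSON(
      list(model = report$model, metrics = report$metrics,
           dataset_hash = report$dataset_hash),
      auto_unbox = TRUE, digits = NA),
      file.path(outdir, "report.json"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               file.path(outdir, "manifest.json"))
  }
  list(model = fit, dataset = ds, report = report, manifest = manifest)
}
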