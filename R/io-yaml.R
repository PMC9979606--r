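# YAML serialization for the two human-editable configuration objects: the
# surrogate surface specification and the symmetry-function descriptor set.

#' Read / write a surrogate specification as YAML
#'
#' @param spec a `surrogate_spec`.
#' @param path file path (conventionally `.yaml`).
#' @return `write_surrogate_yaml` returns `path` invisibly;
#'   `read_surrogate_yaml` returns the `surrogate_spec`.
#' @export
write_surrogate_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "surrogate_spec"))
  obj <- list(
    offset = spec$offset, smoothness = spec$smoothness,
    basins = lapply(spec$basins, function(b) list(
      label = b$label,
      center = as.list(b$center[1, ]),
      depth = b$depth, de = as.numeric(b$de), a = as.numeric(b$a),
      k_theta = as.numeric(b$k_theta), a_phi = b$a_phi)))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_surrogate_yaml
#' @export
read_surrogate_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  basins <- lapply(obj$basins, function(b)
    surrogate_basin(b$label,
                    do.call(internal_coords, b$center),
                    depth = b$depth, de = unlist(b$de), a = unlist(b$a),
                    k_theta = unlist(b$k_theta), a_phi = b$a_phi))
  surrogate_spec(basins, offset = obj$offset, smoothness = obj$smoothness)
}

#' Read / write a descriptor set as YAML
#'
#' The serialized order is the feature order, so a descriptor file uniquely
#' pins down the feature layout of any model trained with it.
#'
#' @param dset a `descriptor_set`.
#' @param path file path.
#' @return `write_descriptors_yaml` returns `path` invisibly;
#'   `read_descriptors_yaml` returns the `descriptor_set`.
#' @export
write_descriptors_yaml <- function(dset, path) {
  stopifnot(inherits(dset, "descriptor_set"))
  obj <- list(rc = dset$rc, elements = as.list(dset$elements),
              functions = lapply(dset$functions, function(p)
                list(kind = p$kind, eta = p$eta, rs = p$rs,
                     zeta = p$zeta, gamma = p$gamma, rc = p$rc)))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_descriptors_yaml
#' @export
read_descriptors_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  fns <- lapply(obj$functions, function(p)
    sym_function(p$kind, eta = p$eta, rs = p$rs, zeta = p$zeta,
                 gamma = p$gamma, rc = p$rc))
  structure(list(functions = fns, rc = obj$rc,
                 elements = unlist(obj$elements)),
            class = "descriptor_set")
}
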