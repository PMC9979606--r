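# Model persistence: a self-describing JSON container. Doubles are encoded
# as "%.17g" strings, which round-trip IEEE values bit-exactly; structure is
# preserved by a small recursive codec for the R types models contain.

obj_enc <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.function(x) || is.call(x)) stop("cannot serialize ", class(x)[1])
  if (is.data.frame(x))
    return(list(t = "df", names = as.list(names(x)),
                v = lapply(x, obj_enc)))
  if (is.list(x)) {
    cl <- setdiff(class(x), "list")
    return(list(t = "list",
                class = if (length(cl)) as.list(cl),
                names = if (!is.null(names(x))) as.list(names(x)),
                v = lapply(unclass(x), obj_enc)))
  }
  meta <- list(dim = as.list(dim(x)),
               names = if (!is.null(names(x))) as.list(names(x)),
               dimnames = if (!is.null(dimnames(x)))
                 lapply(dimnames(x), function(d)
                   if (is.null(d)) list() else as.list(d)),
               class = {cl <- setdiff(class(x),
                                      c("numeric", "integer", "character",
                                        "logical", "matrix", "array"))
                        if (length(cl)) as.list(cl)})
  if (is.numeric(x))
    return(c(list(t = "num", v = as.list(sprintf("%.17g", x))), meta))
  if (is.character(x)) return(c(list(t = "chr", v = as.list(x)), meta))
  if (is.logical(x)) return(c(list(t = "lgl", v = as.list(x)), meta))
  stop("cannot serialize object of class ", class(x)[1])
}

obj_dec <- function(e) {
  restore_meta <- function(v) {
    if (length(e$dim)) dim(v) <- unlist(e$dim)
    if (length(e$dimnames))
      dimnames(v) <- lapply(e$dimnames, function(d)
        if (length(d)) unlist(d) else NULL)
    if (length(e$names)) names(v) <- unlist(e$names)
    if (length(e$class)) class(v) <- unlist(e$class)
    v
  }
  switch(e$t,
    null = NULL,
    num = restore_meta(as.numeric(unlist(e$v))),
    chr = restore_meta(unlist(e$v)),
    lgl = restore_meta(as.logical(unlist(e$v))),
    df = {
      cols <- lapply(e$v, obj_dec)
      names(cols) <- unlist(e$names)
      as.data.frame(cols, stringsAsFactors = FALSE)
    },
    list = {
      v <- lapply(e$v, obj_dec)
      if (length(e$names)) names(v) <- unlist(e$names)
      if (length(e$class)) class(v) <- unlist(e$class)
      v
    },
    stop("unknown encoded type ", e$t))
}

.model_format_version <- 1L

#' Save / load a fitted model
#'
#' Models are stored in a self-describing JSON container (architecture tag,
#' format version, package version, master seed and dataset hash alongside
#' all weights, descriptor sets and scalers). Doubles are written with 17
#' significant digits so that save-load-predict reproduces the original
#' predictions bit-exactly.
#'
#' @param model a fitted `slnn`, `bpnn` or `gcnn`.
#' @param path file path (conventionally `.json`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  arch <- intersect(class(model), c("slnn", "bpnn", "gcnn"))
  if (length(arch) != 1) stop("not a saveable model", call. = FALSE)
  body <- unclass(model)
  body$call <- NULL
  container <- list(format = "hcnopes-model",
                    version = .model_format_version,
                    architecture = arch,
                    package_version =
                      as.character(utils::packageVersion("hcnopes")),
                    body = obj_enc(body))
  writeLines(jsonlite::toJSON(container, auto_unbox = TRUE, null = "null"),
             path)
  invisible(path)
}

#' @rdname save_model
#' @param expected_class optionally require the container to hold this
#'   architecture (`"slnn"`, `"bpnn"` or `"gcnn"`); a mismatch raises an
#'   error of class `hcnopes_model_type_error`.
#' @export
load_model <- function(path, expected_class = NULL) {
  container <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(container$format, "hcnopes-model"))
    stop("not an hcnopes model container", call. = FALSE)
  if (!identical(as.integer(container$version), .model_format_version))
    stop("model container format version ", container$version,
         " needs migration; this build reads version ",
         .model_format_version, call. = FALSE)
  if (!is.null(expected_class) &&
      !identical(container$architecture, expected_class))
    stop(errorCondition(
      paste0("container holds a ", container$architecture,
             " model, not ", expected_class),
      class = c("hcnopes_model_type_error", "error")))
  model <- obj_dec(container$body)
  class(model) <- container$architecture
  model
}
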