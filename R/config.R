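# Structured run configuration: YAML file + programmatic overrides, with a
# content hash written next to every run's outputs.

#' Resolve a run configuration
#'
#' Starts from the [dcgat_config] defaults, overlays key/value pairs from an
#' optional YAML file, then overlays explicit overrides (highest
#' precedence). The resolved configuration carries an MD5 content hash.
#'
#' @param file optional YAML file path.
#' @param overrides named list of overrides.
#' @return a [dcgat_config] with attributes `hash` and `resolved` (the
#'   canonical text representation).
#' @export
resolve_config <- function(file = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(file)) {
    stop_if(!file.exists(file), "config file not found: ", file)
    vals <- yaml::read_yaml(file)
  }
  vals[names(overrides)] <- overrides
  cfg <- do.call(dcgat_config, vals)
  txt <- config_text(cfg)
  tmp <- tempfile(); writeLines(txt, tmp)
  attr(cfg, "hash") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  attr(cfg, "resolved") <- txt
  cfg
}

config_text <- function(cfg) {
  flat <- lapply(cfg, function(v) paste(format(v, digits = 15), collapse = ","))
  paste0(names(cfg), ": ", unlist(flat))
}

#' Write a resolved configuration next to run outputs
#' @param cfg a config from [resolve_config] (or [dcgat_config]).
#' @param dir output directory.
#' @return path of the written file, invisibly.
#' @export
write_resolved_config <- function(cfg, dir) {
  txt <- attr(cfg, "resolved") %||% config_text(cfg)
  hash <- attr(cfg, "hash")
  if (is.null(hash)) {
    tmp <- tempfile(); writeLines(txt, tmp)
    hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  }
  path <- file.path(dir, "resolved_config.txt")
  writeLines(c(paste0("# config_hash: ", hash), txt), path)
  invisible(path)
}

#' Save a fitted model as a checkpoint file
#'
#' Single-file JSON archive holding every named parameter tensor with its
#' shape, the configuration, and the configuration hash.
#'
#' @param fit a `dcgat_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  cfg <- fit$config
  tensors <- lapply(fit$params, function(m)
    list(dim = dim(m), data = as.vector(m)))
  obj <- list(config = unclass(cfg),
              config_hash = attr(resolve_config(overrides = unclass(cfg)),
                                 "hash"),
              seed = fit$seed, thresholds = fit$thresholds,
              tensors = tensors)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint]
#' @param path checkpoint file.
#' @return a `dcgat_fit` (without training history).
#' @export
load_checkpoint <- function(path) {
  stop_if(!file.exists(path), "checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$tensors, function(t)
    matrix(t$data, t$dim[1], t$dim[2]))
  cfgl <- obj$config
  cfgl$threshold_protein <- as.list(cfgl$threshold_protein)
  cfgl$threshold_drug <- as.list(cfgl$threshold_drug)
  structure(list(params = params, config = do.call(dcgat_config, cfgl),
                 history = NULL, thresholds = obj$thresholds,
                 seed = obj$seed),
            class = "dcgat_fit")
}

#' Export a selection log as TSV
#' @param selection_log data.frame from [dcgat_forward].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_log <- function(selection_log, path) {
  utils::write.table(selection_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
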