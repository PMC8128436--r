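#' Save / load a trained model artifact
#'
#' A model artifact is a weights file (`<path>`, serialized R object)
#' accompanied by a JSON metadata sidecar (`<path>.json`) recording kind,
#' encoder layout, configuration and seed, so a prediction run can verify
#' it is using the encoder settings the model was trained with.
#'
#' @param model an `az_model`.
#' @param path file path for the weights; the sidecar is written next to it.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `az_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "az_model"))
  saveRDS(model, path)
  sidecar <- list(
    kind = model$kind,
    encoder = model$meta,
    config = if (!is.null(model$config)) unclass(model$config) else NULL,
    seed = if (!is.null(model$config)) model$config$seed else model$seed,
    package = "aptazyme"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "az_model")) {
    az_stop("az_io_error", "'%s' does not contain an az_model", path)
  }
  model
}
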