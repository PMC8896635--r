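#' Save / load an encoder checkpoint bundle
#'
#' The bundle holds the architecture configuration, every weight tensor and
#' both vocabularies, and round-trips exactly.
#'
#' @param model a [CrossEncoder-class].
#' @param path file path (`.rds`).
#' @return `path` / the restored [CrossEncoder-class].
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "CrossEncoder"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  model <- readRDS(path)
  if (!is(model, "CrossEncoder")) stop("not a checkpoint bundle: ", path)
  model
}
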