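# Checkpoint persistence: weight archive plus a JSON sidecar carrying the
# configuration, vocabulary hash and provenance.

config_hash <- function(x) {
  # stable short fingerprint of a configuration list
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(s)) %% 251 + 1)) %% .Machine$integer.max)
}

#' Save a checkpoint (weights + JSON sidecar)
#'
#' @param checkpoint A `cgm_checkpoint` or `cgm_classifier`.
#' @param path Base path; writes `<path>.rds` and `<path>.json`.
#' @return Base path, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, paste0(path, ".rds"))
  sidecar <- list(checkpoint_id = checkpoint$checkpoint_id,
                  class = class(checkpoint)[1L],
                  config = unclass(checkpoint$config),
                  config_hash = config_hash(unclass(checkpoint$config)),
                  vocab_size = checkpoint$config$vocab_size,
                  saved = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path Base path used at save time.
#' @return The checkpoint object.
#' @export
load_checkpoint <- function(path) {
  readRDS(paste0(path, ".rds"))
}
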