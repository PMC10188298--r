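# Checkpoint directory layout: config.json (config snapshot), vocabulary.txt
# (one token per line), weights.rds (parameter trees), loss_trace.csv.

#' Save a pretrained model to a checkpoint directory
#'
#' @param result Result list of [claps_pretrain()] (elements `model`, `pss`,
#'   `loss_trace`), or a bare `claps_model`.
#' @param dir Directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(result, dir) {
  if (inherits(result, "claps_model")) {
    result <- list(model = result, pss = NULL, loss_trace = numeric(0))
  }
  model <- result$model
  stopifnot(inherits(model, "claps_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(model$vocab$tokens, file.path(dir, "vocabulary.txt"))
  saveRDS(list(params = model$params, pss = result$pss),
          file.path(dir, "weights.rds"))
  if (length(result$loss_trace)) {
    utils::write.csv(
      data.frame(epoch = seq_along(result$loss_trace),
                 mean_loss = result$loss_trace),
      file.path(dir, "loss_trace.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Load a checkpoint directory
#'
#' Restores the model (and PSS network, if saved).  Loading a checkpoint
#' whose vocabulary size disagrees with its stored embedding matrix is an
#' error.
#'
#' @param dir Checkpoint directory written by [save_checkpoint()].
#' @return List with `model`, `pss`, `loss_trace`.
#' @export
load_checkpoint <- function(dir) {
  need <- file.path(dir, c("config.json", "vocabulary.txt", "weights.rds"))
  if (!all(file.exists(need))) {
    stop(sprintf("load_checkpoint: %s is not a checkpoint directory", dir))
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$proj_dims <- as.integer(cfg$proj_dims)
  cfg$predictor_widths <- as.integer(cfg$predictor_widths)
  config <- do.call(claps_config, cfg)
  tokens <- readLines(file.path(dir, "vocabulary.txt"))
  w <- readRDS(file.path(dir, "weights.rds"))
  if (!all(c("<pad>", "<mask>") %in% tokens) ||
      nrow(w$params$emb) != length(tokens)) {
    stop("load_checkpoint: vocabulary size does not match embedding table")
  }
  ids <- stats::setNames(seq_along(tokens), tokens)
  vocab <- structure(
    list(tokens = tokens, ids = ids,
         pad_id = unname(ids[["<pad>"]]), mask_id = unname(ids[["<mask>"]])),
    class = "claps_vocabulary")
  model <- structure(
    list(params = w$params,
         pe = positional_encoding(config$C, config$d),
         vocab = vocab, config = config),
    class = "claps_model")
  trace_file <- file.path(dir, "loss_trace.csv")
  loss_trace <- if (file.exists(trace_file)) {
    utils::read.csv(trace_file)$mean_loss
  } else {
    numeric(0)
  }
  list(model = model, pss = w$pss, loss_trace = loss_trace)
}
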