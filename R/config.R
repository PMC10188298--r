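# Run configuration: validated defaults for every stage of the pipeline.

.claps_defaults <- function() {
  list(
    # masking / positive-sample selection
    strategy = "roulette",        # roulette | top | random
    ratio = 0.25,                 # weight masking ratio
    roulette_occurrence = FALSE,  # frequency-based roulette variant
    pss_heads = 3L,
    pss_layers = 2L,
    # encoder
    d = 128L,
    C = 220L,
    enc_layers = 3L,
    enc_heads = 4L,
    ff_mult = 4L,
    proj_dims = c(2048L, 512L),
    dropout = 0.2,
    pool = "mean",                # mean | sum over non-pad positions
    # contrastive pretraining
    temperature = 0.1,
    batch = 1500L,
    lr_pretrain = 1e-3,
    epochs_pretrain = 30L,
    # property prediction
    predictor_widths = c(4096L, 512L, 64L),
    lr_finetune = 1e-4,
    epochs_finetune = 100L,
    patience = 10L,
    batch_finetune = 32L,
    freeze_encoder = FALSE,
    seed = 7L
  )
}

#' Build a validated run configuration
#'
#' Returns the full configuration used across pretraining and fine-tuning,
#' with defaults taken from the method's published settings: roulette
#' masking at ratio 0.25, batch size 1500, projection head (2048, 512),
#' learning rates 1e-3 (pretraining) and 1e-4 (prediction), dropout 0.2,
#' 30 pretraining epochs, a 3-head PSS network, a 3-layer 4-head encoder,
#' and a (4096, 512, 64) predictor.  Unknown keys are rejected and every
#' value is validated.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `claps_config`.
#' @examples
#' cfg <- claps_config(d = 32L, batch = 64L, epochs_pretrain = 5L)
#' cfg$strategy
#' @export
claps_config <- function(...) {
  cfg <- .claps_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over))))) {
    stop("claps_config: all overrides must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop(sprintf("claps_config: unknown key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(unknown, collapse = ", ")))
  }
  for (k in names(over)) {
    v <- over[[k]]
    proto <- cfg[[k]]
    if (is.integer(proto) && is.numeric(v)) v <- as.integer(v)
    cfg[[k]] <- v
  }
  .validate_config(cfg)
  structure(cfg, class = c("claps_config", "list"))
}

.validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(sprintf("claps_config: %s", msg))
  chk(cfg$strategy %in% c("roulette", "top", "random"),
      "strategy must be roulette, top or random")
  chk(is.numeric(cfg$ratio) && cfg$ratio > 0 && cfg$ratio < 1,
      "ratio must lie in (0,1)")
  chk(cfg$d >= 2L && cfg$d %% 2L == 0L, "d must be even and >= 2")
  chk(cfg$d %% cfg$enc_heads == 0L, "d must be divisible by enc_heads")
  chk(cfg$C >= 1L, "C must be >= 1")
  chk(cfg$enc_layers >= 1L && cfg$enc_heads >= 1L, "encoder shape invalid")
  chk(cfg$pss_heads >= 1L && cfg$pss_layers >= 1L, "PSS shape invalid")
  chk(length(cfg$proj_dims) == 2L && all(cfg$proj_dims >= 1L),
      "proj_dims must be two positive widths")
  chk(is.numeric(cfg$dropout) && cfg$dropout >= 0 && cfg$dropout < 1,
      "dropout must lie in [0,1)")
  chk(cfg$pool %in% c("mean", "sum"), "pool must be mean or sum")
  chk(cfg$temperature > 0, "temperature must be > 0")
  chk(cfg$batch >= 2L, "batch must be >= 2")
  chk(cfg$lr_pretrain > 0 && cfg$lr_finetune > 0, "learning rates must be > 0")
  chk(cfg$epochs_pretrain >= 1L && cfg$epochs_finetune >= 1L,
      "epoch counts must be >= 1")
  chk(all(cfg$predictor_widths >= 1L), "predictor widths must be positive")
  chk(cfg$patience >= 1L, "patience must be >= 1")
  chk(cfg$batch_finetune >= 1L, "batch_finetune must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be a number")
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' A flat key-value YAML file with any subset of the [claps_config()] keys;
#' `overrides` (e.g. parsed command-line flags) win over file values.
#'
#' @param path Path to the YAML file, or `NULL` for defaults only.
#' @param overrides Named list applied after the file.
#' @return A `claps_config`.
#' @export
claps_config_from_yaml <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(vals)) stop("claps_config_from_yaml: file must hold a mapping")
  vals[names(overrides)] <- overrides
  do.call(claps_config, vals)
}
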