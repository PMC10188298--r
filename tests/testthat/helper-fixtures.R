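# Shared desk-scale fixtures. Everything is generated in code; the tiny
# config keeps forward/backward passes fast while exercising every layer.

tiny_config <- function(...) {
  base <- list(d = 16L, C = 60L, enc_layers = 2L, enc_heads = 2L,
               ff_mult = 2L, proj_dims = c(24L, 16L),
               predictor_widths = c(16L, 8L, 4L), batch = 8L,
               epochs_pretrain = 2L, epochs_finetune = 5L, patience = 3L,
               dropout = 0, seed = 7L)
  do.call(claps_config, utils::modifyList(base, list(...)))
}

tiny_corpus <- c("CCOc1ccccc1", "CCN", "c1ccsc1CC", "NCCO", "CC(C)Cl",
                 "c1ccncc1CCO", "SCCS", "BrCCc1ccco1")

tiny_model <- function(cfg = tiny_config()) {
  init_claps_model(build_vocabulary(tiny_corpus), cfg)
}

# Brute-force NT-Xent with explicit loops, straight from the defining
# formulas; the reference the fast implementation is checked against.
ntxent_oracle <- function(Z, temperature) {
  n <- nrow(Z)
  sim <- function(i, j) {
    sum(Z[i, ] * Z[j, ]) / (sqrt(sum(Z[i, ]^2)) * sqrt(sum(Z[j, ]^2)))
  }
  pair_loss <- function(i, j) {
    den <- 0
    for (k in seq_len(n)) {
      if (k != i) den <- den + exp(sim(i, k) / temperature)
    }
    -log(exp(sim(i, j) / temperature) / den)
  }
  total <- 0
  for (k in seq_len(n / 2)) {
    total <- total + pair_loss(2 * k - 1, 2 * k) + pair_loss(2 * k, 2 * k - 1)
  }
  total / n
}

# Exhaustive pairwise ROC-AUC: mean over all positive-negative pairs of
# 1, 1/2 (tie) or 0.
auc_oracle <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}
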