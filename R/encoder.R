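# The transformer encoder (3 layers x 4 heads by default), pad-aware
# pooling, and the bias-free two-layer projection head used for the
# contrastive objective.

#' Initialize a SMILES encoder model
#'
#' Creates the full trainable model: token-embedding table (entries drawn
#' from N(0,1)), fixed sinusoidal positional encoding, a stack of
#' transformer encoder layers (multi-head self-attention and a two-linear
#' ReLU feed-forward sublayer, each wrapped in residual + layer
#' normalization), and the bias-free projection head
#' `z = ReLU(h W2) W1` used during contrastive pretraining.
#'
#' @param vocab A `claps_vocabulary`.
#' @param config A [claps_config()] list; `d`, `C`, `enc_layers`,
#'   `enc_heads`, `ff_mult`, `proj_dims`, `dropout`, `pool` and `seed` are
#'   used.
#' @return An object of class `claps_model`.
#' @export
init_claps_model <- function(vocab, config = claps_config()) {
  stopifnot(inherits(vocab, "claps_vocabulary"))
  d <- config$d
  if (d %% config$enc_heads != 0L) {
    stop("init_claps_model: d must be divisible by enc_heads")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  V <- length(vocab$tokens)
  params <- list(
    emb = matrix(stats::rnorm(V * d), V, d),
    layers = lapply(seq_len(config$enc_layers), function(l) {
      .init_enc_layer(d, config$ff_mult * d)
    }),
    proj = list(W2 = .xavier(d, config$proj_dims[1]),
                W1 = .xavier(config$proj_dims[1], config$proj_dims[2]))
  )
  structure(
    list(params = params,
         pe = positional_encoding(config$C, d),
         vocab = vocab,
         config = config),
    class = "claps_model"
  )
}

#' @export
print.claps_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<claps_model> d=%d C=%d, %d encoder layers x %d heads, proj (%s), vocab %d\n",
    cfg$d, cfg$C, cfg$enc_layers, cfg$enc_heads,
    paste(cfg$proj_dims, collapse = ", "), length(x$vocab$tokens)))
  invisible(x)
}

#' One transformer encoder layer
#'
#' Applies multi-head self-attention (per-head value projections and an
#' output projection) with residual + layer norm, then the two-linear ReLU
#' feed-forward sublayer with residual + layer norm.  Attention is computed
#' only over the first `true_length` positions, so pad positions are never
#' attended to; rows at and beyond `true_length` pass through unchanged.
#'
#' @param X `C x d` input matrix.
#' @param params Layer parameter list (one element of
#'   `model$params$layers`).
#' @param true_length Number of non-pad positions.
#' @param heads Number of attention heads.
#' @param dropout Dropout rate (0 disables; active only if
#'   `training = TRUE`).
#' @param training Logical; enables dropout.
#' @return `C x d` output matrix.
#' @export
encoder_layer <- function(X, params, true_length, heads = 4L,
                          dropout = 0, training = FALSE) {
  if (!is.matrix(X) || ncol(X) %% heads != 0L) {
    stop("encoder_layer: X must be a matrix with ncol divisible by heads")
  }
  if (nrow(params$Wq) != ncol(X)) stop("encoder_layer: shape mismatch")
  stopifnot(true_length >= 1L, true_length <= nrow(X))
  L <- true_length
  out <- X
  out[seq_len(L), ] <- .enc_layer_fwd(X[seq_len(L), , drop = FALSE], params,
                                      heads, dropout, training)$out
  out
}

# Forward pass through embeddings + all encoder layers + pooling for one
# encoded molecule. Returns pooled h and the caches for backprop.
.encoder_fwd <- function(model, mol, training = FALSE) {
  L <- mol$true_length
  ids <- mol$token_ids[seq_len(L)]
  X <- model$params$emb[ids, , drop = FALSE] +
    model$pe[seq_len(L), , drop = FALSE]
  caches <- vector("list", length(model$params$layers))
  H <- X
  for (l in seq_along(model$params$layers)) {
    caches[[l]] <- .enc_layer_fwd(H, model$params$layers[[l]],
                                  model$config$enc_heads,
                                  model$config$dropout, training)
    H <- caches[[l]]$out
  }
  h <- if (identical(model$config$pool, "sum")) colSums(H) else colMeans(H)
  list(h = h, ids = ids, caches = caches, L = L)
}

# Backward from dh (gradient on pooled h) to gradients on all parameters.
# Returns a tree shaped like model$params (emb gradient is dense V x d).
.encoder_bwd <- function(model, fwd, dh) {
  L <- fwd$L
  d <- model$config$d
  dH <- matrix(rep(dh, each = L), L, d)
  if (!identical(model$config$pool, "sum")) dH <- dH / L
  layer_grads <- vector("list", length(model$params$layers))
  for (l in rev(seq_along(model$params$layers))) {
    bk <- .enc_layer_bwd(dH, fwd$caches[[l]], model$params$layers[[l]],
                         model$config$enc_heads)
    layer_grads[[l]] <- bk$grads
    dH <- bk$dX
  }
  demb <- matrix(0, nrow(model$params$emb), d)
  agg <- rowsum(dH, fwd$ids)
  demb[as.integer(rownames(agg)), ] <- agg
  list(emb = demb, layers = layer_grads)
}

#' Encode a molecule to its representation vector
#'
#' Runs the full encoder stack in evaluation mode (dropout off) and pools
#' the per-position outputs over the non-pad positions (mean by default,
#' sum if the model was configured with `pool = "sum"`).
#'
#' @param mol A `claps_encoded` (or a SMILES string, which is encoded with
#'   the model's vocabulary and `C` first).
#' @param model A `claps_model`.
#' @return Numeric vector `h` of length `d`.
#' @export
encode_molecule <- function(mol, model) {
  stopifnot(inherits(model, "claps_model"))
  if (is.character(mol)) mol <- encode(mol, model$vocab, model$config$C)
  .encoder_fwd(model, mol, training = FALSE)$h
}

#' Project a representation into the contrastive space
#'
#' The bias-free two-layer perceptron `z = ReLU(h W2) W1`.
#'
#' @param h Numeric vector (length `d`) or matrix with one representation
#'   per row.
#' @param model A `claps_model` (its projection head is used).
#' @return Projection `z` as a vector, or a matrix with one row per input
#'   row.
#' @export
project <- function(h, model) {
  stopifnot(inherits(model, "claps_model"))
  vec <- !is.matrix(h)
  H <- if (vec) matrix(h, 1L) else h
  if (any(!is.finite(H))) stop("project: non-finite representation")
  Z <- .proj_fwd(H, model$params$proj)$out
  if (vec) Z[1L, ] else Z
}

.proj_fwd <- function(H, p) {
  A <- H %*% p$W2
  R <- relu(A)
  list(out = R %*% p$W1, H = H, A = A, R = R)
}

.proj_bwd <- function(dZ, cache, p) {
  dW1 <- crossprod(cache$R, dZ)
  dR <- tcrossprod(dZ, p$W1)
  dA <- dR * (cache$A > 0)
  list(dH = tcrossprod(dA, p$W2),
       grads = list(W2 = crossprod(cache$H, dA), W1 = dW1))
}
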