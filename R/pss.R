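# Positive-sample selection: a small multilayer multi-head self-attention
# network scores every character of a SMILES string, and the scores drive
# one of three masking strategies that produce the positive view for
# contrastive learning.

#' Initialize the positive-sample-selection attention network
#'
#' A multilayer multi-head self-attention network with per-head query/key
#' parameter matrices of shape `d x d_k`.  Each layer computes per-head
#' attention `softmax(X Wq (X Wk)^T / sqrt(d))` over the non-pad positions
#' and forwards the head-averaged mixture `mean_i(Att_i X)` to the next
#' layer; the last layer's attention matrices are consumed for the
#' character weight vector.  Mask selection is discrete sampling, so no
#' gradient reaches these parameters and they remain at their seeded
#' initialization.
#'
#' @param d Model dimension of the inputs `X`.
#' @param heads Number of attention heads (default 3).
#' @param layers Number of attention layers (default 2).
#' @param d_k Per-head query/key width; defaults to `d %/% heads`.
#' @param seed Integer seed for the initialization.
#' @return An object of class `claps_pss`.
#' @export
init_pss <- function(d, heads = 3L, layers = 2L, d_k = NULL, seed = 1L) {
  stopifnot(heads >= 1L, layers >= 1L, d >= 1L)
  if (is.null(d_k)) d_k <- max(1L, d %/% heads)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- lapply(seq_len(layers), function(l) {
    lapply(seq_len(heads), function(h) {
      list(Wq = .xavier(d, d_k), Wk = .xavier(d, d_k))
    })
  })
  structure(list(params = params, d = d, heads = heads, layers = layers,
                 d_k = d_k),
            class = "claps_pss")
}

#' Per-head attention matrices of the PSS network
#'
#' Restricted to the non-pad positions: with `L = true_length`, each head
#' of the final layer yields an `L x L` matrix
#' `softmax(X Wq (X Wk)^T / sqrt(d))` whose rows are probability vectors.
#'
#' @param X `C x d` (or `L x d`) embedded input.
#' @param net A `claps_pss`.
#' @param true_length Number of non-pad positions `L >= 1`.
#' @return List of `L x L` matrices, one per head.
#' @export
attention_matrix <- function(X, net, true_length) {
  stopifnot(inherits(net, "claps_pss"))
  if (is.null(true_length) || true_length < 1L) {
    stop("attention_matrix: true_length must be >= 1")
  }
  if (ncol(X) != net$d) stop("attention_matrix: X has wrong dimension")
  H <- X[seq_len(true_length), , drop = FALSE]
  att <- NULL
  for (layer in net$params) {
    att <- lapply(layer, function(hp) {
      .softmax_rows(tcrossprod(H %*% hp$Wq, H %*% hp$Wk) / sqrt(net$d))
    })
    H <- Reduce(`+`, lapply(att, function(A) A %*% H)) / length(att)
  }
  att
}

#' Aggregate attention into a per-character weight vector
#'
#' Sums the per-head attention matrices and then the rows of the result:
#' `w[r] = sum_heads sum_c Att_i[r, c]`.  Because every attention row sums
#' to one, the weights conserve `sum(w) = heads * L`.
#'
#' @param att List of `L x L` attention matrices (one per head), as
#'   returned by [attention_matrix()].
#' @return Numeric weight vector of length `L` (class `claps_weights`).
#' @export
weight_vector <- function(att) {
  if (length(att) < 1L) stop("weight_vector: need at least one head")
  w <- rowSums(Reduce(`+`, att))
  structure(w, class = "claps_weights")
}

.check_ratio <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
    stop("ratio must lie in (0, 1)")
  }
}

.mask_plan <- function(positions, ratio, strategy) {
  structure(list(positions = sort(as.integer(positions)), ratio = ratio,
                 strategy = strategy),
            class = "claps_mask_plan")
}

#' Roulette masking
#'
#' Draws `ceil(ratio * L)` positions sequentially without replacement, each
#' draw proportional to the remaining weights, so higher-weight characters
#' are more likely to be masked.  With `occurrence = TRUE` the selection
#' probabilities are instead proportional to how often each position's
#' token occurs in the string (`p_i = f_i / sum(f)`), the frequency-based
#' variant; the attention-weight form is the default.  Uses R's global RNG
#' stream: seed with `set.seed()` for reproducibility.
#'
#' @param w Weight vector from [weight_vector()] (length `L`).
#' @param ratio Masking ratio in (0, 1).
#' @param tokens Token vector of length `L`; required when
#'   `occurrence = TRUE`.
#' @param occurrence Use token-occurrence frequencies instead of attention
#'   weights.
#' @return A `claps_mask_plan` with 1-based positions.
#' @export
roulette_mask <- function(w, ratio, tokens = NULL, occurrence = FALSE) {
  .check_ratio(ratio)
  w <- as.numeric(w)
  if (occurrence) {
    if (is.null(tokens) || length(tokens) != length(w)) {
      stop("roulette_mask: occurrence variant needs 'tokens' of length L")
    }
    f <- table(tokens)
    w <- as.numeric(f[tokens])
  }
  if (any(w < 0) || any(!is.finite(w))) {
    stop("roulette_mask: weights must be finite and nonnegative")
  }
  if (sum(w) <= 0) stop("roulette_mask: degenerate weights (all zero)")
  L <- length(w)
  k <- ceiling(ratio * L)
  chosen <- integer(0)
  remaining <- w
  for (draw in seq_len(k)) {
    p <- remaining / sum(remaining)
    r <- stats::runif(1)
    pick <- which(r <= cumsum(p))[1]
    chosen <- c(chosen, pick)
    remaining[pick] <- 0
    if (sum(remaining) <= 0 && length(chosen) < k) {
      # all residual weight exhausted: fill uniformly from the rest
      rest <- setdiff(seq_len(L), chosen)
      fill <- rest[sample.int(length(rest), k - length(chosen))]
      chosen <- c(chosen, fill)
      break
    }
  }
  .mask_plan(chosen, ratio, "roulette")
}

#' Top-weight masking
#'
#' Deterministically masks the `ceil(ratio * L)` positions with the
#' largest weights; ties at the cut are broken in favour of the lower
#' position index.
#'
#' @inheritParams roulette_mask
#' @return A `claps_mask_plan`.
#' @export
top_mask <- function(w, ratio) {
  .check_ratio(ratio)
  w <- as.numeric(w)
  L <- length(w)
  k <- ceiling(ratio * L)
  ord <- order(-w, seq_len(L)) # stable: lower index wins ties
  .mask_plan(ord[seq_len(k)], ratio, "top")
}

#' Random masking
#'
#' Uniform sample without replacement of `ceil(ratio * L)` of the non-pad
#' positions.  Uses R's global RNG stream.
#'
#' @param true_length Number of maskable (non-pad) positions `L`.
#' @param ratio Masking ratio in (0, 1).
#' @return A `claps_mask_plan`.
#' @export
random_mask <- function(true_length, ratio) {
  .check_ratio(ratio)
  stopifnot(true_length >= 1L)
  k <- ceiling(ratio * true_length)
  .mask_plan(sample.int(true_length, k), ratio, "random")
}

#' Apply a mask plan to an encoded molecule
#'
#' Replaces the token ids at the plan's positions by the vocabulary's mask
#' id; every other position (including all pads) and the true length are
#' unchanged.
#'
#' @param mol A `claps_encoded`.
#' @param plan A `claps_mask_plan`.
#' @param vocab The `claps_vocabulary` the molecule was encoded with.
#' @return A new `claps_encoded` with masked token ids.
#' @export
apply_mask <- function(mol, plan, vocab) {
  stopifnot(inherits(mol, "claps_encoded"), inherits(plan, "claps_mask_plan"),
            inherits(vocab, "claps_vocabulary"))
  if (length(plan$positions) &&
      (max(plan$positions) > mol$true_length || min(plan$positions) < 1L)) {
    stop("apply_mask: mask position outside the non-pad prefix")
  }
  mol$token_ids[plan$positions] <- vocab$mask_id
  mol
}

# Draw one positive sample for an encoded molecule under the configured
# strategy, using the PSS network for the weight vector when needed.
.positive_sample <- function(mol, model, pss, strategy, ratio,
                             occurrence = FALSE) {
  plan <- switch(
    strategy,
    roulette = {
      X <- embed_molecule(mol, model$params$emb, model$pe)
      w <- weight_vector(attention_matrix(X, pss, mol$true_length))
      toks <- if (occurrence) decode_tokens(mol, model$vocab)
      roulette_mask(w, ratio, tokens = toks, occurrence = occurrence)
    },
    top = {
      X <- embed_molecule(mol, model$params$emb, model$pe)
      w <- weight_vector(attention_matrix(X, pss, mol$true_length))
      top_mask(w, ratio)
    },
    random = random_mask(mol$true_length, ratio),
    stop(sprintf("unknown masking strategy '%s'", strategy))
  )
  apply_mask(mol, plan, model$vocab)
}
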