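# NT-Xent contrastive loss over interleaved positive pairs, and the
# pretraining loop pairing every molecule with its attention-masked view.

#' Cosine similarity
#'
#' `Sim(z_i, z_j) = (z_i . z_j) / (||z_i|| ||z_j||)`.
#'
#' @param z_i,z_j Nonzero numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(z_i, z_j) {
  stopifnot(length(z_i) == length(z_j))
  ni <- sqrt(sum(z_i^2))
  nj <- sqrt(sum(z_j^2))
  if (ni == 0 || nj == 0) stop("cosine_similarity: zero-norm projection")
  sum(z_i * z_j) / (ni * nj)
}

# Row-normalized projections and the full similarity matrix S = U U^T.
.sim_matrix <- function(Z) {
  norms <- sqrt(rowSums(Z^2))
  if (any(norms == 0)) stop("zero-norm projection in batch")
  U <- Z / norms
  list(S = tcrossprod(U), U = U, norms = norms)
}

.check_batch <- function(Z, temperature) {
  if (!is.matrix(Z) || nrow(Z) %% 2L != 0L || nrow(Z) < 2L) {
    stop("projections must form a matrix with an even number of rows")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be > 0")
  }
}

#' NT-Xent loss of one ordered pair
#'
#' For anchor `i` and partner `j` in a batch of `2N` projections,
#' `l(i, j) = -log( exp(Sim(z_i, z_j)/T) / sum_{k != i} exp(Sim(z_i, z_k)/T) )`;
#' the denominator runs over the other `2N - 1` samples, excluding only
#' `k = i`.
#'
#' @param Z `2N x d` matrix of projections, rows `(2k-1, 2k)` forming the
#'   positive pairs.
#' @param i,j Row indices of the anchor and its positive partner (`i != j`).
#' @param temperature Positive temperature `T`.
#' @return The pair loss (nonnegative scalar).
#' @export
nt_xent_pair <- function(Z, i, j, temperature = 0.1) {
  .check_batch(Z, temperature)
  n <- nrow(Z)
  stopifnot(i >= 1L, j >= 1L, i <= n, j <= n)
  if (i == j) stop("nt_xent_pair: i and j must differ")
  s <- .sim_matrix(Z)$S[i, ] / temperature
  m <- max(s[-i])
  -(s[j] - m - log(sum(exp(s[-i] - m))))
}

#' NT-Xent loss of a batch
#'
#' Mean of the pair losses over all `2N` anchors:
#' `L = (1/2N) * sum_k [ l(2k-1, 2k) + l(2k, 2k-1) ]`.
#'
#' @inheritParams nt_xent_pair
#' @return Scalar batch loss.
#' @export
nt_xent_batch <- function(Z, temperature = 0.1) {
  .nt_xent(Z, temperature, grad = FALSE)$loss
}

# Loss and (optionally) its gradient with respect to Z.
.nt_xent <- function(Z, temperature, grad = TRUE) {
  .check_batch(Z, temperature)
  n <- nrow(Z)
  sm <- .sim_matrix(Z)
  S <- sm$S / temperature
  partner <- seq_len(n) + c(1L, -1L) # 1<->2, 3<->4, ...
  Sx <- S
  diag(Sx) <- -Inf
  m <- apply(Sx, 1L, max)
  E <- exp(Sx - m)
  rs <- rowSums(E)
  loss_i <- -(S[cbind(seq_len(n), partner)] - m - log(rs))
  loss <- mean(loss_i)
  if (!grad) return(list(loss = loss))
  P <- E / rs # row-softmax over k != i (diag exactly 0)
  G <- P / n
  G[cbind(seq_len(n), partner)] <- G[cbind(seq_len(n), partner)] - 1 / n
  dU <- (G + t(G)) %*% sm$U / temperature
  dZ <- (dU - sm$U * rowSums(sm$U * dU)) / sm$norms
  list(loss = loss, dZ = dZ)
}

#' Contrastive pretraining of the SMILES encoder
#'
#' For every minibatch of `N` molecules, draws one positive view per
#' molecule with the configured masking strategy, encodes and projects all
#' `2N` views, evaluates the NT-Xent batch loss, and takes one Adam step on
#' the encoder, embedding and projection parameters.  Fresh masks are drawn
#' every epoch.  Fully deterministic under `config$seed`.
#'
#' @param corpus Character vector of SMILES strings (one molecule each).
#' @param config A [claps_config()]; `strategy`, `ratio`, `batch`,
#'   `temperature`, `epochs_pretrain`, `lr_pretrain`, `dropout` and `seed`
#'   are used.  `batch` must be at least 2.
#' @param model Optional pre-built `claps_model`; by default one is
#'   initialized from a vocabulary built on the corpus.
#' @param pss Optional pre-built `claps_pss` network.
#' @param verbose Print the per-epoch mean loss.
#' @return List with elements `model`, `pss` and `loss_trace` (numeric
#'   vector of per-epoch mean losses).
#' @export
claps_pretrain <- function(corpus, config = claps_config(), model = NULL,
                           pss = NULL, verbose = FALSE) {
  if (length(corpus) == 0L) stop("claps_pretrain: empty corpus")
  if (config$batch < 2L) {
    stop("claps_pretrain: batch size must be >= 2 (contrastive loss is degenerate)")
  }
  if (is.null(model)) {
    model <- init_claps_model(build_vocabulary(corpus), config)
  }
  if (is.null(pss)) {
    pss <- init_pss(config$d, heads = config$pss_heads,
                    layers = config$pss_layers, seed = config$seed + 1L)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  mols <- .encode_corpus(corpus, model$vocab, config$C)
  n <- length(mols)
  if (n == 0L) stop("claps_pretrain: no encodable molecules in corpus")
  state <- adam_init(model$params)
  trace <- numeric(config$epochs_pretrain)

  for (epoch in seq_len(config$epochs_pretrain)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1L, n)]
      if (length(idx) < 2L) next
      views <- vector("list", 2L * length(idx))
      for (k in seq_along(idx)) {
        mol <- mols[[idx[k]]]
        views[[2L * k - 1L]] <- mol
        views[[2L * k]] <- .positive_sample(
          mol, model, pss, config$strategy, config$ratio,
          occurrence = isTRUE(config$roulette_occurrence))
      }
      fwd <- lapply(views, function(v) .encoder_fwd(model, v, training = TRUE))
      H <- do.call(rbind, lapply(fwd, `[[`, "h"))
      pj <- .proj_fwd(H, model$params$proj)
      nt <- .nt_xent(pj$out, config$temperature)
      losses <- c(losses, nt$loss)
      pb <- .proj_bwd(nt$dZ, pj, model$params$proj)
      grads <- NULL
      for (k in seq_along(views)) {
        g <- .encoder_bwd(model, fwd[[k]], pb$dH[k, ])
        grads <- if (is.null(grads)) g else .tree_add(grads, g)
      }
      grads <- list(emb = grads$emb, layers = grads$layers, proj = pb$grads)
      stepped <- adam_step(model$params, grads, state, config$lr_pretrain)
      model$params <- stepped$params
      state <- stepped$state
    }
    trace[epoch] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %d/%d  mean NT-Xent loss %.4f",
                      epoch, config$epochs_pretrain, trace[epoch]))
    }
  }
  list(model = model, pss = pss, loss_trace = trace)
}

# Encode a corpus, dropping over-length or non-encodable strings with a
# logged count (they are hard errors in encode() itself).
.encode_corpus <- function(corpus, vocab, C) {
  mols <- vector("list", length(corpus))
  bad <- 0L
  for (k in seq_along(corpus)) {
    m <- tryCatch(encode(corpus[k], vocab, C), error = function(e) NULL)
    if (is.null(m)) bad <- bad + 1L else mols[[k]] <- m
  }
  if (bad > 0L) {
    message(sprintf("dropped %d of %d corpus strings (over-length or unknown tokens)",
                    bad, length(corpus)))
  }
  Filter(Negate(is.null), mols)
}
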