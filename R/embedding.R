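# Token embeddings and sinusoidal positional encoding.

#' Create a token embedding table
#'
#' One row per vocabulary token, entries drawn i.i.d. from the standard
#' normal distribution N(0, 1); reproducible under `seed`.
#'
#' @param vocab A `claps_vocabulary`.
#' @param d Embedding dimension (default 128).
#' @param seed Integer seed for the initialization.
#' @return A `length(vocab$tokens) x d` numeric matrix with tokens as
#'   rownames.
#' @export
embedding_table <- function(vocab, d = 128L, seed = 1L) {
  stopifnot(inherits(vocab, "claps_vocabulary"), d >= 1L)
  n <- length(vocab$tokens)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
  rownames(m) <- vocab$tokens
  m
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sinusoidal positional encoding
#'
#' The standard sine-cosine position matrix: for position `pos` (0-based)
#' and dimension pair `i` (0-based), entry `(pos, 2i)` is
#' `sin(pos / 10000^(2i/d))` and entry `(pos, 2i+1)` is
#' `cos(pos / 10000^(2i/d))`.
#'
#' @param C Number of positions (sequence length).
#' @param d Model dimension; must be even.
#' @return A `C x d` numeric matrix (row 1 is position 0).
#' @export
positional_encoding <- function(C, d) {
  if (d %% 2L != 0L || d < 2L) stop("positional_encoding: d must be even, >= 2")
  stopifnot(C >= 1L)
  pos <- 0:(C - 1L)
  i <- 0:(d / 2L - 1L)
  angle <- outer(pos, 1 / 10000^(2 * i / d)) # C x d/2
  pe <- matrix(0, C, d)
  pe[, 2L * i + 1L] <- sin(angle)
  pe[, 2L * i + 2L] <- cos(angle)
  pe
}

#' Embed an encoded molecule
#'
#' Looks up the token-embedding row for every position and adds the
#' positional row elementwise: `X = S + P`.
#'
#' @param mol A `claps_encoded`.
#' @param table Embedding table from [embedding_table()].
#' @param pe Positional matrix from [positional_encoding()]; must have at
#'   least as many rows as the encoded length and the same column count as
#'   `table`.
#' @return A `C x d` numeric matrix.
#' @export
embed_molecule <- function(mol, table, pe) {
  stopifnot(inherits(mol, "claps_encoded"))
  C <- length(mol$token_ids)
  if (ncol(table) != ncol(pe) || nrow(pe) < C) {
    stop("embed_molecule: shape mismatch between embedding table and positional matrix")
  }
  if (max(mol$token_ids) > nrow(table)) {
    stop("embed_molecule: token id exceeds embedding table rows")
  }
  out <- table[mol$token_ids, , drop = FALSE] + pe[seq_len(C), , drop = FALSE]
  dimnames(out) <- NULL
  out
}
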