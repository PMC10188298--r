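# SMILES tokenization and vocabulary construction.
#
# Tokens are the atom/bond/branch characters of SMILES, except that
# two-letter halogen element symbols (Cl, Br), bracket atom expressions
# ([NH+], [C@H], ...) and two-digit ring closures (%12) are kept whole:
# splitting "Cl" into "C","l" would invent a carbon that is not there.

.token_regex <- "\\[[^]]+\\]|Cl|Br|%[0-9]{2}|."

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the tokens used by the vocabulary and the
#' encoder: bracket atom expressions (e.g. `[NH+]`, `[C@@H]`), the two-letter
#' element symbols `Cl` and `Br`, two-digit ring-closure labels (`%nn`), and
#' every remaining character singly.  Tokenization is lossless:
#' `paste(tokenize(s), collapse = "")` is always `s`.
#'
#' @param s A single non-empty SMILES string.
#' @return Character vector of tokens.
#' @examples
#' tokenize("C[NH+]1CCC[C@@H]1c2cccnc2")
#' tokenize("C(Cl)Br")
#' @export
tokenize <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("tokenize: 's' must be a single non-empty string")
  }
  toks <- regmatches(s, gregexpr(.token_regex, s, perl = TRUE))[[1]]
  # regex alternation covers every character, so this only guards regressions
  stopifnot(identical(paste(toks, collapse = ""), s))
  toks
}

#' Build a token vocabulary from a SMILES corpus
#'
#' Traverses every string in the corpus, recording each distinct token in
#' first-appearance order, then appends the two special tokens `<pad>` and
#' `<mask>`.  Ids are 1-based and form a bijection onto `1..length(tokens)`.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @return An object of class `claps_vocabulary` with elements `tokens`
#'   (ordered character vector), `ids` (named integer vector mapping token to
#'   id), `pad_id` and `mask_id`.
#' @examples
#' v <- build_vocabulary(c("CCO", "CCN"))
#' v$tokens
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop("build_vocabulary: empty corpus")
  if (any(!nzchar(corpus)) || anyNA(corpus)) {
    stop("build_vocabulary: corpus contains empty or missing strings")
  }
  seen <- character(0)
  for (s in corpus) {
    toks <- tokenize(s)
    new <- toks[!(toks %in% seen)]
    if (length(new)) seen <- c(seen, unique(new))
  }
  tokens <- c(seen, "<pad>", "<mask>")
  ids <- stats::setNames(seq_along(tokens), tokens)
  structure(
    list(
      tokens = tokens,
      ids = ids,
      pad_id = unname(ids[["<pad>"]]),
      mask_id = unname(ids[["<mask>"]])
    ),
    class = "claps_vocabulary"
  )
}

#' @export
print.claps_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<claps_vocabulary> %d tokens (pad_id=%d, mask_id=%d)\n",
    length(x$tokens), x$pad_id, x$mask_id
  ))
  cat("  ", paste(utils::head(x$tokens, 30), collapse = " "),
      if (length(x$tokens) > 30) "...\n" else "\n")
  invisible(x)
}

#' Encode a SMILES string as a fixed-length id sequence
#'
#' Replaces each token by its vocabulary id and pads the sequence with
#' `pad_id` up to the fixed length `C`.  Over-length strings are a hard
#' error: silent truncation would corrupt contrastive pairs.
#'
#' @param s SMILES string.
#' @param vocab A `claps_vocabulary`.
#' @param C Fixed sequence length.
#' @return An object of class `claps_encoded`: list with `smiles`,
#'   `token_ids` (integer vector of length `C`) and `true_length`.
#' @export
encode <- function(s, vocab, C) {
  stopifnot(inherits(vocab, "claps_vocabulary"), C >= 1L)
  toks <- tokenize(s)
  if (length(toks) > C) {
    stop(sprintf("encode: '%s' has %d tokens, exceeds C = %d",
                 s, length(toks), C))
  }
  unknown <- setdiff(toks, names(vocab$ids))
  if (length(unknown)) {
    stop(sprintf("encode: unknown token%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(unique(unknown), collapse = ", ")))
  }
  ids <- unname(vocab$ids[toks])
  structure(
    list(
      smiles = s,
      token_ids = c(ids, rep.int(vocab$pad_id, C - length(ids))),
      true_length = length(ids)
    ),
    class = "claps_encoded"
  )
}

#' Decode an encoded molecule back to tokens
#'
#' Inverse of [encode()] on the non-pad prefix; mask ids decode to `<mask>`.
#'
#' @param mol A `claps_encoded`.
#' @param vocab The vocabulary used to encode it.
#' @return Character vector of tokens of length `mol$true_length`.
#' @export
decode_tokens <- function(mol, vocab) {
  stopifnot(inherits(mol, "claps_encoded"), inherits(vocab, "claps_vocabulary"))
  vocab$tokens[mol$token_ids[seq_len(mol$true_length)]]
}
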