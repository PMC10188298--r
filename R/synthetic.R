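# Synthetic SMILES corpora with planted, structure-dependent labels.
# The generator emulates a desk-scale drug-like fragment space: linear
# heteroatom chains, branches, halogen terminals, and zero, one or two
# aromatic rings joined by a short alkyl linker.  Every emitted string is
# valid by construction (and parseable by OpenBabel).

# Aromatic ring templates. `atoms` are written in ring order; substituents
# may only be attached at positions where `free` is TRUE (aromatic carbon).
.ring_templates <- function() {
  six <- list(
    c("c", "c", "c", "c", "c", "c"),            # benzene
    c("c", "c", "c", "c", "c", "n"),            # pyridine
    c("c", "c", "c", "c", "n", "n"),            # pyridazine
    c("c", "c", "c", "n", "c", "n"),            # pyrimidine
    c("c", "c", "n", "c", "c", "n")             # pyrazine
  )
  five <- list(
    c("c", "c", "c", "c", "o"),                 # furan
    c("c", "c", "c", "c", "s"),                 # thiophene
    c("c", "c", "c", "c", "[nH]"),              # pyrrole
    c("c", "c", "o", "c", "n"),                 # oxazole-like
    c("c", "c", "s", "c", "n"),                 # thiazole-like
    c("c", "c", "[nH]", "c", "n")               # imidazole-like
  )
  c(six, five)
}

# Write one ring with substituent strings `subs` attached at free carbons.
# `digit` is the ring-closure label.
.write_ring <- function(atoms, subs, digit) {
  free <- which(atoms == "c")
  stopifnot(length(subs) <= length(free))
  at <- sample(free, length(subs))
  out <- character(0)
  for (i in seq_along(atoms)) {
    out <- c(out, atoms[i], if (i == 1L) digit)
    j <- match(i, at)
    if (!is.na(j) && nzchar(subs[j])) out <- c(out, "(", subs[j], ")")
    if (i == length(atoms)) out <- c(out, digit)
  }
  paste(out, collapse = "")
}

# A random valence-safe linear chain of the given length: carbons with
# occasional N/O/S, optional single-carbon branch, optional halogen end.
.rand_chain <- function(len, terminal_hal = TRUE) {
  if (len <= 0L) return("")
  pool <- c("C", "C", "C", "C", "N", "O", "S")
  atoms <- sample(pool, len, replace = TRUE)
  out <- character(0)
  for (i in seq_len(len)) {
    out <- c(out, atoms[i])
    if (atoms[i] == "C" && len > 1L && stats::runif(1) < 0.15) {
      out <- c(out, "(C)")
    }
  }
  if (terminal_hal && stats::runif(1) < 0.25) {
    out <- c(out, sample(c("F", "Cl", "Br"), 1L))
  }
  paste(out, collapse = "")
}

.rand_molecule <- function(max_atoms) {
  shape <- sample(c("acyclic", "one_ring", "two_ring"), 1L,
                  prob = c(0.15, 0.50, 0.35))
  rings <- .ring_templates()
  if (shape == "acyclic") {
    return(.rand_chain(sample(3:max(3L, max_atoms - 2L), 1L)))
  }
  if (shape == "one_ring") {
    atoms <- rings[[sample(length(rings), 1L)]]
    budget <- max(0L, max_atoms - length(atoms))
    nsub <- sample(0:2, 1L)
    subs <- vapply(seq_len(nsub), function(i) {
      .rand_chain(sample(1:max(1L, budget %/% max(1L, nsub)), 1L))
    }, "")
    head_chain <- if (stats::runif(1) < 0.5) {
      .rand_chain(sample(1:2, 1L), terminal_hal = FALSE)
    } else {
      ""
    }
    return(paste0(head_chain, .write_ring(atoms, subs, "1")))
  }
  # two rings joined by a 0-3 carbon linker, written as a substituent
  a1 <- rings[[sample(length(rings), 1L)]]
  a2 <- rings[[sample(length(rings), 1L)]]
  linker <- paste(rep("C", sample(0:3, 1L)), collapse = "")
  second <- paste0(linker, .write_ring(a2, character(0), "2"))
  extra <- if (stats::runif(1) < 0.4) .rand_chain(1L) else character(0)
  .write_ring(a1, c(second, extra), "1")
}

#' Generate a synthetic SMILES corpus
#'
#' Emits `n` syntactically valid SMILES strings from a small fragment
#' grammar: linear chains over C/N/O/S with occasional branches and halogen
#' terminals, and molecules with one or two aromatic rings (benzene- and
#' pyridine-like 6-rings, furan/thiophene/pyrrole-like 5-rings) joined by
#' short alkyl linkers.  Deterministic under `seed`.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed.
#' @param max_atoms Approximate heavy-atom budget per molecule (default 12).
#' @return Character vector of `n` SMILES strings.
#' @examples
#' generate_synthetic_corpus(5, seed = 1)
#' @export
generate_synthetic_corpus <- function(n, seed = 1L, max_atoms = 12L) {
  stopifnot(n >= 1L, max_atoms >= 3L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(n), function(i) .rand_molecule(max_atoms), "")
}

# Heavy-atom counts per element from the token stream (bracket atoms are
# attributed to their element symbol; aromatic lower case folds to upper).
.atom_counts <- function(smiles) {
  counts <- c(C = 0, N = 0, O = 0, S = 0, F = 0, Cl = 0, Br = 0, other = 0)
  for (tok in tokenize(smiles)) {
    el <- if (grepl("^\\[", tok)) {
      m <- regmatches(tok, regexpr("[A-Za-z][a-z]?", tok))
      if (length(m)) m else ""
    } else {
      tok
    }
    el <- sub("^([A-Za-z])", "\\U\\1", el, perl = TRUE)
    if (el %in% c("C", "N", "O", "S", "F", "Cl", "Br")) {
      counts[el] <- counts[el] + 1
    } else if (grepl("^[A-Z][a-z]?$", el) || grepl("^\\[", tok)) {
      counts["other"] <- counts["other"] + 1
    }
  }
  counts
}

#' Plant labels on a set of molecules
#'
#' Classification: the label is the indicator of a planted structural motif
#' (default: the molecule contains at least one nitrogen atom), flipped
#' with probability `noise`.  Regression: the label is a fixed linear
#' function of the heavy-atom counts,
#' `y = w_C n_C + w_N n_N + w_O n_O + w_S n_S + w_hal (n_F + n_Cl + n_Br)`,
#' plus `N(0, noise^2)` noise.  The planted rule is recorded in the
#' returned dataset's `rule` attribute so recovery is checkable.
#'
#' @param smiles Character vector of valid SMILES.
#' @param task_type `"classification"` or `"regression"`.
#' @param noise Flip probability (classification, default 0.05) or Gaussian
#'   standard deviation (regression, default 0.1).
#' @param seed Integer seed.
#' @param motif Planted element motif for classification (default `"S"`:
#'   "molecule contains sulfur", which close to balances the corpus; a
#'   near-balanced motif keeps presence/absence recoverable at high AUC
#'   under label noise).
#' @param weights Named weights per element for regression; default
#'   `c(C = 1, N = 2, O = 3, S = 4, hal = 1)`.
#' @return A `claps_dataset` (see [property_dataset()]) with one task.
#' @export
generate_synthetic_labels <- function(smiles,
                                      task_type = c("classification", "regression"),
                                      noise = NULL, seed = 1L, motif = "S",
                                      weights = c(C = 1, N = 2, O = 3, S = 4,
                                                  hal = 1)) {
  task_type <- match.arg(task_type)
  if (is.null(noise)) noise <- if (task_type == "classification") 0.05 else 0.1
  stopifnot(noise >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tmpl <- c(C = 0, N = 0, O = 0, S = 0, F = 0, Cl = 0, Br = 0, other = 0)
  counts <- t(vapply(smiles, .atom_counts, tmpl, USE.NAMES = FALSE))
  colnames(counts) <- names(tmpl)
  rownames(counts) <- NULL
  if (task_type == "classification") {
    y <- as.numeric(counts[, motif] > 0)
    flip <- stats::runif(length(y)) < noise
    y[flip] <- 1 - y[flip]
    rule <- list(type = "motif", motif = motif, noise = noise)
  } else {
    y <- counts[, "C"] * weights[["C"]] + counts[, "N"] * weights[["N"]] +
      counts[, "O"] * weights[["O"]] + counts[, "S"] * weights[["S"]] +
      (counts[, "F"] + counts[, "Cl"] + counts[, "Br"]) * weights[["hal"]]
    y <- y + stats::rnorm(length(y), sd = noise)
    rule <- list(type = "atom_count", weights = weights, noise = noise)
  }
  ds <- property_dataset(smiles, matrix(y, ncol = 1L,
                                        dimnames = list(NULL, "task1")),
                         task_type = task_type)
  attr(ds, "rule") <- rule
  ds
}
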