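# Train/valid/test splitting: Bemis-Murcko scaffold groups or uniform
# random, both 8/1/1 by default.

.new_split <- function(train, valid, test, n, scaffold_of = NULL) {
  structure(list(train = sort(train), valid = sort(valid), test = sort(test),
                 n = n, scaffold_of = scaffold_of),
            class = "claps_split")
}

#' @export
print.claps_split <- function(x, ...) {
  cat(sprintf("<claps_split> n=%d: train %d / valid %d / test %d\n",
              x$n, length(x$train), length(x$valid), length(x$test)))
  invisible(x)
}

.check_fractions <- function(fractions) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive numbers summing to 1")
  }
}

#' Scaffold-based dataset split
#'
#' Groups molecules by canonical Bemis-Murcko scaffold and assigns whole
#' groups greedily, in descending group-size order (ties broken by the
#' scaffold string, ascending), to train, then valid, then test, so that no
#' scaffold ever spans two subsets.  Molecules sharing a scaffold are
#' structurally similar, so this split is deliberately harder than a random
#' split.  The assignment is fully deterministic; `seed` is accepted for
#' interface parity with [random_split()] but unused.
#'
#' @param ds A `claps_dataset` (at least 3 molecules).
#' @param fractions Target train/valid/test fractions (default 0.8/0.1/0.1).
#' @param seed Ignored (deterministic split).
#' @return A `claps_split`: integer index vectors `train`, `valid`, `test`
#'   and the per-molecule `scaffold_of` character vector.
#' @export
scaffold_split <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = NULL) {
  stopifnot(inherits(ds, "claps_dataset"))
  .check_fractions(fractions)
  n <- length(ds$smiles)
  if (n < 3L) stop("scaffold_split: dataset must hold at least 3 molecules")
  scaffolds <- murcko_scaffold(ds$smiles)
  groups <- split(seq_len(n), scaffolds)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  cut_train <- fractions[1] * n
  cut_valid <- (fractions[1] + fractions[2]) * n
  assign_to <- character(length(groups))
  sz <- c(train = 0L, valid = 0L, test = 0L)
  for (k in seq_along(groups)) {
    g <- length(groups[[k]])
    dest <- if (sz[["train"]] + g <= cut_train) {
      "train"
    } else if (sz[["train"]] + sz[["valid"]] + g <= cut_valid) {
      "valid"
    } else {
      "test"
    }
    assign_to[k] <- dest
    sz[[dest]] <- sz[[dest]] + g
  }
  # greedy fill can leave valid/test empty on tiny or lumpy data: move the
  # smallest trailing train groups (groups are ordered largest first)
  for (dest in c("valid", "test")) {
    if (sz[[dest]] == 0L) {
      cand <- rev(which(assign_to == "train"))
      if (length(cand) >= 1L && sum(assign_to == "train") >= 2L) {
        assign_to[cand[1L]] <- dest
      }
    }
  }
  pick <- function(dest) {
    out <- unlist(groups[assign_to == dest], use.names = FALSE)
    if (is.null(out)) integer(0) else out
  }
  .new_split(pick("train"), pick("valid"), pick("test"), n,
             scaffold_of = scaffolds)
}

#' Random dataset split
#'
#' Uniformly shuffles the molecule indices under `seed` and cuts at the
#' fraction boundaries.
#'
#' @inheritParams scaffold_split
#' @param seed Integer seed for the shuffle.
#' @return A `claps_split`.
#' @export
random_split <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(ds, "claps_dataset"))
  .check_fractions(fractions)
  n <- length(ds$smiles)
  if (n < 3L) stop("random_split: dataset must hold at least 3 molecules")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- max(1L, floor(fractions[1] * n))
  n_valid <- max(1L, floor((fractions[1] + fractions[2]) * n) - n_train)
  if (n_train + n_valid >= n) {
    n_train <- n - 2L
    n_valid <- 1L
  }
  .new_split(ord[seq_len(n_train)],
             ord[n_train + seq_len(n_valid)],
             ord[(n_train + n_valid + 1L):n],
             n)
}

#' Write a split assignment to CSV
#'
#' Columns `index`, `smiles`, `subset`.
#'
#' @param split A `claps_split`.
#' @param ds The `claps_dataset` it partitions.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, ds, path) {
  stopifnot(inherits(split, "claps_split"), inherits(ds, "claps_dataset"))
  subset <- character(split$n)
  subset[split$train] <- "train"
  subset[split$valid] <- "valid"
  subset[split$test] <- "test"
  utils::write.csv(
    data.frame(index = seq_len(split$n), smiles = ds$smiles, subset = subset),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
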