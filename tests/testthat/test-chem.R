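test_that("murcko scaffold strips side chains and canonicalizes", {
  # acyclic molecules have the empty scaffold
  expect_identical(murcko_scaffold("CCO"), "")
  # side chains of different length collapse to the same ring scaffold
  s <- murcko_scaffold(c("c1ccccc1CC", "c1ccccc1C", "c1ccccc1"))
  expect_identical(s[1], s[2])
  expect_identical(s[2], s[3])
  # idempotent on the scaffold itself
  expect_identical(murcko_scaffold(s[3]), s[3])
  # ring systems joined by a linker keep the linker
  two <- murcko_scaffold("c1ccccc1CCc1ccncc1")
  expect_true(nzchar(two))
  expect_identical(murcko_scaffold("c1ccccc1CCc1ccncc1C"), two)
  expect_error(murcko_scaffold("xx99"), "unparsable")
})

test_that("SMILES validity check accepts generated corpora and rejects junk", {
  corp <- generate_synthetic_corpus(80, seed = 9)
  expect_true(all(is_valid_smiles(corp)))
  expect_equal(is_valid_smiles(c("CCO", "not_a_smiles", "c1ccccc1")),
               c(TRUE, FALSE, TRUE))
})

test_that("scaffold split is a cohesive partition near the target fractions", {
  smi <- generate_synthetic_corpus(200, seed = 13)
  ds <- generate_synthetic_labels(smi, "classification", seed = 14)
  sp <- scaffold_split(ds)
  idx <- sort(c(sp$train, sp$valid, sp$test))
  expect_identical(idx, seq_along(smi))      # partition, no overlap
  expect_identical(anyDuplicated(c(sp$train, sp$valid, sp$test)), 0L)
  # scaffold cohesion: no scaffold string spans two subsets
  subset_of <- integer(length(smi))
  subset_of[sp$train] <- 1L
  subset_of[sp$valid] <- 2L
  subset_of[sp$test] <- 3L
  coh <- tapply(subset_of, sp$scaffold_of, function(x) length(unique(x)))
  expect_true(all(coh == 1L))
  expect_gte(length(sp$train) / length(smi), 0.7)
  expect_lte(length(sp$train) / length(smi), 0.9)
  # deterministic
  sp2 <- scaffold_split(ds)
  expect_identical(sp$train, sp2$train)
})

test_that("ten distinct scaffolds split 8/1/1", {
  smi <- c("c1ccccc1C", "c1ccncc1C", "c1cnccc1O", "c1ccc(cc1)N", "c1ccsc1C",
           "c1ccoc1C", "c1cc[nH]c1C", "CCCCCC", "c1ncncc1C", "c1ccccc1CCc1ccccc1")
  ds <- property_dataset(smi, rep(0, 10), task_type = "regression")
  sp <- scaffold_split(ds)
  expect_equal(lengths(sp[c("train", "valid", "test")]),
               c(train = 8L, valid = 1L, test = 1L))
})

test_that("random split respects fractions, seed determinism, and shuffling", {
  smi <- generate_synthetic_corpus(100, seed = 21)
  ds <- generate_synthetic_labels(smi, "regression", seed = 22)
  sp <- random_split(ds, seed = 5)
  expect_equal(lengths(sp[c("train", "valid", "test")]),
               c(train = 80L, valid = 10L, test = 10L))
  expect_identical(sort(c(sp$train, sp$valid, sp$test)), 1:100)
  expect_identical(random_split(ds, seed = 5)$train, sp$train)
  expect_false(identical(random_split(ds, seed = 6)$train, sp$train))
  expect_error(random_split(dataset_subset(ds, 1:2)), "at least 3")
})

test_that("split CSV export writes index/smiles/subset rows", {
  smi <- generate_synthetic_corpus(20, seed = 31)
  ds <- generate_synthetic_labels(smi, "classification", seed = 32)
  sp <- random_split(ds, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_split_csv(sp, ds, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 20L)
  expect_equal(sort(unique(out$subset)), c("test", "train", "valid"))
  expect_equal(sum(out$subset == "train"), length(sp$train))
})
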