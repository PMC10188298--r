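test_that("BCE matches hand values and a loop oracle, honoring the mask", {
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2))
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               -0.5 * (log(0.9) + log(0.8)))
  eps <- 1e-12
  expect_lt(bce_loss(c(1 - eps, eps), c(1, 0)), 1e-10)
  set.seed(10)
  o <- runif(20, 0.01, 0.99)
  t <- rbinom(20, 1, 0.5)
  obs <- runif(20) < 0.7
  ref <- 0
  for (k in which(obs)) ref <- ref - (t[k] * log(o[k]) + (1 - t[k]) * log(1 - o[k]))
  expect_equal(bce_loss(o, t, obs), ref / sum(obs), tolerance = 1e-9)
  # unobserved entries never contribute
  o2 <- o; o2[!obs] <- 0.123
  t2 <- t; t2[!obs] <- 1 - t2[!obs]
  expect_identical(bce_loss(o, t, obs), bce_loss(o2, t2, obs))
  expect_error(bce_loss(o, t, rep(FALSE, 20)), "no observed")
})

test_that("RMSE matches hand values and a loop oracle", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  set.seed(11)
  y <- rnorm(15); yh <- rnorm(15)
  ref <- sqrt(sum((y - yh)^2) / 15)
  expect_equal(rmse(y, yh), ref, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("ROC-AUC equals the exhaustive pairwise oracle on all small cases", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(1:6, c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(6:1, c(0, 0, 0, 1, 1, 1)), 0)
  set.seed(12)
  for (n in 2:12) {
    for (rep in 1:20) {
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes present
      scores <- sample(seq_len(ceiling(n / 2)), n, replace = TRUE) # force ties
      expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels),
                   tolerance = 1e-9)
    }
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("multi-task ROC-AUC macro-averages observed tasks and skips single-class ones", {
  scores <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.4, 0.3, 0.2, 0.6))
  labels <- cbind(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_warning(a <- roc_auc(scores, labels), "single class")
  expect_equal(a, 1)
  # missing labels excluded per task
  labels2 <- cbind(c(1, NA, 0, 0), c(0, 1, NA, 1))
  obs <- !is.na(labels2)
  m <- roc_auc(scores, labels2, obs)
  t1 <- roc_auc(scores[obs[, 1], 1], labels2[obs[, 1], 1])
  t2 <- roc_auc(scores[obs[, 2], 2], labels2[obs[, 2], 2])
  expect_equal(m, mean(c(t1, t2)))
})

test_that("property CSV reader handles blanks, missing columns, bad SMILES", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("smiles,task_a,task_b",
               "CCO,1,0",
               "CCN,,1",
               "not_a_smiles,0,0",
               "c1ccccc1,0,"), path)
  expect_message(ds <- read_property_csv(path, task_type = "classification"),
                 "dropped 1")
  expect_length(ds$smiles, 3L)
  expect_equal(sum(!ds$observed), 2L)
  expect_false(ds$observed[2, 1])
  expect_error(read_property_csv(path, smiles_column = "mol"), "mol")
  expect_error(read_property_csv(path, label_columns = "task_c"), "task_c")
  # single-row layout: smiles plus two labels
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("smiles,t1,t2", "C[NH+]1CCC[C@H]1c2cccnc2,1,0"), p2)
  d2 <- read_property_csv(p2, task_type = "classification")
  expect_equal(as.numeric(d2$labels), c(1, 0))
})

test_that("dataset validation enforces label invariants", {
  expect_error(property_dataset(c("C", "CC"), c(0.5, 1), "classification"),
               "0 or 1")
  expect_error(property_dataset(c("C", "CC"), c(Inf, 1), "regression",
                                observed = matrix(TRUE, 2, 1)),
               "finite")
  ds <- property_dataset(c("C", "CC", "CCC"), c(1, NA, 0), "classification")
  expect_equal(sum(ds$observed), 2L)
  sub <- dataset_subset(ds, c(1, 3))
  expect_equal(sub$labels[, 1], c(1, 0))
})

test_that("fine-tuned head predicts per molecule with sigmoid-squashed scores", {
  cfg <- tiny_config(epochs_finetune = 2L, batch_finetune = 16L)
  smi <- generate_synthetic_corpus(60, seed = 33)
  ds <- generate_synthetic_labels(smi, "classification", noise = 0, seed = 34)
  sp <- random_split(ds, seed = 2)
  model <- init_claps_model(build_vocabulary(smi), cfg)
  fit <- claps_finetune(ds, sp, model, cfg)
  expect_s3_class(fit$report, "claps_report")
  preds <- claps_predict(fit, c(smi[1:3], "??bad??"), "classification")
  expect_equal(dim(preds), c(4L, 1L))
  expect_true(all(preds[1:3, ] > 0 & preds[1:3, ] < 1))
  expect_true(is.na(preds[4, ]))
  # eval mode: same input, same output
  expect_identical(preds[1, 1],
                   claps_predict(fit, smi[1], "classification")[1, 1])
})

test_that("unobserved labels never influence fine-tuning", {
  cfg <- tiny_config(epochs_finetune = 2L, batch_finetune = 8L)
  smi <- generate_synthetic_corpus(40, seed = 35)
  ds <- generate_synthetic_labels(smi, "classification", noise = 0, seed = 36)
  ds$observed[c(3, 7, 11), 1] <- FALSE
  sp <- random_split(ds, seed = 3)
  model <- init_claps_model(build_vocabulary(smi), cfg)
  f1 <- claps_finetune(ds, sp, model, cfg)
  ds2 <- ds
  ds2$labels[c(3, 7, 11), 1] <- 1 - ds2$labels[c(3, 7, 11), 1]
  f2 <- claps_finetune(ds2, sp, model, cfg)
  expect_identical(f1$report$macro, f2$report$macro)
  expect_identical(f1$head, f2$head)
})
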