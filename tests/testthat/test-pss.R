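make_pss_input <- function(smiles = "CCOc1ccccc1", cfg = tiny_config()) {
  model <- tiny_model(cfg)
  mol <- encode(smiles, model$vocab, cfg$C)
  X <- embed_molecule(mol, model$params$emb, model$pe)
  list(model = model, mol = mol, X = X,
       pss = init_pss(cfg$d, heads = 3L, layers = 2L, seed = 2L))
}

test_that("attention rows are probability vectors; constant inputs give uniform rows", {
  f <- make_pss_input()
  att <- attention_matrix(f$X, f$pss, f$mol$true_length)
  expect_length(att, 3L)
  for (A in att) {
    expect_equal(dim(A), rep(f$mol$true_length, 2))
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  }
  # identical rows -> identical scores -> uniform attention
  Xc <- f$X
  Xc[] <- rep(Xc[1, ], each = nrow(Xc))
  attc <- attention_matrix(Xc, f$pss, 5L)
  for (A in attc) expect_equal(A, matrix(1 / 5, 5, 5), tolerance = 1e-9)
  # L = 1 degenerates to [[1]]
  att1 <- attention_matrix(f$X, f$pss, 1L)
  for (A in att1) expect_equal(A, matrix(1, 1, 1))
  expect_error(attention_matrix(f$X, f$pss, 0L), "true_length")
})

test_that("single-head attention matches a dense-loop softmax oracle", {
  set.seed(5)
  d <- 8L
  X <- matrix(rnorm(3 * d), 3, d)
  net <- init_pss(d, heads = 1L, layers = 1L, seed = 3L)
  A <- attention_matrix(X, net, 3L)[[1]]
  Wq <- net$params[[1]][[1]]$Wq
  Wk <- net$params[[1]][[1]]$Wk
  ref <- matrix(0, 3, 3)
  for (r in 1:3) {
    sc <- numeric(3)
    for (cc in 1:3) {
      sc[cc] <- sum((X[r, ] %*% Wq) * (X[cc, ] %*% Wk)) / sqrt(d)
    }
    ref[r, ] <- exp(sc) / sum(exp(sc))
  }
  expect_equal(A, ref, tolerance = 1e-10)
})

test_that("weight vector sums heads x L and matches a double-loop sum", {
  f <- make_pss_input()
  att <- attention_matrix(f$X, f$pss, f$mol$true_length)
  w <- weight_vector(att)
  L <- f$mol$true_length
  expect_length(w, L)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 3 * L, tolerance = 1e-5)
  ref <- numeric(L)
  for (A in att) {
    for (r in seq_len(L)) {
      for (cc in seq_len(L)) ref[r] <- ref[r] + A[r, cc]
    }
  }
  expect_equal(as.numeric(w), ref, tolerance = 1e-12)
  # uniform attention, 3 heads, L = 4 -> w = (3,3,3,3)
  uni <- replicate(3, matrix(0.25, 4, 4), simplify = FALSE)
  expect_equal(as.numeric(weight_vector(uni)), rep(3, 4))
  expect_equal(as.numeric(weight_vector(list(matrix(1, 1, 1)))), 1)
})

test_that("every strategy masks exactly ceil(ratio*L) distinct non-pad positions", {
  f <- make_pss_input()
  L <- f$mol$true_length
  w <- weight_vector(attention_matrix(f$X, f$pss, L))
  set.seed(1)
  for (ratio in c(0.1, 0.25, 0.5, 0.9)) {
    for (plan in list(roulette_mask(w, ratio), top_mask(w, ratio),
                      random_mask(L, ratio))) {
      expect_length(plan$positions, ceiling(ratio * L))
      expect_identical(anyDuplicated(plan$positions), 0L)
      expect_true(all(plan$positions >= 1L & plan$positions <= L))
    }
  }
  expect_error(roulette_mask(rep(0, 4), 0.5), "degenerate")
  expect_error(top_mask(w, 0), "ratio")
  expect_error(random_mask(L, 1), "ratio")
})

test_that("top masking selects the largest weights with lower-index tie-break", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(top_mask(w, 0.25)$positions, 1L)
  expect_equal(top_mask(w, 0.5)$positions, c(1L, 2L))
  wt <- c(2, 1, 1)
  expect_equal(top_mask(wt, 1 / 3)$positions, 1L)
  expect_equal(top_mask(wt, 2 / 3)$positions, c(1L, 2L)) # tie: lower index
  # monotone nesting in the ratio
  set.seed(2)
  wr <- runif(9)
  ratios <- c(0.1, 0.3, 0.5, 0.8)
  for (k in seq_len(length(ratios) - 1L)) {
    expect_true(all(top_mask(wr, ratios[k])$positions %in%
                      top_mask(wr, ratios[k + 1])$positions))
  }
})

test_that("roulette single-draw frequencies follow the weights", {
  set.seed(11)
  n <- 20000L
  w <- c(0.7, 0.1, 0.1, 0.1)
  first <- replicate(n, roulette_mask(w, 0.25)$positions[1])
  expect_lt(abs(mean(first == 1) - 0.7), 0.015)
  # uniform weights: every position equally likely
  u <- replicate(n, roulette_mask(c(1, 1, 1, 1), 0.25)$positions[1])
  expect_true(all(abs(as.numeric(table(u)) / n - 0.25) < 0.02))
})

test_that("roulette without-replacement inclusion matches exact enumeration", {
  # w = (5,3,2), 2 of 3 masked: enumerate all ordered draws for the exact
  # inclusion probability of each position
  w <- c(5, 3, 2)
  inc <- numeric(3)
  for (a in 1:3) {
    pa <- w[a] / sum(w)
    for (b in setdiff(1:3, a)) {
      pb <- w[b] / (sum(w) - w[a])
      inc[a] <- inc[a] + pa * pb
      inc[b] <- inc[b] + pa * pb
    }
  }
  set.seed(12)
  n <- 30000L
  hits <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    hits[k, roulette_mask(w, 2 / 3)$positions] <- 1
  }
  expect_true(all(abs(colMeans(hits) - inc) < 0.015))
})

test_that("occurrence-based roulette uses token frequencies", {
  set.seed(3)
  toks <- c("C", "C", "C", "O")              # f = (3,3,3,1)
  w <- c(0, 0, 0, 100)                        # attention would pick 4 always
  first <- replicate(20000, {
    roulette_mask(w, 0.25, tokens = toks, occurrence = TRUE)$positions[1]
  })
  expect_lt(abs(mean(first == 4) - 0.1), 0.015)
})

test_that("masking replaces exactly the planned positions with the mask token", {
  v <- build_vocabulary(c("CCO", "CCN"))
  m <- encode("CCO", v, 6L)
  masked <- apply_mask(m, claps:::.mask_plan(1L, 0.34, "top"), v)
  expect_equal(masked$token_ids[1], v$mask_id)
  expect_equal(masked$token_ids[-1], m$token_ids[-1])
  expect_equal(masked$true_length, m$true_length)
  # empty plan is the identity
  expect_equal(apply_mask(m, claps:::.mask_plan(integer(0), 0.1, "top"), v),
               m)
  expect_error(apply_mask(m, claps:::.mask_plan(4L, 0.5, "top"), v),
               "outside")
  # pads untouched for random plans
  set.seed(9)
  for (k in 1:10) {
    plan <- random_mask(m$true_length, 0.5)
    mk <- apply_mask(m, plan, v)
    expect_equal(sum(mk$token_ids == v$mask_id), length(plan$positions))
    expect_equal(mk$token_ids[4:6], m$token_ids[4:6])
  }
})

test_that("seeded masking is reproducible", {
  w <- c(5, 1, 3, 2, 4)
  set.seed(100)
  a <- roulette_mask(w, 0.5)
  r1 <- random_mask(5L, 0.5)
  set.seed(100)
  b <- roulette_mask(w, 0.5)
  r2 <- random_mask(5L, 0.5)
  expect_identical(a, b)
  expect_identical(r1, r2)
})
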