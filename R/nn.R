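# Dense neural-network primitives with hand-derived reverse-mode gradients.
# Everything operates on ordinary numeric matrices; sequences are L x d with
# one row per (non-pad) token position.  Forward functions return the output
# plus the cache needed by the matching backward function.

.xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

relu <- function(x) pmax(x, 0)

# ---- layer normalization (per row) ------------------------------------------

.ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * inv
  n <- nrow(X)
  list(out = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, inv = inv)
}

.ln_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- dout * rep(g, each = nrow(dout))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dout * xhat), db = colSums(dout))
}

# ---- dropout (inverted, active only in training mode) -----------------------

.drop_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(out = X * mask, mask = mask)
}

.drop_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# ---- multi-head self-attention ----------------------------------------------

# p: list(Wq, Wk, Wv, Wo), all d x d; nh heads of width d/nh.
.mha_fwd <- function(X, p, nh) {
  d <- ncol(X)
  dk <- d %/% nh
  Q <- X %*% p$Wq
  K <- X %*% p$Wk
  V <- X %*% p$Wv
  O <- matrix(0, nrow(X), d)
  heads <- vector("list", nh)
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    P <- .softmax_rows(S)
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    heads[[h]] <- list(idx = idx, P = P)
  }
  list(out = O %*% p$Wo, X = X, Q = Q, K = K, V = V, O = O, heads = heads)
}

.mha_bwd <- function(dout, cache, p) {
  d <- ncol(cache$X)
  dk <- d %/% length(cache$heads)
  dO <- dout %*% t(p$Wo)
  dWo <- crossprod(cache$O, dout)
  dQ <- matrix(0, nrow(cache$X), d)
  dK <- dQ
  dV <- dQ
  for (hc in cache$heads) {
    idx <- hc$idx
    P <- hc$P
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dP <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  list(dX = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = crossprod(cache$X, dQ),
       dWk = crossprod(cache$X, dK),
       dWv = crossprod(cache$X, dV),
       dWo = dWo)
}

# ---- position-wise feed-forward ---------------------------------------------

.ffn_fwd <- function(X, p) {
  A <- X %*% p$W1 + rep(p$b1, each = nrow(X))
  H <- relu(A)
  list(out = H %*% p$W2 + rep(p$b2, each = nrow(X)), X = X, A = A, H = H)
}

.ffn_bwd <- function(dout, cache, p) {
  dW2 <- crossprod(cache$H, dout)
  db2 <- colSums(dout)
  dH <- dout %*% t(p$W2)
  dA <- dH * (cache$A > 0)
  list(dX = dA %*% t(p$W1),
       dW1 = crossprod(cache$X, dA), db1 = colSums(dA),
       dW2 = dW2, db2 = db2)
}

# ---- one transformer encoder layer ------------------------------------------
# y = LN2( n1 + Drop(FFN(n1)) ),  n1 = LN1( x + Drop(MHA(x)) )

.enc_layer_fwd <- function(X, lp, nh, dropout, training) {
  att <- .mha_fwd(X, lp, nh)
  d1 <- .drop_fwd(att$out, dropout, training)
  ln1 <- .ln_fwd(X + d1$out, lp$ln1_g, lp$ln1_b)
  ff <- .ffn_fwd(ln1$out, lp)
  d2 <- .drop_fwd(ff$out, dropout, training)
  ln2 <- .ln_fwd(ln1$out + d2$out, lp$ln2_g, lp$ln2_b)
  list(out = ln2$out, att = att, d1 = d1, ln1 = ln1, ff = ff, d2 = d2,
       ln2 = ln2)
}

.enc_layer_bwd <- function(dout, cache, lp, nh) {
  l2 <- .ln_bwd(dout, cache$ln2, lp$ln2_g)
  dff <- .drop_bwd(l2$dX, cache$d2)
  fb <- .ffn_bwd(dff, cache$ff, lp)
  dn1 <- l2$dX + fb$dX
  l1 <- .ln_bwd(dn1, cache$ln1, lp$ln1_g)
  datt <- .drop_bwd(l1$dX, cache$d1)
  ab <- .mha_bwd(datt, cache$att, lp)
  list(
    dX = l1$dX + ab$dX,
    grads = list(Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv, Wo = ab$dWo,
                 ln1_g = l1$dg, ln1_b = l1$db,
                 W1 = fb$dW1, b1 = fb$db1, W2 = fb$dW2, b2 = fb$db2,
                 ln2_g = l2$dg, ln2_b = l2$db)
  )
}

.init_enc_layer <- function(d, ff) {
  list(Wq = .xavier(d, d), Wk = .xavier(d, d), Wv = .xavier(d, d),
       Wo = .xavier(d, d),
       ln1_g = rep(1, d), ln1_b = rep(0, d),
       W1 = .xavier(d, ff), b1 = rep(0, ff),
       W2 = .xavier(ff, d), b2 = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d))
}

# ---- parameter-tree utilities and Adam --------------------------------------

.tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) .tree_map(f, x)) else f(a)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- .tree_map2(f, a[[k]], b[[k]])
    out
  } else {
    f(a, b)
  }
}

.tree_zeros <- function(p) .tree_map(function(x) x * 0, p)

.tree_add <- function(a, b) .tree_map2(`+`, a, b)

adam_init <- function(params) {
  list(m = .tree_zeros(params), v = .tree_zeros(params), t = 0L)
}

# Returns list(params, state) after one Adam update with gradient tree `grads`.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                    state$m, state$v)
  list(params = .tree_map2(`-`, params, upd), state = state)
}
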