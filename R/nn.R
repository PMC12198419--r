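# Sequence-regression networks for the marker enhancer: per-frame linear,
# stacked LSTM, and transformer encoder. Forward and backward passes are
# implemented directly on base matrices (no deep-learning framework);
# gradients are verified against finite differences in the test suite.
#
# Batch layout: arrays [B, T, F]. Collapsing the first two dimensions gives a
# (B*T) x F matrix whose row index is b + (t-1)*B, used for all frame-wise
# affine maps so they run as single matrix products.

# ---- parameter-tree helpers -------------------------------------------------

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, function(x) tree_map(f, x))
           else Map(function(x, y) tree_map(f, x, y), a, b)
    return(out)
  }
  if (is.null(b)) f(a) else f(a, b)
}

tree_sum <- function(a, f = length) {
  if (is.list(a)) sum(vapply(a, tree_sum, numeric(1), f = f)) else f(a)
}

init_mat <- function(nr, nc) {
  lim <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
init_vec <- function(n) rep(0, n)

sigmoid <- function(x) 1 / (1 + exp(-x))

collapse_bt <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}
expand_bt <- function(x, B, T_) {
  dim(x) <- c(B, T_, ncol(x))
  x
}

# ---- linear -----------------------------------------------------------------

init_linear <- function(f_in, f_out) {
  list(W = init_mat(f_in, f_out), b = init_vec(f_out))
}

linear_forward <- function(params, x, cache = FALSE) {
  d <- dim(x)
  xm <- collapse_bt(x)
  out <- xm %*% params$W
  out <- sweep(out, 2, params$b, "+")
  list(out = expand_bt(out, d[1], d[2]),
       cache = if (cache) list(xm = xm, d = d) else NULL)
}

linear_backward <- function(params, cache, dout) {
  dm <- collapse_bt(dout)
  list(grads = list(W = crossprod(cache$xm, dm), b = colSums(dm)),
       dx = expand_bt(dm %*% t(params$W), cache$d[1], cache$d[2]))
}

# ---- LSTM -------------------------------------------------------------------

# Stacked LSTM with one bias vector per gate set (W: in x 4H, U: H x 4H,
# b: 4H; gate order input, forget, cell, output) and a per-frame affine
# readout.

init_lstm <- function(f_in, f_out, layers, units) {
  lay <- list()
  d_in <- f_in
  for (l in seq_len(layers)) {
    lay[[l]] <- list(W = init_mat(d_in, 4 * units),
                     U = init_mat(units, 4 * units),
                     b = init_vec(4 * units))
    d_in <- units
  }
  list(layers = lay, readout = init_linear(units, f_out))
}

lstm_layer_forward <- function(lp, x, cache = FALSE) {
  d <- dim(x); B <- d[1]; T_ <- d[2]
  units <- nrow(lp$U)
  xm <- collapse_bt(x)
  xw <- sweep(xm %*% lp$W, 2, lp$b, "+")
  h <- matrix(0, B, units); cc <- matrix(0, B, units)
  hs <- array(0, dim = c(B, units, T_ + 1L))
  cs <- array(0, dim = c(B, units, T_ + 1L))
  gi <- array(0, dim = c(B, units, T_)); gf <- gi; gg <- gi; go <- gi
  tc <- gi
  ii <- seq_len(units)
  for (t in seq_len(T_)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    z <- xw[rows, , drop = FALSE] + h %*% lp$U
    i_ <- sigmoid(z[, ii, drop = FALSE])
    f_ <- sigmoid(z[, ii + units, drop = FALSE])
    g_ <- tanh(z[, ii + 2L * units, drop = FALSE])
    o_ <- sigmoid(z[, ii + 3L * units, drop = FALSE])
    cc <- f_ * cc + i_ * g_
    tch <- tanh(cc)
    h <- o_ * tch
    gi[, , t] <- i_; gf[, , t] <- f_; gg[, , t] <- g_; go[, , t] <- o_
    tc[, , t] <- tch
    hs[, , t + 1L] <- h; cs[, , t + 1L] <- cc
  }
  hmat <- matrix(aperm(hs[, , -1L, drop = FALSE], c(1, 3, 2)), B * T_, units)
  out <- expand_bt(hmat, B, T_)
  ch <- if (cache) list(xm = xm, hs = hs, cs = cs, gi = gi, gf = gf, gg = gg,
                        go = go, tc = tc, B = B, T_ = T_, units = units)
        else NULL
  list(out = out, cache = ch)
}

lstm_layer_backward <- function(lp, ch, dout) {
  B <- ch$B; T_ <- ch$T_; units <- ch$units
  ii <- seq_len(units)
  dzall <- matrix(0, B * T_, 4L * units)
  dh_carry <- matrix(0, B, units)
  dc <- matrix(0, B, units)
  dU <- matrix(0, units, 4L * units)
  for (t in T_:1) {
    dh <- dout[, t, ] + dh_carry
    if (is.null(dim(dh))) dh <- matrix(dh, B, units)
    o_ <- ch$go[, , t]; tch <- ch$tc[, , t]
    i_ <- ch$gi[, , t]; f_ <- ch$gf[, , t]; g_ <- ch$gg[, , t]
    do_ <- dh * tch
    dc <- dc + dh * o_ * (1 - tch^2)
    di <- dc * g_
    dg <- dc * i_
    df <- dc * ch$cs[, , t]      # c_{t-1}
    dz <- cbind(di * i_ * (1 - i_), df * f_ * (1 - f_),
                dg * (1 - g_^2), do_ * o_ * (1 - o_))
    rows <- ((t - 1L) * B + 1L):(t * B)
    dzall[rows, ] <- dz
    hprev <- matrix(ch$hs[, , t], B, units)
    dU <- dU + crossprod(hprev, dz)
    dh_carry <- dz %*% t(lp$U)
    dc <- dc * f_
  }
  dW <- crossprod(ch$xm, dzall)
  db <- colSums(dzall)
  dx <- expand_bt(dzall %*% t(lp$W), B, T_)
  list(grads = list(W = dW, U = dU, b = db), dx = dx)
}

lstm_forward <- function(params, x, cache = FALSE) {
  caches <- list()
  h <- x
  for (l in seq_along(params$layers)) {
    r <- lstm_layer_forward(params$layers[[l]], h, cache)
    h <- r$out
    caches[[l]] <- r$cache
  }
  ro <- linear_forward(params$readout, h, cache)
  list(out = ro$out,
       cache = if (cache) list(layers = caches, readout = ro$cache) else NULL)
}

lstm_backward <- function(params, cache, dout) {
  ro <- linear_backward(params$readout, cache$readout, dout)
  d <- ro$dx
  glayers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    r <- lstm_layer_backward(params$layers[[l]], cache$layers[[l]], d)
    glayers[[l]] <- r$grads
    d <- r$dx
  }
  list(grads = list(layers = glayers, readout = ro$grads), dx = d)
}

# ---- transformer ------------------------------------------------------------

# Per-frame affine embedding, fixed sinusoidal positional encoding, encoder
# blocks (multi-head self-attention with biased q/k/v/output projections,
# feed-forward with two affine maps, two post-block layer normalizations with
# gain and offset, residual connections), per-frame affine readout. No
# stack-level final normalization; positional encodings carry no parameters.

sinusoidal_pe <- function(T_, E) {
  pos <- 0:(T_ - 1)
  pe <- matrix(0, T_, E)
  for (i in 0:(E / 2 - 1)) {
    div <- 10000^(2 * i / E)
    pe[, 2 * i + 1] <- sin(pos / div)
    if (2 * i + 2 <= E) pe[, 2 * i + 2] <- cos(pos / div)
  }
  pe
}

init_transformer <- function(f_in, f_out, embed, ff, layers, heads) {
  blk <- function() list(
    Wq = init_mat(embed, embed), bq = init_vec(embed),
    Wk = init_mat(embed, embed), bk = init_vec(embed),
    Wv = init_mat(embed, embed), bv = init_vec(embed),
    Wo = init_mat(embed, embed), bo = init_vec(embed),
    W1 = init_mat(embed, ff), b1 = init_vec(ff),
    W2 = init_mat(ff, embed), b2 = init_vec(embed),
    ln1_g = rep(1, embed), ln1_b = init_vec(embed),
    ln2_g = rep(1, embed), ln2_b = init_vec(embed))
  list(embed = init_linear(f_in, embed),
       blocks = lapply(seq_len(layers), function(i) blk()),
       readout = init_linear(embed, f_out))
}

LN_EPS <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(out = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_backward <- function(cache, dout) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  E <- ncol(xhat)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Multi-head self-attention over one batch; x is (B*T) x E with row index
# b + (t-1)*B. Attention mixes frames within each sequence.
mha_forward <- function(bp, x, B, T_, heads, cache = FALSE) {
  E <- ncol(x)
  dk <- E / heads
  q <- sweep(x %*% bp$Wq, 2, bp$bq, "+")
  k <- sweep(x %*% bp$Wk, 2, bp$bk, "+")
  v <- sweep(x %*% bp$Wv, 2, bp$bv, "+")
  att <- matrix(0, nrow(x), E)
  A_list <- if (cache) vector("list", B * heads) else NULL
  for (b in seq_len(B)) {
    rows <- b + (0:(T_ - 1)) * B
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      qh <- q[rows, cols, drop = FALSE]
      kh <- k[rows, cols, drop = FALSE]
      vh <- v[rows, cols, drop = FALSE]
      A <- softmax_rows(qh %*% t(kh) / sqrt(dk))
      att[rows, cols] <- A %*% vh
      if (cache) A_list[[(b - 1) * heads + h]] <- A
    }
  }
  out <- sweep(att %*% bp$Wo, 2, bp$bo, "+")
  ch <- if (cache) list(x = x, q = q, k = k, v = v, att = att, A = A_list,
                        B = B, T_ = T_, heads = heads, dk = dk) else NULL
  list(out = out, cache = ch)
}

mha_backward <- function(bp, ch, dout) {
  B <- ch$B; T_ <- ch$T_; heads <- ch$heads; dk <- ch$dk
  datt <- dout %*% t(bp$Wo)
  dWo <- crossprod(ch$att, dout)
  dbo <- colSums(dout)
  dq <- matrix(0, nrow(datt), ncol(datt))
  dk_ <- dq; dv <- dq
  for (b in seq_len(B)) {
    rows <- b + (0:(T_ - 1)) * B
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      A <- ch$A[[(b - 1) * heads + h]]
      dOh <- datt[rows, cols, drop = FALSE]
      vh <- ch$v[rows, cols, drop = FALSE]
      dA <- dOh %*% t(vh)
      dv[rows, cols] <- crossprod(A, dOh)
      dS <- (dA - rowSums(dA * A)) * A / sqrt(dk)
      dq[rows, cols] <- dS %*% ch$k[rows, cols, drop = FALSE]
      dk_[rows, cols] <- crossprod(dS, ch$q[rows, cols, drop = FALSE])
    }
  }
  gr <- list(Wq = crossprod(ch$x, dq), bq = colSums(dq),
             Wk = crossprod(ch$x, dk_), bk = colSums(dk_),
             Wv = crossprod(ch$x, dv), bv = colSums(dv),
             Wo = dWo, bo = dbo)
  dx <- dq %*% t(bp$Wq) + dk_ %*% t(bp$Wk) + dv %*% t(bp$Wv)
  list(grads = gr, dx = dx)
}

transformer_block_forward <- function(bp, x, B, T_, heads, cache = FALSE) {
  mh <- mha_forward(bp, x, B, T_, heads, cache)
  r1 <- x + mh$out
  ln1 <- layernorm_forward(r1, bp$ln1_g, bp$ln1_b)
  h1 <- sweep(ln1$out %*% bp$W1, 2, bp$b1, "+")
  a1 <- pmax(h1, 0)
  ffo <- sweep(a1 %*% bp$W2, 2, bp$b2, "+")
  r2 <- ln1$out + ffo
  ln2 <- layernorm_forward(r2, bp$ln2_g, bp$ln2_b)
  ch <- if (cache) list(mha = mh$cache, ln1 = ln1$cache, ln2 = ln2$cache,
                        ln1_out = ln1$out, a1 = a1, h1pos = h1 > 0) else NULL
  list(out = ln2$out, cache = ch)
}

transformer_block_backward <- function(bp, ch, dout) {
  l2 <- layernorm_backward(ch$ln2, dout)
  dffo <- l2$dx
  dW2 <- crossprod(ch$a1, dffo)
  db2 <- colSums(dffo)
  da1 <- dffo %*% t(bp$W2)
  dh1 <- da1 * ch$h1pos
  dW1 <- crossprod(ch$ln1_out, dh1)
  db1 <- colSums(dh1)
  dln1_out <- dh1 %*% t(bp$W1) + l2$dx  # residual: r2 = ln1_out + ffo
  l1 <- layernorm_backward(ch$ln1, dln1_out)
  dr1 <- l1$dx
  mh <- mha_backward(bp, ch$mha, dr1)
  dx <- dr1 + mh$dx
  grads <- c(mh$grads,
             list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                  ln1_g = l1$dg, ln1_b = l1$db,
                  ln2_g = l2$dg, ln2_b = l2$db))
  list(grads = grads, dx = dx)
}

transformer_forward <- function(params, x, heads, cache = FALSE) {
  d <- dim(x); B <- d[1]; T_ <- d[2]
  emb <- linear_forward(params$embed, x, cache)
  E <- ncol(params$embed$W)
  pe <- sinusoidal_pe(T_, E)
  h <- collapse_bt(emb$out) + pe[rep(seq_len(T_), each = B), , drop = FALSE]
  caches <- list()
  for (l in seq_along(params$blocks)) {
    r <- transformer_block_forward(params$blocks[[l]], h, B, T_, heads, cache)
    h <- r$out
    caches[[l]] <- r$cache
  }
  ro_in <- expand_bt(h, B, T_)
  ro <- linear_forward(params$readout, ro_in, cache)
  list(out = ro$out,
       cache = if (cache) list(embed = emb$cache, blocks = caches,
                               readout = ro$cache, B = B, T_ = T_) else NULL)
}

transformer_backward <- function(params, cache, dout, heads) {
  B <- cache$B; T_ <- cache$T_
  ro <- linear_backward(params$readout, cache$readout, dout)
  d <- collapse_bt(ro$dx)
  gblocks <- vector("list", length(params$blocks))
  for (l in rev(seq_along(params$blocks))) {
    r <- transformer_block_backward(params$blocks[[l]], cache$blocks[[l]], d)
    gblocks[[l]] <- r$grads
    d <- r$dx
  }
  demb <- expand_bt(d, B, T_)
  emb <- linear_backward(params$embed, cache$embed, demb)
  list(grads = list(embed = emb$grads, blocks = gblocks, readout = ro$grads),
       dx = emb$dx)
}

# ---- generic dispatch -------------------------------------------------------

nn_forward <- function(model, x, cache = FALSE) {
  switch(model$config$architecture,
    linear = linear_forward(model$params, x, cache),
    lstm = lstm_forward(model$params, x, cache),
    transformer = transformer_forward(model$params, x,
                                      model$config$tf_heads, cache))
}

nn_backward <- function(model, cache, dout) {
  switch(model$config$architecture,
    linear = linear_backward(model$params, cache, dout),
    lstm = lstm_backward(model$params, cache, dout),
    transformer = transformer_backward(model$params, cache, dout,
                                       model$config$tf_heads))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, mv) p - mv, params,
                     tree_map(function(m, v)
                       lr * (m / bc1) / (sqrt(v / bc2) + eps),
                       state$m, state$v))
  list(params = params, state = state)
}

# Warm-up / inverse-square-root decay learning-rate schedule used for the
# transformer (scaled by the embedding dimension).
transformer_lr <- function(step, embed = 256, warmup = 4000) {
  embed^-0.5 * min(step^-0.5, step * warmup^-1.5)
}
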