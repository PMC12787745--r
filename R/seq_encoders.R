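# Sequence encoders with manual backprop: transformer (pre-norm, multi-head
# self-attention), GRU, LSTM and a causal dilated TCN. All encoders share
# one interface: `.enc_forward(enc, X)` takes an array B x T x C and returns
# a pooled feature matrix B x d plus a cache; `.enc_backward` returns
# gradients with the same structure as `enc$params`.
#
# Batched attention trick: rows of all samples are stacked into one
# (B*T) x d matrix and attention is computed as full (B*T) x (B*T)
# attention under an additive block-diagonal mask, so every step is a
# single BLAS call instead of a loop over samples.

# ---- shared helpers --------------------------------------------------------

# row layout: row (b-1)*T + t  <-> sample b, time t
.seq_flatten <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

.seq_unflatten <- function(M, B, T_len) {
  aperm(array(M, c(T_len, B, ncol(M))), c(2L, 1L, 3L))
}

.sinusoidal_pe <- function(T_len, d) {
  pe <- matrix(0, T_len, d)
  pos <- seq_len(T_len) - 1L
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= d) pe[, 2L * i] <- cos(pos * freq)
  }
  pe
}

.ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xhat <- Xc * inv
  list(out = sweep(Xhat * rep(g, each = nrow(X)), 2L, b, "+"),
       Xhat = Xhat, inv = inv)
}

.ln_backward <- function(cache, g, dY) {
  Xhat <- cache$Xhat
  dXhat <- dY * rep(g, each = nrow(dY))
  dg <- colSums(dY * Xhat)
  db <- colSums(dY)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- cache$inv * (dXhat - m1 - Xhat * m2)
  list(dX = dX, dg = dg, db = db)
}

# numerically stable row softmax for a small square score matrix
.row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# ---- transformer encoder ---------------------------------------------------

enc_tr_init <- function(in_dim, d, n_layers, n_heads, ff_mult = 4) {
  if (d %% n_heads != 0) stop("'d' must be divisible by the head count")
  layers <- list()
  for (l in seq_len(n_layers)) {
    layers[[l]] <- list(
      g1 = rep(1, d), b1 = rep(0, d),
      Wq = .init_mat(d, d), Wk = .init_mat(d, d),
      Wv = .init_mat(d, d), Wo = .init_mat(d, d),
      g2 = rep(1, d), b2 = rep(0, d),
      F1 = .init_mat(d, ff_mult * d), fb1 = numeric(ff_mult * d),
      F2 = .init_mat(ff_mult * d, d), fb2 = numeric(d))
  }
  list(type = "transformer", in_dim = in_dim, d = d,
       n_layers = n_layers, n_heads = n_heads, ff_mult = ff_mult,
       params = list(Wi = .init_mat(in_dim, d), bi = numeric(d),
                     layers = layers, gf = rep(1, d), bf = rep(0, d)))
}

enc_tr_forward <- function(enc, X) {
  B <- dim(X)[1L]; T_len <- dim(X)[2L]
  p <- enc$params
  d <- enc$d; nh <- enc$n_heads; dh <- d / nh
  Xm <- .seq_flatten(X)
  H <- sweep(Xm %*% p$Wi, 2L, p$bi, "+") +
    .sinusoidal_pe(T_len, d)[rep(seq_len(T_len), times = B), ]
  blk <- rep(seq_len(B), each = T_len)
  cache <- list(Xm = Xm, B = B, T_len = T_len, layers = vector("list", enc$n_layers))
  for (l in seq_len(enc$n_layers)) {
    lp <- p$layers[[l]]
    ln1 <- .ln_forward(H, lp$g1, lp$b1)
    Q <- ln1$out %*% lp$Wq; K <- ln1$out %*% lp$Wk; V <- ln1$out %*% lp$Wv
    at <- attn_forward_cpp(Q, K, V, T_len, nh)
    attn <- at$O %*% lp$Wo
    H1 <- H + attn
    ln2 <- .ln_forward(H1, lp$g2, lp$b2)
    Z1 <- sweep(ln2$out %*% lp$F1, 2L, lp$fb1, "+")
    gf <- gelu_forward_cpp(Z1)
    A1 <- gf$Y
    H <- H1 + sweep(A1 %*% lp$F2, 2L, lp$fb2, "+")
    cache$layers[[l]] <- list(ln1 = ln1, Q = Q, K = K, V = V, O = at$O,
                              Ps = at$P, H1 = H1, ln2 = ln2, Z1 = Z1,
                              A1 = A1, U1 = gf$U)
  }
  lnf <- .ln_forward(H, p$gf, p$bf)
  feat <- rowsum(lnf$out, blk) / T_len
  cache$lnf <- lnf
  cache$blk <- blk
  list(feat = feat, cache = cache)
}

enc_tr_backward <- function(enc, cache, dFeat) {
  p <- enc$params
  d <- enc$d; nh <- enc$n_heads; dh <- d / nh
  B <- cache$B; T_len <- cache$T_len
  g <- list(Wi = NULL, bi = NULL, layers = vector("list", enc$n_layers),
            gf = NULL, bf = NULL)
  dH <- dFeat[cache$blk, , drop = FALSE] / T_len
  lb <- .ln_backward(cache$lnf, p$gf, dH)
  g$gf <- lb$dg; g$bf <- lb$db
  dH <- lb$dX
  for (l in rev(seq_len(enc$n_layers))) {
    lp <- p$layers[[l]]
    cl <- cache$layers[[l]]
    # FFN branch
    dZ2 <- dH  # gradient wrt FFN output (residual add)
    gF2 <- crossprod(cl$A1, dZ2)
    gfb2 <- colSums(dZ2)
    dA1 <- tcrossprod(dZ2, lp$F2)
    dZ1 <- gelu_backward_cpp(cl$Z1, cl$U1, dA1)
    gF1 <- crossprod(cl$ln2$out, dZ1)
    gfb1 <- colSums(dZ1)
    dLn2 <- tcrossprod(dZ1, lp$F1)
    lb2 <- .ln_backward(cl$ln2, lp$g2, dLn2)
    dH1 <- dH + lb2$dX
    # attention branch
    dAttn <- dH1
    gWo <- crossprod(cl$O, dAttn)
    dO <- tcrossprod(dAttn, lp$Wo)
    ab <- attn_backward_cpp(cl$Ps, dO, cl$Q, cl$K, cl$V, cache$T_len, nh)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    ln1out <- cl$ln1$out
    gWq <- crossprod(ln1out, dQ)
    gWk <- crossprod(ln1out, dK)
    gWv <- crossprod(ln1out, dV)
    dLn1 <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
      tcrossprod(dV, lp$Wv)
    lb1 <- .ln_backward(cl$ln1, lp$g1, dLn1)
    dH <- dH1 + lb1$dX
    g$layers[[l]] <- list(g1 = lb1$dg, b1 = lb1$db,
                          Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo,
                          g2 = lb2$dg, b2 = lb2$db,
                          F1 = gF1, fb1 = gfb1, F2 = gF2, fb2 = gfb2)
  }
  g$Wi <- crossprod(cache$Xm, dH)
  g$bi <- colSums(dH)
  g
}

# ---- GRU encoder -----------------------------------------------------------

enc_gru_init <- function(in_dim, d) {
  list(type = "gru", in_dim = in_dim, d = d,
       params = list(Wz = .init_mat(in_dim, d), Uz = .init_mat(d, d), bz = numeric(d),
                     Wr = .init_mat(in_dim, d), Ur = .init_mat(d, d), br = numeric(d),
                     Wh = .init_mat(in_dim, d), Uh = .init_mat(d, d), bh = numeric(d)))
}

enc_gru_forward <- function(enc, X) {
  B <- dim(X)[1L]; T_len <- dim(X)[2L]
  p <- enc$params; d <- enc$d
  h <- matrix(0, B, d)
  steps <- vector("list", T_len)
  sig <- .act_fun("sigmoid")$f
  for (t in seq_len(T_len)) {
    xt <- X[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, B)
    z <- sig(sweep(xt %*% p$Wz + h %*% p$Uz, 2L, p$bz, "+"))
    r <- sig(sweep(xt %*% p$Wr + h %*% p$Ur, 2L, p$br, "+"))
    rh <- r * h
    hc <- tanh(sweep(xt %*% p$Wh + rh %*% p$Uh, 2L, p$bh, "+"))
    h_new <- (1 - z) * h + z * hc
    steps[[t]] <- list(x = xt, h_prev = h, z = z, r = r, rh = rh, hc = hc)
    h <- h_new
  }
  list(feat = h, cache = list(steps = steps, T_len = T_len))
}

enc_gru_backward <- function(enc, cache, dFeat) {
  p <- enc$params
  g <- lapply(p, function(x) x * 0)
  dh <- dFeat
  for (t in rev(seq_len(cache$T_len))) {
    st <- cache$steps[[t]]
    dz <- dh * (st$hc - st$h_prev)
    dhc <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dhc_pre <- dhc * (1 - st$hc^2)
    g$Wh <- g$Wh + crossprod(st$x, dhc_pre)
    g$Uh <- g$Uh + crossprod(st$rh, dhc_pre)
    g$bh <- g$bh + colSums(dhc_pre)
    drh <- tcrossprod(dhc_pre, p$Uh)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    g$Wz <- g$Wz + crossprod(st$x, dz_pre)
    g$Uz <- g$Uz + crossprod(st$h_prev, dz_pre)
    g$bz <- g$bz + colSums(dz_pre)
    dh_prev <- dh_prev + tcrossprod(dz_pre, p$Uz)
    dr_pre <- dr * st$r * (1 - st$r)
    g$Wr <- g$Wr + crossprod(st$x, dr_pre)
    g$Ur <- g$Ur + crossprod(st$h_prev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    dh_prev <- dh_prev + tcrossprod(dr_pre, p$Ur)
    dh <- dh_prev
  }
  g
}

# ---- LSTM encoder ----------------------------------------------------------

enc_lstm_init <- function(in_dim, d) {
  gate <- function() list(W = .init_mat(in_dim, d), U = .init_mat(d, d),
                          b = numeric(d))
  list(type = "lstm", in_dim = in_dim, d = d,
       params = list(i = gate(), f = gate(), o = gate(), g = gate()))
}

enc_lstm_forward <- function(enc, X) {
  B <- dim(X)[1L]; T_len <- dim(X)[2L]
  p <- enc$params; d <- enc$d
  h <- matrix(0, B, d); cst <- matrix(0, B, d)
  steps <- vector("list", T_len)
  sig <- .act_fun("sigmoid")$f
  for (t in seq_len(T_len)) {
    xt <- X[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, B)
    gi <- sig(sweep(xt %*% p$i$W + h %*% p$i$U, 2L, p$i$b, "+"))
    gf <- sig(sweep(xt %*% p$f$W + h %*% p$f$U, 2L, p$f$b, "+"))
    go <- sig(sweep(xt %*% p$o$W + h %*% p$o$U, 2L, p$o$b, "+"))
    gg <- tanh(sweep(xt %*% p$g$W + h %*% p$g$U, 2L, p$g$b, "+"))
    c_new <- gf * cst + gi * gg
    tc <- tanh(c_new)
    steps[[t]] <- list(x = xt, h_prev = h, c_prev = cst,
                       i = gi, f = gf, o = go, g = gg, tc = tc)
    cst <- c_new
    h <- go * tc
  }
  list(feat = h, cache = list(steps = steps, T_len = T_len))
}

enc_lstm_backward <- function(enc, cache, dFeat) {
  p <- enc$params
  g <- rapply(p, function(x) x * 0, how = "replace")
  dh <- dFeat
  dc <- dh * 0
  for (t in rev(seq_len(cache$T_len))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_prev <- dc * st$f
    pre <- list(i = di * st$i * (1 - st$i),
                f = df * st$f * (1 - st$f),
                o = do_ * st$o * (1 - st$o),
                g = dg * (1 - st$g^2))
    dh_prev <- dh * 0
    for (nm in names(pre)) {
      g[[nm]]$W <- g[[nm]]$W + crossprod(st$x, pre[[nm]])
      g[[nm]]$U <- g[[nm]]$U + crossprod(st$h_prev, pre[[nm]])
      g[[nm]]$b <- g[[nm]]$b + colSums(pre[[nm]])
      dh_prev <- dh_prev + tcrossprod(pre[[nm]], p[[nm]]$U)
    }
    dh <- dh_prev
    dc <- dc_prev
  }
  g
}

# ---- temporal convolutional encoder (causal, dilated) ----------------------

enc_tcn_init <- function(in_dim, channels, kernel = 3,
                         dilations = 2^(seq_along(channels) - 1L)) {
  stopifnot(length(dilations) == length(channels))
  layers <- list()
  c_in <- in_dim
  for (l in seq_along(channels)) {
    Ws <- lapply(seq_len(kernel), function(j) .init_mat(c_in, channels[l]))
    names(Ws) <- paste0("W", seq_len(kernel))
    layers[[l]] <- c(Ws, list(b = numeric(channels[l])))
    c_in <- channels[l]
  }
  list(type = "tcn", in_dim = in_dim, d = channels[length(channels)],
       channels = channels, kernel = kernel, dilations = dilations,
       params = list(layers = layers))
}

# shift rows back by s timesteps within each sample block (zero-padded)
.tcn_shift_idx <- function(B, T_len, s) {
  t_of <- rep(seq_len(T_len), times = B)
  idx <- seq_len(B * T_len) - s
  idx[t_of - s < 1L] <- NA_integer_
  idx
}

enc_tcn_forward <- function(enc, X) {
  B <- dim(X)[1L]; T_len <- dim(X)[2L]
  A <- .seq_flatten(X)
  caches <- vector("list", length(enc$channels))
  for (l in seq_along(enc$channels)) {
    lp <- enc$params$layers[[l]]
    dil <- enc$dilations[l]
    Z <- matrix(rep(lp$b, each = nrow(A)), nrow(A))
    shifted <- vector("list", enc$kernel)
    for (j in seq_len(enc$kernel)) {
      idx <- .tcn_shift_idx(B, T_len, (j - 1L) * dil)
      As <- A * 0
      ok <- !is.na(idx)
      As[ok, ] <- A[idx[ok], , drop = FALSE]
      shifted[[j]] <- As
      Z <- Z + As %*% lp[[paste0("W", j)]]
    }
    A_new <- pmax(Z, 0)
    caches[[l]] <- list(A_in = A, shifted = shifted, Z = Z)
    A <- A_new
  }
  last <- seq_len(B) * T_len  # row of t = T for each sample
  list(feat = A[last, , drop = FALSE],
       cache = list(caches = caches, B = B, T_len = T_len, A_out = A))
}

enc_tcn_backward <- function(enc, cache, dFeat) {
  B <- cache$B; T_len <- cache$T_len
  dA <- cache$A_out * 0
  dA[seq_len(B) * T_len, ] <- dFeat
  g <- list(layers = vector("list", length(enc$channels)))
  for (l in rev(seq_along(enc$channels))) {
    lp <- enc$params$layers[[l]]
    cl <- cache$caches[[l]]
    dZ <- dA * (cl$Z > 0)
    gl <- list()
    dA_in <- cl$A_in * 0
    dil <- enc$dilations[l]
    for (j in seq_len(enc$kernel)) {
      gl[[paste0("W", j)]] <- crossprod(cl$shifted[[j]], dZ)
      idx <- .tcn_shift_idx(B, T_len, (j - 1L) * dil)
      ok <- !is.na(idx)
      dShift <- tcrossprod(dZ, lp[[paste0("W", j)]])
      tmp <- dA_in * 0
      tmp[idx[ok], ] <- dShift[ok, , drop = FALSE]
      dA_in <- dA_in + tmp
    }
    gl$b <- colSums(dZ)
    g$layers[[l]] <- gl
    dA <- dA_in
  }
  g
}

# ---- dispatch --------------------------------------------------------------

.enc_forward <- function(enc, X) {
  switch(enc$type,
         transformer = enc_tr_forward(enc, X),
         gru = enc_gru_forward(enc, X),
         lstm = enc_lstm_forward(enc, X),
         tcn = enc_tcn_forward(enc, X))
}

.enc_backward <- function(enc, cache, dFeat) {
  switch(enc$type,
         transformer = enc_tr_backward(enc, cache, dFeat),
         gru = enc_gru_backward(enc, cache, dFeat),
         lstm = enc_lstm_backward(enc, cache, dFeat),
         tcn = enc_tcn_backward(enc, cache, dFeat))
}

.n_params <- function(params) {
  sum(unlist(rapply(params, length, how = "unlist")))
}
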