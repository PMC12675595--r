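# Minimal dense-layer toolkit used by the TAPB model: every primitive has a
# forward returning (out, cache) and a backward mapping upstream gradients to
# input/parameter gradients. Rows are sequence positions, columns features.
# Analytic gradients are verified against finite differences in the tests.

addb <- function(m, b) m + rep(b, each = nrow(m))

softmax_rows <- function(s) {
  # max.col is much faster than apply(s, 1, max) on the small matrices here
  e <- exp(s - s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))])
  e / rowSums(e)
}

nn_linear_fwd <- function(x, W, b) {
  list(out = addb(x %*% W, b), x = x)
}

nn_linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% t(W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

LN_EPS <- 1e-5

nn_layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(out = addb(xhat * rep(g, each = nrow(x)), b),
       xhat = xhat, inv = inv, g = g)
}

nn_layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- dout * rep(cache$g, each = nrow(dout))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = cache$inv * (dxhat - m1 - xhat * m2),
       dg = colSums(dout * xhat),
       db = colSums(dout))
}

# Rotary position encoding: positions rotate query/key feature pairs by
# angles pos * base^(-2k/dk); applied per attention head.
rope_cache <- function(L, dk, base = 10000) {
  stopifnot(dk %% 2L == 0L)
  inv_freq <- base^(-(2 * (seq_len(dk / 2L) - 1L)) / dk)
  ang <- outer(0:(L - 1L), inv_freq)
  list(cos = cos(ang), sin = sin(ang))
}

rope_apply <- function(x, rc) {
  dk <- ncol(x)
  odd <- seq(1L, dk, 2L)
  even <- odd + 1L
  L <- nrow(x)
  cs <- rc$cos[seq_len(L), , drop = FALSE]
  sn <- rc$sin[seq_len(L), , drop = FALSE]
  out <- x
  out[, odd] <- x[, odd] * cs - x[, even] * sn
  out[, even] <- x[, odd] * sn + x[, even] * cs
  out
}

rope_unapply <- function(d, rc) {
  dk <- ncol(d)
  odd <- seq(1L, dk, 2L)
  even <- odd + 1L
  L <- nrow(d)
  cs <- rc$cos[seq_len(L), , drop = FALSE]
  sn <- rc$sin[seq_len(L), , drop = FALSE]
  out <- d
  out[, odd] <- d[, odd] * cs + d[, even] * sn
  out[, even] <- -d[, odd] * sn + d[, even] * cs
  out
}

# Multi-head attention over unpadded sequences. p holds Wq,bq,Wk,bk,Wv,bv,
# Wo,bo; rope (NULL or a rope_cache) rotates queries and keys.
nn_mha_fwd <- function(xq, xkv, p, H, rope = NULL) {
  Dm <- ncol(p$Wq)
  dk <- Dm %/% H
  Q <- addb(xq %*% p$Wq, p$bq)
  K <- addb(xkv %*% p$Wk, p$bk)
  V <- addb(xkv %*% p$Wv, p$bv)
  heads <- vector("list", H)
  O <- matrix(0, nrow(xq), Dm)
  for (h in seq_len(H)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    Qh <- Q[, idx, drop = FALSE]
    Kh <- K[, idx, drop = FALSE]
    if (!is.null(rope)) {
      Qh <- rope_apply(Qh, rope)
      Kh <- rope_apply(Kh, rope)
    }
    Vh <- V[, idx, drop = FALSE]
    A <- softmax_rows(tcrossprod(Qh, Kh) / sqrt(dk))
    O[, idx] <- A %*% Vh
    heads[[h]] <- list(Q = Qh, K = Kh, V = Vh, A = A)
  }
  out <- addb(O %*% p$Wo, p$bo)
  list(out = out, O = O, heads = heads, xq = xq, xkv = xkv, H = H, dk = dk,
       rope = rope)
}

nn_mha_bwd <- function(dout, cache, p) {
  H <- cache$H
  dk <- cache$dk
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  Lq <- nrow(cache$xq)
  Lk <- nrow(cache$xkv)
  dQ <- matrix(0, Lq, H * dk)
  dK <- matrix(0, Lk, H * dk)
  dV <- matrix(0, Lk, H * dk)
  for (h in seq_len(H)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    hc <- cache$heads[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, hc$V)
    dVh <- crossprod(hc$A, dOh)
    dS <- hc$A * (dA - rowSums(dA * hc$A))
    dQh <- dS %*% hc$K / sqrt(dk)
    dKh <- crossprod(dS, hc$Q) / sqrt(dk)
    if (!is.null(cache$rope)) {
      dQh <- rope_unapply(dQh, cache$rope)
      dKh <- rope_unapply(dKh, cache$rope)
    }
    dQ[, idx] <- dQh
    dK[, idx] <- dKh
    dV[, idx] <- dVh
  }
  list(
    dxq = dQ %*% t(p$Wq),
    dxkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
    grads = list(
      Wq = crossprod(cache$xq, dQ), bq = colSums(dQ),
      Wk = crossprod(cache$xkv, dK), bk = colSums(dK),
      Wv = crossprod(cache$xkv, dV), bv = colSums(dV),
      Wo = dWo, bo = dbo
    )
  )
}

nn_ffn_fwd <- function(x, p) {
  h <- addb(x %*% p$W1, p$b1)
  a <- gelu(h)
  list(out = addb(a %*% p$W2, p$b2), x = x, h = h, a = a)
}

nn_ffn_bwd <- function(dout, cache, p) {
  da <- dout %*% t(p$W2)
  dh <- da * gelu_grad(cache$h)
  list(
    dx = dh %*% t(p$W1),
    grads = list(
      W1 = crossprod(cache$x, dh), b1 = colSums(dh),
      W2 = crossprod(cache$a, dout), b2 = colSums(dout)
    )
  )
}
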