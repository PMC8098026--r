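# Dense building blocks for the sequence encoders and the interaction head.
#
# There is no automatic differentiation here: every layer exposes a forward
# pass that returns its output together with a cache, and a matching backward
# pass that maps the upstream gradient to gradients for the layer input and
# parameters.  A sequence is represented as an L x d matrix (rows = positions,
# d = embedding width); all derivations follow the standard post-norm
# transformer encoder block (self-attention + position-wise feed-forward).

# Truncated-normal initializer: N(0, sd^2) restricted to |x| <= 2 sd.
trunc_normal <- function(n, sd = 0.02) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(n, 16L), sd = sd)
    out <- c(out, x[abs(x) <= 2 * sd])
  }
  out[seq_len(n)]
}

mat_init <- function(nr, nc, sd = 0.02) matrix(trunc_normal(nr * nc, sd), nr, nc)

## ---- layer norm -----------------------------------------------------------

layer_norm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu                       # mu recycles down columns (length nrow)
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layer_norm_backward <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- multi-head self-attention -------------------------------------------

# key_mask: logical length L; FALSE marks PAD positions, which are excluded as
# attention *keys* so padding content cannot leak into real-token context.
mha_forward <- function(x, p, n_heads, key_mask) {
  L <- nrow(x)
  d <- ncol(x)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  Q <- sweep(x %*% p$Wq, 2, p$bq, `+`)
  K <- sweep(x %*% p$Wk, 2, p$bk, `+`)
  V <- sweep(x %*% p$Wv, 2, p$bv, `+`)
  H <- matrix(0, L, d)
  heads <- vector("list", n_heads)
  neg <- -1e30
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scale
    S[, !key_mask] <- neg
    S <- S - apply(S, 1, max)
    P <- exp(S)
    P <- P / rowSums(P)
    H[, cols] <- P %*% V[, cols, drop = FALSE]
    heads[[h]] <- list(P = P, cols = cols)
  }
  out <- sweep(H %*% p$Wo, 2, p$bo, `+`)
  list(out = out,
       cache = list(x = x, Q = Q, K = K, V = V, H = H, heads = heads,
                    scale = scale, n_heads = n_heads))
}

mha_backward <- function(dout, p, cache) {
  x <- cache$x
  dH <- dout %*% t(p$Wo)
  g <- list(Wq = NULL, bq = NULL, Wk = NULL, bk = NULL, Wv = NULL, bv = NULL,
            Wo = t(cache$H) %*% dout, bo = colSums(dout))
  dQ <- matrix(0, nrow(x), ncol(x))
  dK <- dQ
  dV <- dQ
  for (h in seq_len(cache$n_heads)) {
    hd <- cache$heads[[h]]
    cols <- hd$cols
    P <- hd$P
    dHh <- dH[, cols, drop = FALSE]
    dP <- dHh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- t(P) %*% dHh
    # softmax jacobian row-wise; masked keys have P == 0 hence dS == 0 there
    dS <- P * (dP - rowSums(dP * P))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) * cache$scale
    dK[, cols] <- (t(dS) %*% cache$Q[, cols, drop = FALSE]) * cache$scale
  }
  g$Wq <- t(x) %*% dQ; g$bq <- colSums(dQ)
  g$Wk <- t(x) %*% dK; g$bk <- colSums(dK)
  g$Wv <- t(x) %*% dV; g$bv <- colSums(dV)
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dx, grads = g)
}

## ---- transformer encoder layer (post-norm) --------------------------------

encoder_layer_init <- function(d, ffn_dim) {
  list(Wq = mat_init(d, d), bq = numeric(d),
       Wk = mat_init(d, d), bk = numeric(d),
       Wv = mat_init(d, d), bv = numeric(d),
       Wo = mat_init(d, d), bo = numeric(d),
       ln1_g = rep(1, d), ln1_b = numeric(d),
       W1 = mat_init(d, ffn_dim), b1 = numeric(ffn_dim),
       W2 = mat_init(ffn_dim, d), b2 = numeric(d),
       ln2_g = rep(1, d), ln2_b = numeric(d))
}

# Inverted dropout; mask cached for the backward pass.  rate 0 => identity.
dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate), nrow(x), ncol(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

encoder_layer_forward <- function(x, p, n_heads, key_mask, dropout = 0, train = FALSE) {
  att <- mha_forward(x, p, n_heads, key_mask)
  dr1 <- dropout_forward(att$out, dropout, train)
  ln1 <- layer_norm_forward(x + dr1$out, p$ln1_g, p$ln1_b)
  x1 <- ln1$out
  h_pre <- sweep(x1 %*% p$W1, 2, p$b1, `+`)
  h <- pmax(h_pre, 0)
  f <- sweep(h %*% p$W2, 2, p$b2, `+`)
  dr2 <- dropout_forward(f, dropout, train)
  ln2 <- layer_norm_forward(x1 + dr2$out, p$ln2_g, p$ln2_b)
  list(out = ln2$out,
       cache = list(att = att$cache, dr1 = dr1$mask, ln1 = ln1$cache, x1 = x1,
                    h_pre = h_pre, h = h, dr2 = dr2$mask, ln2 = ln2$cache))
}

encoder_layer_backward <- function(dout, p, cache) {
  b2 <- layer_norm_backward(dout, cache$ln2)
  dx1 <- b2$dx
  df <- if (is.null(cache$dr2)) b2$dx else b2$dx * cache$dr2
  dh <- df %*% t(p$W2)
  gW2 <- t(cache$h) %*% df
  gb2 <- colSums(df)
  dh_pre <- dh * (cache$h_pre > 0)
  gW1 <- t(cache$x1) %*% dh_pre
  gb1 <- colSums(dh_pre)
  dx1 <- dx1 + dh_pre %*% t(p$W1)
  b1 <- layer_norm_backward(dx1, cache$ln1)
  dx <- b1$dx
  datt <- if (is.null(cache$dr1)) b1$dx else b1$dx * cache$dr1
  ba <- mha_backward(datt, p, cache$att)
  dx <- dx + ba$dx
  g <- ba$grads
  g$ln1_g <- b1$dgamma; g$ln1_b <- b1$dbeta
  g$W1 <- gW1; g$b1 <- gb1; g$W2 <- gW2; g$b2 <- gb2
  g$ln2_g <- b2$dgamma; g$ln2_b <- b2$dbeta
  # order grads to mirror encoder_layer_init
  g[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
      "ln1_g", "ln1_b", "W1", "b1", "W2", "b2", "ln2_g", "ln2_b")] -> g
  list(dx = dx, grads = g)
}

## ---- 2-D valid convolution + ReLU ----------------------------------------

# I: H x W map (one input channel); K: k x k x n_filters kernels; bias: n_filters.
conv_relu_forward <- function(I, K, bias) {
  k <- dim(K)[1]
  nf <- dim(K)[3]
  Ho <- nrow(I) - k + 1
  Wo <- ncol(I) - k + 1
  if (Ho < 1 || Wo < 1) stop("interaction map smaller than convolution kernel")
  pre <- array(0, c(Ho, Wo, nf))
  for (f in seq_len(nf)) {
    acc <- matrix(bias[f], Ho, Wo)
    for (u in seq_len(k)) {
      for (v in seq_len(k)) {
        acc <- acc + K[u, v, f] * I[u:(u + Ho - 1), v:(v + Wo - 1), drop = FALSE]
      }
    }
    pre[, , f] <- acc
  }
  list(out = pmax(pre, 0), pre = pre)
}

conv_relu_backward <- function(dout, I, K, pre) {
  k <- dim(K)[1]
  nf <- dim(K)[3]
  Ho <- dim(pre)[1]
  Wo <- dim(pre)[2]
  dpre <- dout * (pre > 0)
  dI <- matrix(0, nrow(I), ncol(I))
  dK <- array(0, dim(K))
  db <- numeric(nf)
  for (f in seq_len(nf)) {
    dp <- dpre[, , f]
    db[f] <- sum(dp)
    for (u in seq_len(k)) {
      for (v in seq_len(k)) {
        rows <- u:(u + Ho - 1)
        cols <- v:(v + Wo - 1)
        dK[u, v, f] <- sum(I[rows, cols] * dp)
        dI[rows, cols] <- dI[rows, cols] + K[u, v, f] * dp
      }
    }
  }
  list(dI = dI, dK = dK, db = db)
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = params_zeros_like(params), v = params_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- params_map2(state$m, state$v, function(m, v) {
    (m / c1) / (sqrt(v / c2) + eps)
  })
  params <- params_map2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}
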