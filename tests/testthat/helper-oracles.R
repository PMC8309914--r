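# Independent straight-line oracles, written scalar-by-scalar on purpose so
# they share no code path with the package internals they check.

# Lin's concordance, population moments, computed with explicit loops
oracle_ccc <- function(y, x) {
  n <- length(y)
  my <- 0; mx <- 0
  for (i in seq_len(n)) { my <- my + y[i] / n; mx <- mx + x[i] / n }
  vy <- 0; vx <- 0; cv <- 0
  for (i in seq_len(n)) {
    vy <- vy + (y[i] - my)^2 / n
    vx <- vx + (x[i] - mx)^2 / n
    cv <- cv + (y[i] - my) * (x[i] - mx) / n
  }
  2 * cv / (vy + vx + (mx - my)^2)
}

# scaled dot-product attention evaluated position by position (single head)
oracle_attention <- function(X, w) {
  t <- nrow(X); dm <- ncol(X)
  lin <- function(M, W, b) {
    out <- matrix(0, nrow(M), ncol(W))
    for (r in seq_len(nrow(M))) for (c in seq_len(ncol(W))) {
      acc <- b[c]
      for (k in seq_len(ncol(M))) acc <- acc + M[r, k] * W[k, c]
      out[r, c] <- acc
    }
    out
  }
  Q <- lin(X, w$Wq, w$bq); K <- lin(X, w$Wk, w$bk); V <- lin(X, w$Wv, w$bv)
  Z <- matrix(0, t, dm)
  for (j in seq_len(t)) {
    a <- numeric(t)
    for (i in seq_len(t)) {
      s <- 0
      for (k in seq_len(dm)) s <- s + Q[j, k] * K[i, k]
      a[i] <- s / sqrt(dm)
    }
    e <- exp(a - max(a)); ap <- e / sum(e)
    for (i in seq_len(t)) Z[j, ] <- Z[j, ] + ap[i] * V[i, ]
  }
  lin(Z, w$Wo, w$bo)
}

# one full encoder layer (h = 1, eval mode): positional encoding, attention,
# residual + layer norm, feed-forward, residual + layer norm
oracle_encoder_layer <- function(X, lp, ln_eps = 1e-5) {
  t <- nrow(X); dm <- ncol(X)
  pe <- matrix(0, t, dm)
  for (pos in seq_len(t)) for (col in seq_len(dm)) {
    i0 <- (col - 1) %/% 2
    ang <- (pos - 1) / 10000^(2 * i0 / dm)
    pe[pos, col] <- if ((col - 1) %% 2 == 0) sin(ang) else cos(ang)
  }
  X <- X + pe
  lnorm <- function(M, g, b) {
    out <- M
    for (r in seq_len(nrow(M))) {
      mu <- mean(M[r, ]); v <- mean((M[r, ] - mu)^2)
      out[r, ] <- g * (M[r, ] - mu) / sqrt(v + ln_eps) + b
    }
    out
  }
  a <- oracle_attention(X, lp$attn)
  n1 <- lnorm(X + a, lp$ln1$g, lp$ln1$b)
  h <- pmax(sweep(n1 %*% lp$ff$W1, 2, lp$ff$b1, "+"), 0)
  f <- sweep(h %*% lp$ff$W2, 2, lp$ff$b2, "+")
  lnorm(n1 + f, lp$ln2$g, lp$ln2$b)
}
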