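# Internal numeric core for the transformer encoder.
#
# All batched activations live in a single (b*t) x d matrix in subject-major
# row order, so linear maps are one BLAS call per batch; only the attention
# similarity matrices are formed per subject. Backpropagation is written by
# hand, layer by layer, and verified against finite differences in the tests.

LN_EPS <- 1e-5

addb <- function(M, b) sweep(M, 2L, b, "+")

relu <- function(x) {
  x[x < 0] <- 0
  x
}

new_mask <- function(nr, nc, p) {
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

linear_init <- function(n_in, n_out) {
  r <- 1 / sqrt(n_in)
  list(W = matrix(runif(n_in * n_out, -r, r), n_in, n_out),
       b = runif(n_out, -r, r))
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like)
  else if (is.null(p)) NULL
  else p * 0
}

init_params <- function(cfg) {
  dm <- cfg$d_model
  layer_init <- function() {
    qk <- linear_init(dm, dm); kk <- linear_init(dm, dm)
    vv <- linear_init(dm, dm); oo <- linear_init(dm, dm)
    f1 <- linear_init(dm, cfg$ff_hidden); f2 <- linear_init(cfg$ff_hidden, dm)
    list(attn = list(Wq = qk$W, bq = qk$b, Wk = kk$W, bk = kk$b,
                     Wv = vv$W, bv = vv$b, Wo = oo$W, bo = oo$b),
         ln1 = list(g = rep(1, dm), b = rep(0, dm)),
         ff = list(W1 = f1$W, b1 = f1$b, W2 = f2$W, b2 = f2$b),
         ln2 = list(g = rep(1, dm), b = rep(0, dm)))
  }
  params <- list(
    proj = if (cfg$project) linear_init(cfg$input_dim, dm),
    layers = lapply(seq_len(cfg$num_layers), function(i) layer_init()),
    embed = linear_init(dm, cfg$embed_dim),
    reg = linear_init(cfg$embed_dim, 1L),
    cls = linear_init(cfg$embed_dim, cfg$n_classes)
  )
  params
}

pe_matrix <- function(t, d_model) {
  pos <- seq_len(t) - 1
  cols <- seq_len(d_model) - 1
  pair <- cols %/% 2L
  angle <- outer(pos, 10000^(2 * pair / d_model), "/")
  pe <- matrix(0, t, d_model)
  is_sin <- cols %% 2L == 0L
  pe[, is_sin] <- sin(angle[, is_sin, drop = FALSE])
  pe[, !is_sin] <- cos(angle[, !is_sin, drop = FALSE])
  pe
}

## ---- attention -------------------------------------------------------------

fwd_attn <- function(M, b, t, w, h) {
  dm <- ncol(M)
  dk <- dm %/% h
  Q <- addb(M %*% w$Wq, w$bq)
  K <- addb(M %*% w$Wk, w$bk)
  V <- addb(M %*% w$Wv, w$bv)
  Z <- matrix(0, nrow(M), dm)
  A_list <- vector("list", b)
  for (i in seq_len(b)) {
    ri <- ((i - 1L) * t + 1L):(i * t)
    A_i <- vector("list", h)
    for (j in seq_len(h)) {
      hj <- ((j - 1L) * dk + 1L):(j * dk)
      S <- tcrossprod(Q[ri, hj, drop = FALSE], K[ri, hj, drop = FALSE]) / sqrt(dk)
      A <- row_softmax(S)
      Z[ri, hj] <- A %*% V[ri, hj, drop = FALSE]
      A_i[[j]] <- A
    }
    A_list[[i]] <- A_i
  }
  out <- addb(Z %*% w$Wo, w$bo)
  list(out = out, cache = list(M = M, Q = Q, K = K, V = V, Z = Z,
                               A = A_list, b = b, t = t, h = h, dk = dk))
}

bwd_attn <- function(dOut, cache, w) {
  b <- cache$b; t <- cache$t; h <- cache$h; dk <- cache$dk
  dZ <- dOut %*% t(w$Wo)
  dWo <- crossprod(cache$Z, dOut)
  dbo <- colSums(dOut)
  dQ <- dZ * 0; dK <- dQ; dV <- dQ
  for (i in seq_len(b)) {
    ri <- ((i - 1L) * t + 1L):(i * t)
    for (j in seq_len(h)) {
      hj <- ((j - 1L) * dk + 1L):(j * dk)
      A <- cache$A[[i]][[j]]
      dZh <- dZ[ri, hj, drop = FALSE]
      dA <- tcrossprod(dZh, cache$V[ri, hj, drop = FALSE])
      dV[ri, hj] <- crossprod(A, dZh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[ri, hj] <- dS %*% cache$K[ri, hj, drop = FALSE] / sqrt(dk)
      dK[ri, hj] <- crossprod(dS, cache$Q[ri, hj, drop = FALSE]) / sqrt(dk)
    }
  }
  dM <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  grads <- list(Wq = crossprod(cache$M, dQ), bq = colSums(dQ),
                Wk = crossprod(cache$M, dK), bk = colSums(dK),
                Wv = crossprod(cache$M, dV), bv = colSums(dV),
                Wo = dWo, bo = dbo)
  list(dM = dM, grads = grads)
}

## ---- layer norm ------------------------------------------------------------

fwd_ln <- function(M, g, be) {
  mu <- rowMeans(M)
  v <- rowMeans(M^2) - mu^2
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- (M - mu) * inv
  out <- addb(sweep(xhat, 2L, g, "*"), be)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

bwd_ln <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, "*")
  dM <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dM = dM, dg = dg, db = db)
}

## ---- encoder layer ---------------------------------------------------------

fwd_layer <- function(M, b, t, lp, h, p_drop, training, layer_id) {
  att <- fwd_attn(M, b, t, lp$attn, h)
  m_a <- if (training && p_drop > 0) new_mask(nrow(M), ncol(M), p_drop)
  a_d <- if (is.null(m_a)) att$out else att$out * m_a
  ln1 <- fwd_ln(M + a_d, lp$ln1$g, lp$ln1$b)
  n1 <- ln1$out
  f1 <- relu(addb(n1 %*% lp$ff$W1, lp$ff$b1))
  f2 <- addb(f1 %*% lp$ff$W2, lp$ff$b2)
  m_f <- if (training && p_drop > 0) new_mask(nrow(M), ncol(M), p_drop)
  f_d <- if (is.null(m_f)) f2 else f2 * m_f
  ln2 <- fwd_ln(n1 + f_d, lp$ln2$g, lp$ln2$b)
  if (!all(is.finite(ln2$out))) {
    abort(sprintf("Non-finite activations in encoder layer %d.", layer_id),
          class = "maft_error_numeric")
  }
  list(out = ln2$out,
       cache = list(attn = att$cache, m_a = m_a, ln1 = ln1$cache,
                    n1 = n1, f1 = f1, m_f = m_f, ln2 = ln2$cache))
}

bwd_layer <- function(dN2, cache, lp) {
  l2 <- bwd_ln(dN2, cache$ln2, lp$ln2$g)
  dR2 <- l2$dM
  dF2 <- if (is.null(cache$m_f)) dR2 else dR2 * cache$m_f
  dN1 <- dR2
  gW2 <- crossprod(cache$f1, dF2)
  gb2 <- colSums(dF2)
  dF1 <- dF2 %*% t(lp$ff$W2)
  dP1 <- dF1 * (cache$f1 > 0)
  gW1 <- crossprod(cache$n1, dP1)
  gb1 <- colSums(dP1)
  dN1 <- dN1 + dP1 %*% t(lp$ff$W1)
  l1 <- bwd_ln(dN1, cache$ln1, lp$ln1$g)
  dR1 <- l1$dM
  dA <- if (is.null(cache$m_a)) dR1 else dR1 * cache$m_a
  att <- bwd_attn(dA, cache$attn, lp$attn)
  list(dM = dR1 + att$dM,
       grads = list(attn = att$grads,
                    ln1 = list(g = l1$dg, b = l1$db),
                    ff = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                    ln2 = list(g = l2$dg, b = l2$db)))
}

## ---- full network ----------------------------------------------------------

# M: (b*t) x input_dim activations, subject-major
forward_net <- function(params, cfg, M, b, t, training = FALSE) {
  cache <- list(M0 = M, b = b, t = t)
  if (cfg$project) M <- addb(M %*% params$proj$W, params$proj$b)
  M <- M + pe_matrix(t, cfg$d_model)[rep(seq_len(t), times = b), , drop = FALSE]
  layer_caches <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    fl <- fwd_layer(M, b, t, params$layers[[l]], cfg$num_heads,
                    cfg$dropout, training, l)
    M <- fl$out
    layer_caches[[l]] <- fl$cache
  }
  V <- rowsum(M, group = rep(seq_len(b), each = t), reorder = FALSE) / t
  R1 <- relu(V)
  m1 <- if (training && cfg$dropout > 0) new_mask(b, cfg$d_model, cfg$dropout)
  D1 <- if (is.null(m1)) R1 else R1 * m1
  Emb <- addb(D1 %*% params$embed$W, params$embed$b)
  Re <- relu(Emb)
  m2 <- if (training && cfg$dropout > 0) new_mask(b, cfg$embed_dim, cfg$dropout)
  m3 <- if (training && cfg$dropout > 0) new_mask(b, cfg$embed_dim, cfg$dropout)
  D2 <- if (is.null(m2)) Re else Re * m2
  D3 <- if (is.null(m3)) Re else Re * m3
  yhat <- drop(addb(D2 %*% params$reg$W, params$reg$b))
  logits <- addb(D3 %*% params$cls$W, params$cls$b)
  cache$layers <- layer_caches
  cache <- c(cache, list(V = V, m1 = m1, D1 = D1, Emb = Emb, Re = Re,
                         m2 = m2, m3 = m3, D2 = D2, D3 = D3))
  list(yhat = yhat, logits = logits, cache = cache)
}

backward_net <- function(dyhat, dlogits, cache, params, cfg) {
  b <- cache$b; t <- cache$t
  dyhat <- matrix(dyhat, ncol = 1L)
  g_reg <- list(W = crossprod(cache$D2, dyhat), b = sum(dyhat))
  dD2 <- dyhat %*% t(params$reg$W)
  g_cls <- list(W = crossprod(cache$D3, dlogits), b = colSums(dlogits))
  dD3 <- dlogits %*% t(params$cls$W)
  dRe <- (if (is.null(cache$m2)) dD2 else dD2 * cache$m2) +
         (if (is.null(cache$m3)) dD3 else dD3 * cache$m3)
  dEmb <- dRe * (cache$Emb > 0)
  g_embed <- list(W = crossprod(cache$D1, dEmb), b = colSums(dEmb))
  dD1 <- dEmb %*% t(params$embed$W)
  dR1 <- if (is.null(cache$m1)) dD1 else dD1 * cache$m1
  dV <- dR1 * (cache$V > 0)
  dM <- dV[rep(seq_len(b), each = t), , drop = FALSE] / t
  g_layers <- vector("list", cfg$num_layers)
  for (l in rev(seq_len(cfg$num_layers))) {
    bl <- bwd_layer(dM, cache$layers[[l]], params$layers[[l]])
    dM <- bl$dM
    g_layers[[l]] <- bl$grads
  }
  g_proj <- NULL
  if (cfg$project) {
    g_proj <- list(W = crossprod(cache$M0, dM), b = colSums(dM))
  }
  list(proj = g_proj, layers = g_layers, embed = g_embed,
       reg = g_reg, cls = g_cls)
}

# loss + gradients for one batch; y on the PHQ-8 scale, cls in 0..4
net_loss_grads <- function(params, cfg, M, b, t, y, cls, a, b_w,
                           training = TRUE) {
  fw <- forward_net(params, cfg, M, b, t, training = training)
  l_re <- if (a > 0) ccc_loss(y, fw$yhat) else 0
  p <- row_softmax(fw$logits)
  l_cl <- if (b_w > 0) cross_entropy(fw$logits, cls, logits = TRUE) else 0
  loss <- a * l_re + b_w * l_cl
  dyhat <- if (a > 0) a * ccc_loss_grad(y, fw$yhat) else rep(0, b)
  dlogits <- if (b_w > 0) {
    onehot <- matrix(0, b, cfg$n_classes)
    onehot[cbind(seq_len(b), cls + 1L)] <- 1
    b_w * (p - onehot) / b
  } else matrix(0, b, cfg$n_classes)
  grads <- backward_net(dyhat, dlogits, fw$cache, params, cfg)
  list(loss = loss, l_re = l_re, l_cl = l_cl,
       yhat = fw$yhat, probs = p, grads = grads)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), step = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  lr_t <- lr * sqrt(1 - beta2^state$step) / (1 - beta1^state$step)
  rec <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    list(p = p - lr_t * m2 / (sqrt(v2) + eps), m = m2, v = v2)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, step = state$step))
}
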