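test_that("positional encoding matches the sinusoidal definition", {
  pe <- positional_encoding(8L, 4L)
  expect_equal(pe[1L, c(1L, 3L)], c(0, 0))          # sin(0) at pos 0
  expect_equal(pe[1L, c(2L, 4L)], c(1, 1))          # cos(0) at pos 0
  expect_equal(pe[2L, 1L], sin(1), tolerance = 1e-12)
  expect_equal(pe[2L, 2L], cos(1), tolerance = 1e-12)
  expect_equal(pe[3L, 3L], sin(2 / 10000^(2 / 4)), tolerance = 1e-12)
  # odd width: unpaired last column uses the sine term
  pe5 <- positional_encoding(4L, 5L)
  expect_equal(pe5[2L, 5L], sin(1 / 10000^(4 / 5)), tolerance = 1e-12)
})

test_that("self-attention degenerates correctly for singleton and tied keys", {
  w <- attention_weights(4L, seed = 1L)
  x1 <- matrix(rnorm(4L), 1L, 4L)
  r1 <- self_attention(x1, w, return_attention = TRUE)
  expect_equal(r1$attention[[1L]][1L, 1L], 1)       # softmax of a singleton
  v <- sweep(x1 %*% w$Wv, 2L, w$bv, "+")
  expect_equal(r1$out, sweep(v %*% w$Wo, 2L, w$bo, "+"), tolerance = 1e-12)

  # identical rows: uniform attention, every output row the projected mean of V
  xr <- matrix(rep(rnorm(4L), each = 5L), 5L, 4L)
  rr <- self_attention(xr, w, return_attention = TRUE)
  expect_true(all(abs(rr$attention[[1L]] - 0.2) < 1e-12))
  expect_true(all(abs(sweep(rr$out, 2L, rr$out[1L, ])) < 1e-12))
})

test_that("self-attention matches a brute-force per-position oracle", {
  set.seed(42)
  X <- matrix(rnorm(12L), 3L, 4L)
  w <- attention_weights(4L, seed = 9L)
  expect_equal(self_attention(X, w), oracle_attention(X, w), tolerance = 1e-6)
})

test_that("attention rows sum to one for every head and input", {
  set.seed(5)
  for (h in c(1L, 2L, 4L)) {
    X <- matrix(rnorm(6L * 8L), 6L, 8L)
    r <- self_attention(X, attention_weights(8L), num_heads = h,
                        return_attention = TRUE)
    for (A in r$attention) {
      expect_equal(rowSums(A), rep(1, 6L), tolerance = 1e-12)
    }
  }
})

test_that("a full encoder layer matches the straight-line oracle", {
  set.seed(17)
  X <- matrix(rnorm(12L), 3L, 4L)
  enc <- init_encoder(4L, encoder_config(num_layers = 1L, num_heads = 1L,
                                         ff_hidden = 6L, dropout = 0),
                      seed = 3L)
  expect_equal(encoder_forward(X, enc),
               oracle_encoder_layer(X, enc$params$layers[[1L]]),
               tolerance = 1e-5)
})

test_that("encoder forward honours its shape and determinism contracts", {
  set.seed(2)
  enc <- init_encoder(6L, encoder_config(num_layers = 2L, ff_hidden = 8L,
                                         embed_dim = 5L), seed = 4L)
  X <- array(rnorm(3L * 7L * 6L), dim = c(3L, 7L, 6L))
  H1 <- encoder_forward(X, enc)
  H2 <- encoder_forward(X, enc)
  expect_identical(H1, H2)                           # eval mode, no dropout
  expect_equal(dim(H1), c(3L, 7L, 6L))
  # empty stack returns the positionally-encoded input
  enc0 <- init_encoder(6L, encoder_config(num_layers = 0L), seed = 4L)
  x <- matrix(rnorm(42L), 7L, 6L)
  expect_equal(encoder_forward(x, enc0), x + positional_encoding(7L, 6L))
})

test_that("input projection is applied when d_model differs from d", {
  enc <- init_encoder(3L, encoder_config(num_layers = 0L, d_model = 8L),
                      seed = 1L)
  x <- matrix(rnorm(15L), 5L, 3L)
  out <- encoder_forward(x, enc)
  expect_equal(dim(out), c(5L, 8L))
  proj <- sweep(x %*% enc$params$proj$W, 2L, enc$params$proj$b, "+")
  expect_equal(out, proj + positional_encoding(5L, 8L))
})

test_that("pure attention is permutation-equivariant; positional encoding is not", {
  set.seed(8)
  X <- matrix(rnorm(6L * 4L), 6L, 4L)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  w <- attention_weights(4L, seed = 2L)
  expect_equal(self_attention(X[perm, ], w), self_attention(X, w)[perm, ],
               tolerance = 1e-10)
  expect_equal(temporal_average(self_attention(X[perm, ], w)),
               temporal_average(self_attention(X, w)), tolerance = 1e-10)
  enc <- init_encoder(4L, encoder_config(num_layers = 1L, ff_hidden = 6L,
                                         dropout = 0), seed = 6L)
  expect_false(isTRUE(all.equal(
    temporal_average(encoder_forward(X[perm, ], enc)),
    temporal_average(encoder_forward(X, enc)))))
})

test_that("temporal averaging is the arithmetic mean over frames", {
  const <- array(rep(c(1, 2, 3, 4), each = 2L * 5L), dim = c(2L, 5L, 4L))
  expect_equal(temporal_average(const), matrix(rep(c(1, 2, 3, 4), each = 2L), 2L, 4L))
  one <- matrix(rnorm(4L), 1L, 4L)
  expect_equal(temporal_average(one), drop(one))
  two <- matrix(c(0, 2, 0, 2), 2L, 2L)
  expect_equal(temporal_average(two), c(1, 1))
})

test_that("embedding block is ReLU -> dropout -> linear with fixed width", {
  enc <- init_encoder(4L, encoder_config(num_layers = 1L, embed_dim = 7L),
                      seed = 5L)
  neg <- matrix(-abs(rnorm(8L)), 2L, 4L)
  out <- embedding_block(neg, enc)                   # ReLU zeroes everything
  expect_equal(out, matrix(enc$params$embed$b, 2L, 7L, byrow = TRUE))
  expect_equal(ncol(embedding_block(matrix(rnorm(12L), 3L, 4L), enc)), 7L)
  # eval mode: dropout is the identity
  x <- matrix(abs(rnorm(8L)), 2L, 4L)
  expect_identical(embedding_block(x, enc), embedding_block(x, enc))
})

test_that("task heads are independent and classification logits normalize", {
  enc <- init_encoder(4L, encoder_config(num_layers = 1L, embed_dim = 6L),
                      seed = 7L)
  e <- matrix(rnorm(12L), 2L, 6L)
  th <- task_heads(e, enc)
  expect_length(th$score, 2L)
  p <- exp(th$class_logits) / rowSums(exp(th$class_logits))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)
  # perturbing the classification head leaves the regression output unchanged
  enc2 <- enc
  enc2$params$cls$W <- enc2$params$cls$W + 1
  expect_identical(task_heads(e, enc2)$score, th$score)
  expect_false(identical(task_heads(e, enc2)$class_logits, th$class_logits))
  # zero embedding: outputs are the heads' biases
  z <- task_heads(matrix(0, 1L, 6L), enc)
  expect_equal(z$score, enc$params$reg$b)
  expect_equal(drop(z$class_logits), enc$params$cls$b)
})

test_that("network gradients are finite and match finite differences", {
  set.seed(10)
  cfg <- maft:::resolve_encoder_config(
    encoder_config(num_layers = 2L, num_heads = 2L, ff_hidden = 7L,
                   d_model = 4L, embed_dim = 5L, dropout = 0), 3L)
  params <- maft:::init_params(cfg)
  b <- 4L; t <- 5L
  M <- matrix(rnorm(b * t * 3L), b * t, 3L)
  y <- c(3, 10, 17, 22); cls <- bin_phq8(y)
  lg <- maft:::net_loss_grads(params, cfg, M, b, t, y, cls,
                              a = 0.9, b_w = 0.1, training = FALSE)
  leaves <- rapply(lg$grads, function(x) all(is.finite(x)), how = "unlist")
  expect_true(all(leaves))

  loss_of <- function(p) maft:::net_loss_grads(p, cfg, M, b, t, y, cls,
                                               0.9, 0.1, training = FALSE)$loss
  get_at <- function(p, path) purrr::reduce(path, `[[`, .init = p)
  set_at <- function(p, path, v) {
    if (length(path) == 1L) { p[[path[[1L]]]] <- v; return(p) }
    p[[path[[1L]]]] <- set_at(p[[path[[1L]]]], path[-1L], v)
    p
  }
  paths <- list(list("layers", 1L, "attn", "Wq"), list("layers", 2L, "ff", "W1"),
                list("layers", 1L, "ln1", "g"), list("proj", "W"),
                list("embed", "W"), list("reg", "W"), list("cls", "W"))
  h <- 1e-5
  for (path in paths) {
    leaf <- get_at(params, path)
    for (ei in c(1L, length(leaf))) {
      l <- leaf; l[ei] <- l[ei] + h
      p1 <- set_at(params, path, l)
      l <- leaf; l[ei] <- l[ei] - h
      p2 <- set_at(params, path, l)
      fd <- (loss_of(p1) - loss_of(p2)) / (2 * h)
      an <- get_at(lg$grads, path)[ei]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})
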