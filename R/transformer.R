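#' Transformer encoder configuration
#'
#' Architecture hyperparameters for the per-feature sequence encoder. The
#' defaults follow the original encoder convention: 6 layers, 1 attention
#' head, a 2048-unit feed-forward hidden layer, dropout 0.1. `d_model`
#' defaults to the input feature dimension (sequences are fed directly, no
#' input projection); setting it to another value inserts a learned linear
#' projection before positional encoding.
#'
#' @param num_layers Number of encoder layers (`>= 0`; 0 gives the
#'   positionally-encoded input back, useful for testing).
#' @param num_heads Number of attention heads; must divide `d_model`.
#' @param ff_hidden Hidden width of the position-wise feed-forward block.
#' @param d_model Model width; `NULL` (default) means "use the input dim".
#' @param dropout Dropout rate in `[0, 1)`, active only in training mode.
#' @param embed_dim Width of the shared subject embedding produced by the
#'   embedding FC block.
#' @param n_classes Number of severity classes for the classification head.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(num_layers = 6L, num_heads = 1L, ff_hidden = 2048L,
                           d_model = NULL, dropout = 0.1, embed_dim = 256L,
                           n_classes = 5L) {
  if (num_layers < 0L || num_heads < 1L || ff_hidden < 1L || embed_dim < 1L ||
      n_classes < 2L || dropout < 0 || dropout >= 1) {
    abort("Invalid encoder configuration.", class = "maft_error_value")
  }
  structure(list(num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 ff_hidden = as.integer(ff_hidden),
                 d_model = if (!is.null(d_model)) as.integer(d_model),
                 dropout = dropout, embed_dim = as.integer(embed_dim),
                 n_classes = as.integer(n_classes)),
            class = "encoder_config")
}

resolve_encoder_config <- function(cfg, input_dim) {
  cfg$input_dim <- as.integer(input_dim)
  cfg$d_model <- cfg$d_model %||% cfg$input_dim
  cfg$project <- cfg$d_model != cfg$input_dim
  if (cfg$d_model %% cfg$num_heads != 0L) {
    abort(sprintf("d_model (%d) must be divisible by num_heads (%d).",
                  cfg$d_model, cfg$num_heads), class = "maft_error_value")
  }
  cfg
}

#' Initialize an encoder with random parameters
#'
#' Weights use a uniform fan-in scheme (`U(-1/sqrt(n_in), 1/sqrt(n_in))`);
#' layer-norm gains start at 1 and shifts at 0.
#'
#' @param input_dim Dimension `d` of the input frames.
#' @param cfg An [encoder_config()].
#' @param seed Optional seed; when given, the caller's RNG state is untouched.
#' @return An object of class `maft_encoder` holding `cfg` and `params`.
#' @export
init_encoder <- function(input_dim, cfg = encoder_config(), seed = NULL) {
  cfg <- resolve_encoder_config(cfg, input_dim)
  params <- with_seed(seed, init_params(cfg))
  structure(list(cfg = cfg, params = params), class = "maft_encoder")
}

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d_model))` and entry
#' `(pos, 2i+1)` is `cos(pos / 10000^(2i/d_model))` with `pos` and `i`
#' zero-based; for odd `d_model` the final unpaired column uses the sine
#' term. The matrix is added elementwise to the (projected) input before the
#' first encoder layer.
#'
#' @param t Number of frames.
#' @param d_model Model width.
#' @return A `t x d_model` matrix.
#' @export
positional_encoding <- function(t, d_model) {
  if (t < 1L || d_model < 1L) {
    abort("t and d_model must be positive.", class = "maft_error_value")
  }
  pe_matrix(t, d_model)
}

#' Random attention weights for a given model width
#'
#' Convenience constructor for the Q/K/V/output projection maps used by
#' [self_attention()], drawn with the same fan-in scheme as [init_encoder()].
#'
#' @param d_model Model width.
#' @param seed Optional seed.
#' @return Named list `Wq, bq, Wk, bk, Wv, bv, Wo, bo`.
#' @export
attention_weights <- function(d_model, seed = NULL) {
  with_seed(seed, {
    q <- linear_init(d_model, d_model); k <- linear_init(d_model, d_model)
    v <- linear_init(d_model, d_model); o <- linear_init(d_model, d_model)
    list(Wq = q$W, bq = q$b, Wk = k$W, bk = k$b,
         Wv = v$W, bv = v$b, Wo = o$W, bo = o$b)
  })
}

#' Scaled dot-product self-attention
#'
#' Projects the input to queries, keys and values, forms the row-stochastic
#' attention matrix `softmax(Q K' / sqrt(d_k))` per head, applies it to the
#' values, concatenates heads and applies the output projection.
#'
#' @param X A `t x d_model` numeric matrix (one sequence).
#' @param weights Projection maps as from [attention_weights()].
#' @param num_heads Number of heads; must divide `d_model`.
#' @param return_attention If `TRUE`, also return the per-head attention
#'   matrices.
#' @return A `t x d_model` matrix, or a list `(out, attention)` when
#'   `return_attention = TRUE`.
#' @export
self_attention <- function(X, weights, num_heads = 1L, return_attention = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) {
    abort("Attention input must be finite.", class = "maft_error_nonfinite")
  }
  if (ncol(X) %% num_heads != 0L || ncol(weights$Wq) != ncol(X)) {
    abort("Weight shapes inconsistent with input width / head count.",
          class = "maft_error_value")
  }
  f <- fwd_attn(X, b = 1L, t = nrow(X), w = weights, h = as.integer(num_heads))
  if (return_attention) list(out = f$out, attention = f$cache$A[[1L]])
  else f$out
}

as_big_matrix <- function(X) {
  if (is.matrix(X)) {
    list(M = X, b = 1L, t = nrow(X), array = FALSE)
  } else if (is.array(X) && length(dim(X)) == 3L) {
    d <- dim(X)
    list(M = matrix(aperm(X, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L]),
         b = d[1L], t = d[2L], array = TRUE)
  } else {
    abort("Input must be a t x d matrix or a b x t x d array.",
          class = "maft_error_value")
  }
}

from_big_matrix <- function(M, b, t, as_array) {
  if (!as_array) return(M)
  aperm(array(M, dim = c(t, b, ncol(M))), c(2L, 1L, 3L))
}

#' Run the encoder stack
#'
#' Applies the optional input projection, adds the positional encoding once,
#' then runs `num_layers` encoder layers (self-attention and feed-forward,
#' each wrapped in residual-add plus layer normalization, post-norm).
#' Dropout is active only in `"train"` mode, so `"eval"` mode is
#' deterministic.
#'
#' @param X A `t x d` matrix or a `b x t x d` array of input sequences.
#' @param encoder A [init_encoder()] object (or a fitted model's encoder).
#' @param mode `"eval"` (default) or `"train"`.
#' @return Encoded sequences with the input's shape and width `d_model`.
#' @export
encoder_forward <- function(X, encoder, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  bm <- as_big_matrix(X)
  fw <- forward_encoder_only(encoder$params, encoder$cfg, bm$M, bm$b, bm$t,
                             training = mode == "train")
  from_big_matrix(fw, bm$b, bm$t, bm$array)
}

# encoder stack only (no pooling/heads); shares fwd_layer with training
forward_encoder_only <- function(params, cfg, M, b, t, training = FALSE) {
  if (cfg$project) M <- addb(M %*% params$proj$W, params$proj$b)
  M <- M + pe_matrix(t, cfg$d_model)[rep(seq_len(t), times = b), , drop = FALSE]
  for (l in seq_len(cfg$num_layers)) {
    M <- fwd_layer(M, b, t, params$layers[[l]], cfg$num_heads,
                   cfg$dropout, training, l)$out
  }
  M
}

#' Average encoded frames over time
#'
#' @param H A `t x d` matrix (one sequence) or `b x t x d` array.
#' @return A length-`d` vector, or a `b x d` matrix for array input.
#' @export
temporal_average <- function(H) {
  if (is.matrix(H)) return(colMeans(H))
  bm <- as_big_matrix(H)
  out <- rowsum(bm$M, group = rep(seq_len(bm$b), each = bm$t),
                reorder = FALSE) / bm$t
  dimnames(out) <- NULL
  out
}

#' Embedding FC block
#'
#' ReLU, then dropout (train mode only), then a linear map to `embed_dim`:
#' produces the fixed-width subject embedding shared by the two task heads.
#'
#' @param v A `b x d_model` matrix (or length-`d_model` vector) of pooled
#'   encoder outputs.
#' @param encoder A [init_encoder()] object.
#' @param mode `"eval"` (default) or `"train"`.
#' @return A `b x embed_dim` matrix.
#' @export
embedding_block <- function(v, encoder, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  v <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  R <- relu(v)
  if (mode == "train" && encoder$cfg$dropout > 0) {
    R <- R * new_mask(nrow(R), ncol(R), encoder$cfg$dropout)
  }
  addb(R %*% encoder$params$embed$W, encoder$params$embed$b)
}

#' Task heads
#'
#' Two independent FC blocks (ReLU, dropout, linear) on the shared embedding:
#' a regression head emitting the predicted PHQ-8 score and a classification
#' head emitting severity-class logits.
#'
#' @param e A `b x embed_dim` matrix (or vector) of embeddings.
#' @param encoder A [init_encoder()] object.
#' @param mode `"eval"` (default) or `"train"`.
#' @return List with `score` (length-`b` vector) and `class_logits`
#'   (`b x n_classes` matrix).
#' @export
task_heads <- function(e, encoder, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  e <- if (is.matrix(e)) e else matrix(e, nrow = 1L)
  R <- relu(e)
  drop_it <- function(x) {
    if (mode == "train" && encoder$cfg$dropout > 0)
      x * new_mask(nrow(x), ncol(x), encoder$cfg$dropout)
    else x
  }
  list(score = drop(addb(drop_it(R) %*% encoder$params$reg$W,
                         encoder$params$reg$b)),
       class_logits = addb(drop_it(R) %*% encoder$params$cls$W,
                           encoder$params$cls$b))
}
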