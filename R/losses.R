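#' Concordance correlation coefficient
#'
#' Lin's agreement measure between true and predicted scores,
#' `2 S_xy / (S_x^2 + S_y^2 + (mean(x) - mean(y))^2)`, using population
#' moments (divide by `n`). It combines Pearson correlation with penalties
#' for mean and variance bias; 1 is perfect agreement, -1 perfect
#' disagreement, 0 no agreement.
#'
#' @param y Numeric vector of true scores.
#' @param y_hat Numeric vector of predicted scores, same length.
#' @param undefined What to do when both vectors are constant and equal, where
#'   the coefficient is 0/0: `"error"` (default) or `"one"` (return 1 with a
#'   warning, treating identical constants as perfect agreement).
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' ccc(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)) # 1
ccc <- function(y, y_hat, undefined = c("error", "one")) {
  undefined <- match.arg(undefined)
  if (length(y) != length(y_hat)) {
    abort("y and y_hat must have the same length.", class = "maft_error_value")
  }
  if (length(y) < 2L) {
    abort("CCC needs at least two observations.", class = "maft_error_value")
  }
  my <- mean(y); mh <- mean(y_hat)
  vy <- mean((y - my)^2); vh <- mean((y_hat - mh)^2)
  cov <- mean((y - my) * (y_hat - mh))
  denom <- vy + vh + (mh - my)^2
  if (denom == 0) {
    if (undefined == "one") {
      warn("CCC undefined for identical constant vectors; returning 1.")
      return(1)
    }
    abort("CCC undefined: both vectors constant and equal.",
          class = "maft_error_undefined")
  }
  2 * cov / denom
}

#' Concordance correlation loss
#'
#' `1 - CCC(y, y_hat)` with a small `eps` added to the denominator for
#' numerical stability, so the loss is defined (and differentiable) even for
#' a degenerate constant batch. Range `[0, 2]`: 0 at perfect agreement, 2 at
#' perfect disagreement.
#'
#' @inheritParams ccc
#' @param eps Stabilizer added to the denominator (default `1e-12`).
#' @return A single non-negative number.
#' @export
ccc_loss <- function(y, y_hat, eps = 1e-12) {
  if (length(y) != length(y_hat) || length(y) < 2L) {
    abort("y and y_hat must have equal length >= 2.", class = "maft_error_value")
  }
  my <- mean(y); mh <- mean(y_hat)
  vy <- mean((y - my)^2); vh <- mean((y_hat - mh)^2)
  cov <- mean((y - my) * (y_hat - mh))
  1 - 2 * cov / (vy + vh + (mh - my)^2 + eps)
}

# analytic gradient of ccc_loss w.r.t. y_hat
ccc_loss_grad <- function(y, y_hat, eps = 1e-12) {
  n <- length(y)
  my <- mean(y); mh <- mean(y_hat)
  vy <- mean((y - my)^2); vh <- mean((y_hat - mh)^2)
  cov <- mean((y - my) * (y_hat - mh))
  D <- vy + vh + (mh - my)^2 + eps
  dcov <- (y - my) / n
  dvh <- 2 * (y_hat - mh) / n
  dmd <- 2 * (mh - my) / n
  -(2 * dcov * D - 2 * cov * (dvh + dmd)) / D^2
}

#' Cross-entropy loss for severity classification
#'
#' Mean negative log-probability of the true class,
#' `-(1/N) sum_i log p[i, y_i]`. Accepts either class probabilities (rows
#' summing to 1, clipped at `eps` before the log) or raw logits, which are
#' normalized internally through a numerically stable log-sum-exp.
#'
#' @param x Numeric `n x C` matrix of class probabilities or logits.
#' @param labels Integer vector of class labels in `0:(C-1)`.
#' @param logits If `TRUE`, `x` holds unnormalized logits.
#' @param eps Probability floor used when `logits = FALSE` (default `1e-12`).
#' @return A single non-negative number.
#' @export
cross_entropy <- function(x, labels, logits = FALSE, eps = 1e-12) {
  x <- as.matrix(x)
  n <- nrow(x); C <- ncol(x)
  labels <- as.integer(labels)
  if (length(labels) != n) {
    abort("One label per row required.", class = "maft_error_value")
  }
  if (any(labels < 0L | labels >= C)) {
    abort(sprintf("Labels must lie in 0..%d.", C - 1L), class = "maft_error_value")
  }
  if (logits) {
    m <- apply(x, 1L, max)
    lse <- m + log(rowSums(exp(x - m)))
    logp <- x[cbind(seq_len(n), labels + 1L)] - lse
  } else {
    logp <- log(pmax(x[cbind(seq_len(n), labels + 1L)], eps))
  }
  -mean(logp)
}

#' Combined multi-task loss
#'
#' `a * L_re + b * L_cl`: the CCC regression loss weighted by `a` plus the
#' classification cross-entropy weighted by `b`. The conventional settings
#' are `a = 1, b = 0` (single-task regression) and `a = 0.9, b = 0.1`
#' (multi-task).
#'
#' @inheritParams ccc
#' @param probs `n x 5` class probability matrix (or logits, see `logits`).
#' @param labels Integer severity classes in `0:4`.
#' @param a,b Non-negative task weights, not both zero.
#' @param logits Passed to [cross_entropy()].
#' @return A single number.
#' @export
multitask_loss <- function(y, y_hat, probs, labels, a = 0.9, b = 0.1,
                           logits = FALSE) {
  if (a < 0 || b < 0 || (a == 0 && b == 0)) {
    abort("Task weights must be non-negative and not both zero.",
          class = "maft_error_value")
  }
  l_re <- if (a > 0) ccc_loss(y, y_hat) else 0
  l_cl <- if (b > 0) cross_entropy(probs, labels, logits = logits) else 0
  a * l_re + b * l_cl
}

#' Root mean square error
#'
#' @inheritParams ccc
#' @return A single non-negative number.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1L) {
    abort("y and y_hat must have equal positive length.", class = "maft_error_value")
  }
  sqrt(mean((y - y_hat)^2))
}

# row-wise softmax with max subtraction
row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}
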