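align_prediction_sets <- function(preds) {
  if (length(preds) < 1L) {
    abort("Need at least one prediction set.", class = "maft_error_empty")
  }
  stopifnot(all(vapply(preds, inherits, logical(1), "maft_predictions")))
  ids <- preds[[1L]]$subject_id
  for (p in preds[-1L]) {
    if (!setequal(p$subject_id, ids) || length(p$subject_id) != length(ids)) {
      off <- c(setdiff(ids, p$subject_id), setdiff(p$subject_id, ids))
      abort(sprintf("Prediction sets disagree on subjects: %s",
                    paste(unique(off), collapse = ", ")),
            class = "maft_error_alignment")
    }
  }
  keep <- c("feature_name", "validation_ccc", "validation_rmse")
  lapply(preds, function(p) {
    q <- p[match(ids, p$subject_id), , drop = FALSE]
    attributes(q)[keep] <- attributes(p)[keep]
    class(q) <- class(p)
    q
  })
}

fusion_result <- function(ids, fused, weights_tbl, strategy, m) {
  structure(list(
    scores = tibble(subject_id = ids, prediction = fused),
    weights = weights_tbl, strategy = strategy, m = m
  ), class = "maft_fusion")
}

#' Averaged late fusion
#'
#' The plain decision-level ensemble: the fused PHQ-8 prediction for each
#' subject is the arithmetic mean of the per-feature predictions, i.e. every
#' feature gets weight `1/M`.
#'
#' @param preds List of [prediction_set()]s over the same subjects.
#' @return An object of class `maft_fusion` with per-subject fused scores
#'   and the weight table.
#' @export
averaged_fusion <- function(preds) {
  preds <- align_prediction_sets(preds)
  S <- vapply(preds, `[[`, numeric(nrow(preds[[1L]])), "prediction")
  S <- matrix(S, nrow = nrow(preds[[1L]]))
  fusion_result(
    preds[[1L]]$subject_id, rowMeans(S),
    tibble(feature_name = vapply(preds, feature_name, character(1)),
           ccc = vapply(preds, validation_ccc, numeric(1)),
           weight = rep(1 / length(preds), length(preds))),
    strategy = "averaged", m = length(preds))
}

#' Adaptive CCC-weighted late fusion
#'
#' Weights each feature's predictions by its validation CCC normalized by
#' the sum of CCCs, so better-validated features dominate the fused score.
#' Negative CCCs are clamped to zero before normalization (a feature that
#' disagrees with the labels should not vote, and unclamped negative weights
#' would flip its sign).
#'
#' @param preds List of [prediction_set()]s over the same subjects, each
#'   carrying a validation CCC; at least one must be positive.
#' @return An object of class `maft_fusion`.
#' @export
adaptive_fusion <- function(preds) {
  preds <- align_prediction_sets(preds)
  cccs <- vapply(preds, validation_ccc, numeric(1))
  if (anyNA(cccs)) {
    abort("Every prediction set needs a validation CCC.", class = "maft_error_value")
  }
  w <- pmax(cccs, 0)
  if (sum(w) <= 0) {
    abort("All validation CCCs are <= 0; adaptive weights are undefined.",
          class = "maft_error_value")
  }
  w <- w / sum(w)
  S <- vapply(preds, `[[`, numeric(nrow(preds[[1L]])), "prediction")
  S <- matrix(S, nrow = nrow(preds[[1L]]))
  fusion_result(
    preds[[1L]]$subject_id, drop(S %*% w),
    tibble(feature_name = vapply(preds, feature_name, character(1)),
           ccc = cccs, weight = w),
    strategy = "adaptive", m = length(preds))
}

#' Keep the top-M prediction sets by validation CCC
#'
#' Ranks the feature models by their validation CCC (ties broken by
#' lexicographically smaller feature name) and keeps the best `m`, so
#' poorly-validated features can be excluded before fusion.
#'
#' @param preds List of [prediction_set()]s.
#' @param m Number of sets to keep, `1 <= m <= length(preds)`.
#' @return The selected prediction sets, in decreasing CCC order.
#' @export
select_top_m <- function(preds, m) {
  if (m < 1L || m > length(preds)) {
    abort(sprintf("m must lie in 1..%d.", length(preds)),
          class = "maft_error_value")
  }
  cccs <- vapply(preds, validation_ccc, numeric(1))
  nms <- vapply(preds, feature_name, character(1))
  ord <- order(-cccs, nms)
  preds[ord[seq_len(m)]]
}

#' @export
print.maft_fusion <- function(x, ...) {
  cat(sprintf("<maft_fusion> %s fusion of %d feature(s), %d subject(s)\n",
              x$strategy, x$m, nrow(x$scores)))
  print(x$weights)
  invisible(x)
}
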