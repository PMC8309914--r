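#' Segment-based frame sampling specification
#'
#' Long frame streams are shortened to a fixed budget of `n_frames` frames by
#' splitting the stream evenly into `segments` contiguous segments and drawing
#' a run of `n_frames / segments` successive frames from each, preserving
#' order. This keeps frames from the whole recording while bounding memory.
#'
#' @param n_frames Target number of frames `N` after sampling.
#' @param segments Number of segments `s` (must satisfy `s <= N`).
#' @param seed Optional integer; when given, sampling is performed under this
#'   seed and the caller's RNG state is untouched.
#' @param pad If `TRUE` (default) sequences shorter than `n_frames` are
#'   repeat-padded cyclically before sampling; if `FALSE` such inputs error.
#' @return An object of class `sampling_spec`.
#' @export
sampling_spec <- function(n_frames, segments, seed = NULL, pad = TRUE) {
  n_frames <- as.integer(n_frames); segments <- as.integer(segments)
  if (n_frames < 1L || segments < 1L || segments > n_frames) {
    abort("Need 1 <= segments <= n_frames.", class = "maft_error_value")
  }
  structure(list(n_frames = n_frames, segments = segments, seed = seed,
                 pad = isTRUE(pad)),
            class = "sampling_spec")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a fixed number of frames by segments
#'
#' Splits the sequence into `s` contiguous segments covering it in order, and
#' from segment `k` draws `L_k` successive frames starting at a uniformly
#' random offset (`L_k = floor(N/s)`, with the remainder spread one frame at a
#' time over the leading segments). The `s` runs are concatenated, so the
#' output is a length-`N` order-preserving subsequence of the input built from
#' `s` consecutive runs.
#'
#' @param seq A [feature_sequence()].
#' @param spec A [sampling_spec()].
#' @return A [feature_sequence()] with exactly `spec$n_frames` frames. The
#'   original frame indices drawn are attached as attribute `"indices"`.
#' @export
segment_sample <- function(seq, spec) {
  stopifnot(inherits(seq, "feature_sequence"), inherits(spec, "sampling_spec"))
  t <- nrow(seq$frames); N <- spec$n_frames; s <- spec$segments
  frames <- seq$frames
  if (t < N) {
    if (!spec$pad) {
      abort(sprintf("Sequence has %d frames but %d requested and padding is off.",
                    t, N), class = "maft_error_length")
    }
    idx_pad <- ((seq_len(N) - 1L) %% t) + 1L
    frames <- frames[idx_pad, , drop = FALSE]
    t <- N
  }
  # even segment boundaries; remainder frames go to the leading segments
  seg_len <- rep(t %/% s, s) + c(rep(1L, t %% s), rep(0L, s - t %% s))
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L
  L <- rep(N %/% s, s) + c(rep(1L, N %% s), rep(0L, s - N %% s))
  idx <- with_seed(spec$seed, {
    unlist(lapply(seq_len(s), function(k) {
      lk <- L[k]
      if (seg_len[k] >= lk) {
        start <- seg_start[k] + sample.int(seg_len[k] - lk + 1L, 1L) - 1L
        start:(start + lk - 1L)
      } else {
        # degenerate short segment: take it all, repeat the last frame
        run <- seg_start[k]:seg_end[k]
        c(run, rep(seg_end[k], lk - length(run)))
      }
    }))
  })
  out <- feature_sequence(frames[idx, , drop = FALSE], seq$feature_name, seq$level)
  attr(out, "indices") <- idx
  out
}

#' Sliding-window functional feature specification
#'
#' @param window Window length in frames (default 100).
#' @param hop Hop between window starts in frames (default 25).
#' @param target_len Output sequence length after nearest-index resampling
#'   (default 1768, the conventional functional-feature length).
#' @return An object of class `functional_spec`.
#' @export
functional_spec <- function(window = 100L, hop = 25L, target_len = 1768L) {
  window <- as.integer(window); hop <- as.integer(hop)
  target_len <- as.integer(target_len)
  if (window < 1L || hop < 1L || target_len < 1L) {
    abort("window, hop and target_len must be positive.", class = "maft_error_value")
  }
  structure(list(window = window, hop = hop, target_len = target_len),
            class = "functional_spec")
}

#' Derive functional (mean/sd) features from a frame stream
#'
#' Per sliding window, emits the per-dimension mean and population standard
#' deviation concatenated (output dimension `2 d`), then resamples the window
#' sequence to exactly `target_len` rows by nearest-index selection. When the
#' native window count already equals `target_len` no resampling happens.
#'
#' @param seq A [feature_sequence()].
#' @param spec A [functional_spec()].
#' @param name Name for the derived feature; defaults to
#'   `"<feature_name>_functional"`.
#' @param level Level tag for the derived feature; defaults to the input's.
#' @return A [feature_sequence()] of shape `target_len x 2d`.
#' @export
compute_functionals <- function(seq, spec = functional_spec(),
                                name = paste0(seq$feature_name, "_functional"),
                                level = seq$level) {
  stopifnot(inherits(seq, "feature_sequence"), inherits(spec, "functional_spec"))
  t <- nrow(seq$frames); d <- ncol(seq$frames)
  if (t < spec$window) {
    abort(sprintf("Sequence length %d is shorter than window %d.", t, spec$window),
          class = "maft_error_window")
  }
  starts <- seq.int(1L, t - spec$window + 1L, by = spec$hop)
  n_win <- length(starts)
  fun <- matrix(0, n_win, 2L * d)
  for (i in seq_len(n_win)) {
    w <- seq$frames[starts[i]:(starts[i] + spec$window - 1L), , drop = FALSE]
    mu <- colMeans(w)
    sd_pop <- sqrt(colMeans(w^2) - mu^2)
    fun[i, ] <- c(mu, sd_pop)
  }
  fun[fun < 0 & fun > -1e-12] <- 0  # clamp tiny negative variances
  if (n_win != spec$target_len) {
    sel <- pmin(pmax(round(seq(1L, n_win, length.out = spec$target_len)), 1L), n_win)
    fun <- fun[sel, , drop = FALSE]
  }
  feature_sequence(fun, feature_name = name, level = level)
}

#' Fit per-dimension z-score statistics on training sequences
#'
#' Statistics are computed over the pooled frames of the training sequences
#' only (population standard deviation, floored at `eps`), so held-out data is
#' always transformed with training-set statistics.
#'
#' @param train List of [feature_sequence()] objects (same dimension).
#' @param eps Floor applied to the standard deviation (default `1e-8`).
#' @return A list with `center` and `scale` vectors of length `d`.
#' @export
zscore_fit <- function(train, eps = 1e-8) {
  if (length(train) == 0L) {
    abort("Need at least one training sequence.", class = "maft_error_empty")
  }
  all_frames <- do.call(rbind, lapply(train, `[[`, "frames"))
  center <- colMeans(all_frames)
  scale <- sqrt(colMeans(all_frames^2) - center^2)
  list(center = center, scale = pmax(scale, eps))
}

#' Apply z-score statistics to sequences
#'
#' @param seqs List of [feature_sequence()] objects, or a single one.
#' @param stats Statistics from [zscore_fit()].
#' @return Transformed sequence(s), same shape as the input.
#' @export
zscore_apply <- function(seqs, stats) {
  one <- inherits(seqs, "feature_sequence")
  if (one) seqs <- list(seqs)
  out <- lapply(seqs, function(s) {
    f <- sweep(sweep(s$frames, 2L, stats$center, "-"), 2L, stats$scale, "/")
    feature_sequence(f, s$feature_name, s$level)
  })
  if (one) out[[1L]] else out
}

#' Normalize held-out sequences with training-set statistics
#'
#' @inheritParams zscore_fit
#' @param apply_to Optional list of held-out sequences transformed with the
#'   training statistics.
#' @return List with `train` (normalized training sequences), `transformed`
#'   (normalized `apply_to`, or `NULL`), and the `center`/`scale` used.
#' @export
zscore_normalize <- function(train, apply_to = NULL, eps = 1e-8) {
  stats <- zscore_fit(train, eps = eps)
  list(train = zscore_apply(train, stats),
       transformed = if (!is.null(apply_to)) zscore_apply(apply_to, stats),
       center = stats$center, scale = stats$scale)
}
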