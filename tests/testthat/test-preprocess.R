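seq_of <- function(t, d = 2L, name = "x", level = "low") {
  feature_sequence(matrix(seq_len(t * d), t, d), name, level)
}

test_that("segment sampling draws consecutive runs from ordered segments", {
  fs <- seq_of(100L)
  out <- segment_sample(fs, sampling_spec(10L, 5L, seed = 11L))
  idx <- attr(out, "indices")
  expect_length(idx, 10L)
  expect_equal(nrow(out$frames), 10L)
  for (k in 1:5) {
    block <- idx[(2L * k - 1L):(2L * k)]
    expect_equal(diff(block), 1L)                 # consecutive within block
    expect_true(all(block >= 20L * (k - 1L) + 1L & block <= 20L * k))
  }
  expect_equal(out$frames, fs$frames[idx, ])      # subsequence of the input
})

test_that("t = N with one segment returns the sequence unchanged", {
  fs <- seq_of(16L)
  out <- segment_sample(fs, sampling_spec(16L, 1L, seed = 1L))
  expect_identical(out$frames, fs$frames)
  expect_identical(attr(out, "indices"), 1:16)
})

test_that("segment sampling is deterministic in the seed", {
  fs <- seq_of(50L)
  a <- segment_sample(fs, sampling_spec(10L, 5L, seed = 7L))
  b <- segment_sample(fs, sampling_spec(10L, 5L, seed = 7L))
  expect_identical(a$frames, b$frames)
  c3 <- segment_sample(fs, sampling_spec(10L, 5L, seed = 8L))
  expect_false(identical(attr(a, "indices"), attr(c3, "indices")))
})

test_that("sampling pads short sequences cyclically or errors when disabled", {
  fs <- seq_of(5L)
  out <- segment_sample(fs, sampling_spec(12L, 3L, seed = 2L))
  expect_equal(nrow(out$frames), 12L)
  expect_true(all(out$frames[, 1L] %in% fs$frames[, 1L]))
  expect_error(segment_sample(fs, sampling_spec(12L, 3L, pad = FALSE)),
               class = "maft_error_length")
})

test_that("non-divisible budgets spread the remainder over leading segments", {
  fs <- seq_of(60L)
  out <- segment_sample(fs, sampling_spec(10L, 4L, seed = 5L))
  idx <- attr(out, "indices")
  expect_length(idx, 10L)
  # blocks of length 3,3,2,2; starts strictly increasing across blocks
  lens <- c(3L, 3L, 2L, 2L)
  starts <- cumsum(c(1L, head(lens, -1L)))
  block_first <- idx[starts]
  expect_true(all(diff(block_first) > 0L))
  for (k in seq_along(lens)) {
    block <- idx[starts[k]:(starts[k] + lens[k] - 1L)]
    expect_true(all(diff(block) == 1L))
  }
})

test_that("functional features hold window means and population sds", {
  fs <- feature_sequence(matrix(c(1, 2, 3), 3, 1), "x", "low")
  out <- compute_functionals(fs, functional_spec(window = 3L, hop = 1L,
                                                 target_len = 1L))
  expect_equal(out$frames[1L, 1L], 2)
  expect_equal(out$frames[1L, 2L], sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(out$feature_name, "x_functional")

  const <- feature_sequence(matrix(4.2, 20L, 3L), "c", "low")
  fo <- compute_functionals(const, functional_spec(window = 5L, hop = 5L,
                                                   target_len = 4L))
  expect_true(all(fo$frames[, 1:3] == 4.2))   # means
  expect_true(all(fo$frames[, 4:6] == 0))     # sds
})

test_that("functional output length is exactly target_len, resampled or not", {
  fs <- seq_of(200L, d = 3L)
  # native window count (200-20)/10+1 = 19 == target_len: no resampling
  native <- compute_functionals(fs, functional_spec(20L, 10L, target_len = 19L))
  expect_equal(nrow(native$frames), 19L)
  starts <- seq(1L, 181L, by = 10L)
  direct <- t(vapply(starts, function(s) {
    w <- fs$frames[s:(s + 19L), , drop = FALSE]
    c(colMeans(w), sqrt(colMeans(w^2) - colMeans(w)^2))
  }, numeric(6L)))
  expect_equal(native$frames, direct, tolerance = 1e-12)
  for (tl in c(5L, 19L, 50L)) {
    out <- compute_functionals(fs, functional_spec(20L, 10L, target_len = tl))
    expect_equal(nrow(out$frames), tl)
    expect_true(all(is.finite(out$frames)))
  }
  expect_error(compute_functionals(seq_of(5L), functional_spec(10L, 1L)),
               class = "maft_error_window")
})

test_that("z-scoring uses training statistics only", {
  set.seed(1)
  train <- lapply(1:3, function(i)
    feature_sequence(matrix(rnorm(40L, mean = 5, sd = 2), 20L, 2L), "x", "low"))
  held <- feature_sequence(matrix(rnorm(20L, mean = 50), 10L, 2L), "x", "low")
  res <- zscore_normalize(train, list(held))
  pooled <- do.call(rbind, lapply(res$train, `[[`, "frames"))
  expect_equal(colMeans(pooled), c(0, 0), tolerance = 1e-10)
  expect_equal(sqrt(colMeans(pooled^2)), c(1, 1), tolerance = 1e-10)
  # held-out transformed with train stats, not its own
  expect_equal(res$transformed[[1L]]$frames,
               sweep(sweep(held$frames, 2L, res$center), 2L, res$scale, "/"))
  expect_gt(mean(res$transformed[[1L]]$frames), 5)
})

test_that("constant dimensions map to zero under the sd floor", {
  train <- list(feature_sequence(cbind(rep(3, 10L), rnorm(10L)), "x", "low"))
  res <- zscore_normalize(train)
  expect_true(all(res$train[[1L]]$frames[, 1L] == 0))
  expect_error(zscore_fit(list()), class = "maft_error_empty")
})
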