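test_that("training is bit-reproducible under a fixed seed", {
  co <- tiny_cohort()
  run <- function() {
    train_feature_model(co$train, co$dev, "f_sig",
                        enc_cfg = encoder_config(num_layers = 1L,
                                                 ff_hidden = 8L,
                                                 embed_dim = 6L),
                        train_cfg = train_config(learning_rate = 1e-3,
                                                 epochs = 15L, batch_size = 8L,
                                                 n_frames = 16L, segments = 4L,
                                                 seed = 5L))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$encoder$params, m2$encoder$params)
  expect_identical(m1$predictions$prediction, m2$predictions$prediction)
  expect_identical(m1$history, m2$history)
})

test_that("loss weights change the optimization trajectory", {
  co <- tiny_cohort()
  fit <- function(a, b) {
    train_feature_model(co$train, co$dev, "f_sig",
                        enc_cfg = encoder_config(num_layers = 1L,
                                                 ff_hidden = 8L,
                                                 embed_dim = 6L),
                        train_cfg = train_config(learning_rate = 1e-3,
                                                 epochs = 5L, batch_size = 8L,
                                                 n_frames = 16L, segments = 4L,
                                                 seed = 5L, a = a, b = b))
  }
  single <- fit(1, 0)
  multi <- fit(0.9, 0.1)
  expect_false(identical(single$encoder$params, multi$encoder$params))
  # single-task: the classification objective never enters the loss
  expect_equal(single$history$loss_classification, rep(0, 5L))
})

test_that("training loss decreases over the toy run", {
  r <- toy_replicate(1L)
  h <- r$models$strong$history
  n <- nrow(h)
  first <- h$loss[seq_len(ceiling(n / 10))]
  last <- h$loss[(n - ceiling(n / 10) + 1L):n]
  expect_lt(stats::median(last), stats::median(first))
})

test_that("evaluation is deterministic and validates its inputs", {
  r <- toy_replicate(1L)
  model <- r$models$strong
  dev <- r$cohort$dev
  p1 <- evaluate_model(model, dev, seed = 2L)
  p2 <- evaluate_model(model, dev, seed = 2L)
  expect_identical(p1$prediction, p2$prediction)
  expect_identical(validation_ccc(p1), validation_ccc(p2))
  expect_error(evaluate_model(model, list()), class = "maft_error_empty")
  # dimension mismatch against the checkpoint
  wrong <- tiny_cohort()$dev
  expect_error(suppressWarnings(evaluate_model(model, wrong)),
               class = "maft_error_value")
})

test_that("training on the training split does not crash and overfits sanely", {
  r <- toy_replicate(1L)
  p_tr <- evaluate_model(r$models$strong, r$cohort$train, seed = 2L)
  expect_s3_class(p_tr, "maft_predictions")
  expect_true(is.finite(validation_ccc(p_tr)))
})

test_that("subjects missing the feature are excluded with a warning", {
  co <- tiny_cohort()
  co$train[[1L]]$features$f_sig <- NULL
  expect_warning(
    m <- train_feature_model(co$train, co$dev, "f_sig",
                             enc_cfg = encoder_config(num_layers = 1L,
                                                      ff_hidden = 8L,
                                                      embed_dim = 6L),
                             train_cfg = train_config(learning_rate = 1e-3,
                                                      epochs = 2L,
                                                      batch_size = 8L,
                                                      n_frames = 16L,
                                                      segments = 4L, seed = 1L)),
    "Excluding")
  expect_s3_class(m, "maft_model")
  bad <- lapply(co$train, function(s) { s$features$f_sig <- NULL; s })
  expect_error(train_feature_model(bad, co$dev, "f_sig"),
               class = "maft_error_value")
})

test_that("checkpoints round-trip through save and load", {
  r <- toy_replicate(1L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(r$models$strong, path)
  back <- load_checkpoint(path)
  expect_identical(back$encoder$params, r$models$strong$encoder$params)
  expect_identical(back$norm, r$models$strong$norm)
})

test_that("tidiers and plots expose the fit", {
  r <- toy_replicate(1L)
  m <- r$models$strong
  td <- tidy(m)
  expect_true(all(c("epoch", "loss", "dev_ccc") %in% names(td)))
  expect_equal(nrow(td), m$train_cfg$epochs)
  gl <- glance(m)
  expect_equal(gl$feature_name, "acoustic_lld")
  expect_equal(gl$dev_ccc, validation_ccc(m$predictions))
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(m$predictions), "ggplot")
  expect_equal(glance(m$predictions)$n, nrow(m$predictions))
})
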