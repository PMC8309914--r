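# Desk-scale study conditions: the default synthetic cohort (train 40 /
# dev 16, strong-signal + medium-signal + pure-noise features) and a small
# 2-layer encoder trained for 200 epochs at a learning rate matched to the
# toy problem size. Replicate runs are memoised so several test files can
# share them.

toy_encoder <- function() {
  encoder_config(num_layers = 2L, ff_hidden = 64L, embed_dim = 32L)
}

toy_train_cfg <- function(seed, epochs = 200L) {
  train_config(learning_rate = 1e-3, epochs = epochs, batch_size = 48L,
               n_frames = 32L, segments = 4L, seed = seed)
}

toy_features <- c(strong = "acoustic_lld", medium = "facial_au",
                  noise = "deep_noise")

.toy_cache <- new.env(parent = emptyenv())

# one replicate: cohort(seed) -> three trained models -> fused dev CCCs
toy_replicate <- function(seed) {
  key <- paste0("rep", seed)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  cohort <- generate_cohort(cohort_spec(seed = seed))
  models <- lapply(toy_features, function(f) {
    train_feature_model(cohort$train, cohort$dev, f,
                        enc_cfg = toy_encoder(), train_cfg = toy_train_cfg(seed))
  })
  preds <- lapply(models, `[[`, "predictions")
  lab <- dplyr::tibble(
    subject_id = vapply(cohort$dev, `[[`, character(1), "subject_id"),
    phq8_score = vapply(cohort$dev, `[[`, integer(1), "phq8_score"))
  fuse_ccc <- function(fr) {
    s <- fr$scores$prediction[match(lab$subject_id, fr$scores$subject_id)]
    ccc(lab$phq8_score, s)
  }
  res <- list(
    cohort = cohort, models = models, preds = preds, labels = lab,
    cccs = vapply(preds, validation_ccc, numeric(1)),
    adaptive_ccc = fuse_ccc(adaptive_fusion(preds)),
    averaged_ccc = fuse_ccc(averaged_fusion(preds)))
  .toy_cache[[key]] <- res
  res
}

# tiny cohort for fast smoke tests
tiny_cohort <- function(seed = 3L) {
  generate_cohort(cohort_spec(
    n_train = 8L, n_dev = 4L, seed = seed,
    feature_specs = list(
      feature_spec("f_sig", "low", d = 4L, t_range = c(20L, 30L),
                   signal_strength = 0.9, noise_sd = 0.5),
      feature_spec("f_null", "high", d = 3L, t_range = c(15L, 20L),
                   signal_strength = 0, noise_sd = 1))))
}

# synthetic prediction set over shared ids
fake_preds <- function(scores, feature_name, ccc_val, ids = NULL) {
  n <- length(scores)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  prediction_set(ids, scores, matrix(0.2, n, 5L), feature_name,
                 validation_ccc = ccc_val, validation_rmse = 1)
}
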