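#' Default pipeline configuration
#'
#' One nested list carrying every tunable of the pipeline with its default:
#' data source (synthetic cohort or a directory in the package's CSV
#' dialect), sampling budgets (2048 frames for low/middle-level features,
#' 720 for high-level), encoder architecture (6 layers, 1 head, feed-forward
#' 2048), training (Adam, learning rate 1e-5, loss weights 0.9/0.1) and the
#' fusion strategy. Partial configurations passed to [run_pipeline()] are
#' merged over these defaults; unknown keys are rejected.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    data = list(source = "synthetic", dir = NULL, n_train = 40L, n_dev = 16L),
    features = NULL,
    sampling = list(N_low_mid = 2048L, N_high = 720L, segments = 8L,
                    pad = TRUE),
    normalize = TRUE,
    encoder = list(num_layers = 6L, num_heads = 1L, ff_hidden = 2048L,
                   d_model = NULL, embed_dim = 256L, dropout = 0.1),
    training = list(learning_rate = 1e-5, batch_size = NULL, epochs = NULL,
                    a = 0.9, b = 0.1, eval_every = 5L,
                    resample_each_epoch = TRUE),
    fusion = list(strategy = "adaptive", top_m = NULL),
    out = "maft_out"
  )
}

merge_config <- function(user, default, path = "") {
  if (is.null(user)) return(default)
  if (length(user) > 0L && (is.null(names(user)) || any(names(user) == ""))) {
    abort(sprintf("Config entries under '%s' must be named.", path),
          class = "maft_error_config")
  }
  for (k in names(user)) {
    if (!k %in% names(default)) {
      abort(sprintf("Unknown config key '%s%s'.", path, k),
            class = "maft_error_config")
    }
    if (is.list(default[[k]]) && length(default[[k]]) > 0L &&
        !is.null(names(default[[k]]))) {
      default[[k]] <- merge_config(user[[k]], default[[k]],
                                   paste0(path, k, "."))
    } else {
      default[k] <- user[k]
    }
  }
  default
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return The fully resolved configuration list.
#' @export
read_run_config <- function(path) {
  merge_config(yaml::read_yaml(path), default_config())
}

#' Run the full pipeline
#'
#' Generates (or loads) a cohort, trains one encoder per feature type,
#' scores the development set, fuses the per-feature predictions and writes
#' all artifacts to `config$out`: per-feature checkpoints and prediction
#' CSVs, `fused.csv`, a `weights.csv` table (feature, CCC, weight), a
#' `metrics.json` with per-feature and fused CCC/RMSE, and `config.yaml`
#' echoing the resolved configuration. Every random draw is derived from
#' `config$seed`, so a rerun with the same configuration reproduces
#' `fused.csv` byte-identically.
#'
#' @param config Partial configuration merged over [default_config()].
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the fitted `models`, per-feature
#'   `predictions`, the `fusion` result, the `metrics` list and the
#'   resolved `config`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- merge_config(config, default_config())
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- cfg$out
  dir.create(file.path(out, "checkpoints"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "predictions"), showWarnings = FALSE)

  cohort <- if (identical(cfg$data$source, "synthetic")) {
    say("Generating synthetic cohort (train %d / dev %d)",
        cfg$data$n_train, cfg$data$n_dev)
    generate_cohort(cohort_spec(n_train = cfg$data$n_train,
                                n_dev = cfg$data$n_dev, seed = cfg$seed))
  } else if (identical(cfg$data$source, "dir")) {
    if (is.null(cfg$data$dir)) {
      abort("data.source = 'dir' needs data.dir.", class = "maft_error_config")
    }
    read_cohort(cfg$data$dir)
  } else {
    abort(sprintf("Unknown data source '%s'.", cfg$data$source),
          class = "maft_error_config")
  }

  feats <- cfg$features %||% names(cohort$train[[1L]]$features)
  enc_cfg <- encoder_config(num_layers = cfg$encoder$num_layers,
                            num_heads = cfg$encoder$num_heads,
                            ff_hidden = cfg$encoder$ff_hidden,
                            d_model = cfg$encoder$d_model,
                            dropout = cfg$encoder$dropout,
                            embed_dim = cfg$encoder$embed_dim)
  models <- list(); preds <- list(); metrics <- list()
  for (k in seq_along(feats)) {
    feat <- feats[[k]]
    level <- cohort$train[[1L]]$features[[feat]]$level
    n_frames <- if (level == "high") cfg$sampling$N_high else cfg$sampling$N_low_mid
    tc <- train_config(
      learning_rate = cfg$training$learning_rate,
      batch_size = cfg$training$batch_size, epochs = cfg$training$epochs,
      a = cfg$training$a, b = cfg$training$b,
      seed = (cfg$seed + 1000L * k) %% .Machine$integer.max,
      n_frames = n_frames, segments = cfg$sampling$segments,
      normalize = cfg$normalize,
      resample_each_epoch = cfg$training$resample_each_epoch,
      eval_every = cfg$training$eval_every, pad = cfg$sampling$pad)
    say("Training feature '%s' (%s-level, N = %d)", feat, level, n_frames)
    model <- train_feature_model(cohort$train, cohort$dev, feat,
                                 enc_cfg = enc_cfg, train_cfg = tc,
                                 quiet = quiet)
    save_checkpoint(model, file.path(out, "checkpoints", paste0(feat, ".rds")))
    readr::write_csv(as_tibble(model$predictions),
                     file.path(out, "predictions", paste0(feat, ".csv")),
                     progress = FALSE)
    metrics[[feat]] <- list(ccc = validation_ccc(model$predictions),
                            rmse = attr(model$predictions, "validation_rmse"))
    say("  dev CCC %.3f, RMSE %.3f", metrics[[feat]]$ccc, metrics[[feat]]$rmse)
    models[[feat]] <- model
    preds[[feat]] <- model$predictions
  }

  sel <- preds
  if (!is.null(cfg$fusion$top_m)) sel <- select_top_m(preds, cfg$fusion$top_m)
  fusion <- switch(cfg$fusion$strategy,
                   adaptive = tryCatch(
                     adaptive_fusion(sel),
                     maft_error_value = function(e) {
                       # no feature validated above CCC 0: adaptive weights
                       # are undefined, fall back to plain averaging
                       warn(paste("All validation CCCs <= 0;",
                                  "falling back to averaged fusion."))
                       averaged_fusion(sel)
                     }),
                   averaged = averaged_fusion(sel),
                   abort(sprintf("Unknown fusion strategy '%s'.",
                                 cfg$fusion$strategy),
                         class = "maft_error_config"))
  lab_dev <- subject_labels(cohort$dev)
  fused_scores <- fusion$scores$prediction[match(lab_dev$subject_id,
                                                 fusion$scores$subject_id)]
  metrics$fused <- list(ccc = ccc(lab_dev$phq8_score, fused_scores),
                        rmse = rmse(lab_dev$phq8_score, fused_scores))
  say("Fused (%s%s): dev CCC %.3f, RMSE %.3f", cfg$fusion$strategy,
      if (is.null(cfg$fusion$top_m)) "" else sprintf(", top %d", cfg$fusion$top_m),
      metrics$fused$ccc, metrics$fused$rmse)

  readr::write_csv(fusion$scores, file.path(out, "fused.csv"), progress = FALSE)
  readr::write_csv(fusion$weights, file.path(out, "weights.csv"),
                   progress = FALSE)
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  invisible(list(models = models, predictions = preds, fusion = fusion,
                 metrics = metrics, config = cfg))
}
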