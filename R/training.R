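#' Training configuration
#'
#' Optimization hyperparameters for a per-feature model. `NULL` entries are
#' resolved by the feature's level at fit time, following the conventional
#' budgets: low/middle-level streams use 2048 sampled frames, batch 48 and
#' 500 epochs; high-level streams use 720 frames, batch 24 and 200 epochs.
#' The optimizer is Adam with canonical moment parameters; only the learning
#' rate is exposed.
#'
#' @param learning_rate Adam learning rate (default `1e-5`).
#' @param batch_size Minibatch size, or `NULL` to resolve by level.
#' @param epochs Number of epochs, or `NULL` to resolve by level.
#' @param a,b Multi-task loss weights: `a` scales the CCC regression loss,
#'   `b` the classification cross-entropy. Defaults 0.9/0.1 (multi-task);
#'   use 1/0 for single-task regression.
#' @param seed Integer seed controlling initialization, frame sampling,
#'   dropout and batch shuffling; identical seeds reproduce a run exactly.
#' @param n_frames Frame budget `N` after segment sampling, or `NULL` to
#'   resolve by level.
#' @param segments Number of segments `s` for [segment_sample()] (default 8).
#' @param normalize Whether to z-score inputs with training-set statistics
#'   (default `TRUE`).
#' @param resample_each_epoch Redraw the segment sample every epoch (acts as
#'   data augmentation, default `TRUE`); `FALSE` freezes the first draw.
#' @param eval_every Evaluate the development set every this many epochs to
#'   track the best checkpoint (default 5).
#' @param pad Passed to [sampling_spec()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = NULL, epochs = NULL,
                         a = 0.9, b = 0.1, seed = 1L, n_frames = NULL,
                         segments = 8L, normalize = TRUE,
                         resample_each_epoch = TRUE, eval_every = 5L,
                         pad = TRUE) {
  if (learning_rate <= 0 || a < 0 || b < 0 || (a == 0 && b == 0)) {
    abort("Invalid training configuration.", class = "maft_error_value")
  }
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, a = a, b = b, seed = as.integer(seed),
                 n_frames = n_frames, segments = as.integer(segments),
                 normalize = isTRUE(normalize),
                 resample_each_epoch = isTRUE(resample_each_epoch),
                 eval_every = as.integer(eval_every), pad = isTRUE(pad)),
            class = "train_config")
}

resolve_train_config <- function(tc, level) {
  low_mid <- level %in% c("low", "middle")
  tc$n_frames <- as.integer(tc$n_frames %||% if (low_mid) 2048L else 720L)
  tc$batch_size <- as.integer(tc$batch_size %||% if (low_mid) 48L else 24L)
  tc$epochs <- as.integer(tc$epochs %||% if (low_mid) 500L else 200L)
  if (tc$epochs < 1L || tc$batch_size < 2L) {
    abort("epochs must be >= 1 and batch_size >= 2.", class = "maft_error_value")
  }
  tc
}

#' Per-feature prediction set
#'
#' Out-of-sample predictions of one feature model over a subject set,
#' together with the validation CCC that drives adaptive fusion.
#'
#' @param subject_ids Character vector.
#' @param scores Predicted PHQ-8 scores.
#' @param class_probs `n x 5` severity class probabilities.
#' @param feature_name Name of the feature the model was trained on.
#' @param validation_ccc,validation_rmse Development-set metrics.
#' @return A tibble of class `maft_predictions` with columns `subject_id`,
#'   `prediction` and `prob_0` .. `prob_4`; the feature name and validation
#'   metrics are stored as attributes.
#' @export
prediction_set <- function(subject_ids, scores, class_probs, feature_name,
                           validation_ccc = NA_real_,
                           validation_rmse = NA_real_) {
  class_probs <- as.matrix(class_probs)
  stopifnot(length(subject_ids) == length(scores),
            nrow(class_probs) == length(scores))
  if (!is.na(validation_ccc) &&
      (validation_ccc < -1 || validation_ccc > 1)) {
    abort("validation_ccc must lie in [-1, 1].", class = "maft_error_value")
  }
  out <- tibble(subject_id = as.character(subject_ids),
                prediction = as.numeric(scores))
  probs <- as_tibble(class_probs, .name_repair = ~ paste0("prob_", seq_along(.) - 1L))
  out <- dplyr::bind_cols(out, probs)
  structure(out, class = c("maft_predictions", class(out)),
            feature_name = feature_name,
            validation_ccc = validation_ccc,
            validation_rmse = validation_rmse)
}

#' @rdname prediction_set
#' @param x A `maft_predictions` object.
#' @export
validation_ccc <- function(x) attr(x, "validation_ccc")

#' @rdname prediction_set
#' @export
feature_name <- function(x) attr(x, "feature_name")

# assemble a subject-major activation matrix from sampled+normalized matrices
stack_frames <- function(mats) do.call(rbind, mats)

# sample + normalize one subject list; returns list of N x d matrices
prepare_frames <- function(subjects, feat, spec, norm, seed_base = NULL) {
  lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]$features[[feat]]
    sp <- spec
    if (!is.null(seed_base)) sp$seed <- (seed_base + i) %% .Machine$integer.max
    out <- segment_sample(s, sp)
    if (!is.null(norm)) out <- zscore_apply(out, norm)
    out$frames
  })
}

#' Train one per-feature transformer model
#'
#' Fits an independent encoder for one feature type: frames are
#' segment-sampled (redrawn each epoch by default), z-scored with
#' training-set statistics, and the network is optimized with Adam on the
#' joint loss `a * (1 - CCC) + b * cross-entropy`, the CCC being computed
#' over each minibatch. The development set is scored periodically and the
#' parameters with the best development CCC are retained.
#'
#' @param train,dev Lists of [subject_record()]s; subjects missing the
#'   feature are excluded with a warning.
#' @param feat Feature name to train on.
#' @param enc_cfg An [encoder_config()].
#' @param train_cfg A [train_config()].
#' @param quiet Suppress per-evaluation progress messages (default `TRUE`).
#' @return An object of class `maft_model`: the best-checkpoint encoder,
#'   normalization statistics, the resolved configurations, the training
#'   history (tibble with epoch, loss, task losses, development CCC at
#'   evaluation points) and the development [prediction_set()].
#' @export
train_feature_model <- function(train, dev, feat,
                                enc_cfg = encoder_config(),
                                train_cfg = train_config(),
                                quiet = TRUE) {
  subs_tr <- subjects_with_feature(train, feat)
  subs_dev <- subjects_with_feature(dev, feat)
  level <- subs_tr[[1L]]$features[[feat]]$level
  tc <- resolve_train_config(train_cfg, level)
  d <- ncol(subs_tr[[1L]]$features[[feat]]$frames)
  dims <- vapply(c(subs_tr, subs_dev),
                 function(s) ncol(s$features[[feat]]$frames), integer(1))
  if (!all(dims == d)) {
    abort(sprintf("Feature '%s' has inconsistent dimensions across subjects.",
                  feat), class = "maft_error_value")
  }
  set.seed(tc$seed)
  norm <- if (tc$normalize)
    zscore_fit(lapply(subs_tr, function(s) s$features[[feat]])) else NULL
  spec <- sampling_spec(tc$n_frames, tc$segments, pad = tc$pad)
  n_tr <- length(subs_tr)
  lab_tr <- subject_labels(subs_tr)
  lab_dev <- subject_labels(subs_dev)
  # development frames: one fixed draw, decoupled from the training stream
  dev_mats <- prepare_frames(subs_dev, feat, spec, norm, seed_base = tc$seed)
  M_dev <- stack_frames(dev_mats)
  cfg <- resolve_encoder_config(enc_cfg, d)
  params <- init_params(cfg)
  state <- adam_init(params)
  best <- list(ccc = -Inf, params = params)
  t_frames <- tc$n_frames
  tr_mats <- NULL
  hist <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs)) {
    if (epoch == 1L || tc$resample_each_epoch) {
      tr_mats <- prepare_frames(subs_tr, feat, spec, norm)
    }
    ord <- sample.int(n_tr)
    n_batch <- ceiling(n_tr / tc$batch_size)
    batches <- split(ord, rep(seq_len(n_batch), length.out = n_tr,
                              each = tc$batch_size))
    if (n_batch > 1L && length(batches[[n_batch]]) < 2L) {
      batches[[n_batch - 1L]] <- c(batches[[n_batch - 1L]], batches[[n_batch]])
      batches[[n_batch]] <- NULL
    }
    losses <- l_res <- l_cls <- numeric(length(batches))
    for (k in seq_along(batches)) {
      ids <- batches[[k]]
      M <- stack_frames(tr_mats[ids])
      lg <- net_loss_grads(params, cfg, M, length(ids), t_frames,
                           y = lab_tr$phq8_score[ids],
                           cls = lab_tr$severity_class[ids],
                           a = tc$a, b_w = tc$b, training = TRUE)
      if (!is.finite(lg$loss)) {
        abort(sprintf("Non-finite loss at epoch %d (feature '%s').",
                      epoch, feat), class = "maft_error_numeric")
      }
      up <- adam_step(params, lg$grads, state, tc$learning_rate)
      params <- up$params; state <- up$state
      losses[k] <- lg$loss; l_res[k] <- lg$l_re; l_cls[k] <- lg$l_cl
    }
    dev_ccc <- NA_real_
    if (epoch %% tc$eval_every == 0L || epoch == tc$epochs) {
      fw <- forward_net(params, cfg, M_dev, length(subs_dev), t_frames,
                        training = FALSE)
      dev_ccc <- tryCatch(ccc(lab_dev$phq8_score, fw$yhat),
                          error = function(e) NA_real_)
      if (!is.na(dev_ccc) && dev_ccc > best$ccc) {
        best <- list(ccc = dev_ccc, params = params)
      }
      if (!quiet) {
        message(sprintf("[%s] epoch %d: loss %.4f, dev CCC %.3f",
                        feat, epoch, mean(losses), dev_ccc))
      }
    }
    hist[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
                            loss_regression = mean(l_res),
                            loss_classification = mean(l_cls),
                            dev_ccc = dev_ccc)
  }
  if (!is.finite(best$ccc)) best$params <- params
  model <- structure(
    list(feature_name = feat, level = level,
         encoder = structure(list(cfg = cfg, params = best$params),
                             class = "maft_encoder"),
         norm = norm, train_cfg = tc,
         history = dplyr::bind_rows(hist),
         version = "maft-checkpoint-1"),
    class = "maft_model")
  model$predictions <- evaluate_model(model, subs_dev, seed = tc$seed)
  model
}

# forward pass over prepared matrices -> scores + probs
predict_frames <- function(model, mats) {
  M <- stack_frames(mats)
  fw <- forward_net(model$encoder$params, model$encoder$cfg, M,
                    length(mats), nrow(mats[[1L]]), training = FALSE)
  list(scores = fw$yhat, probs = row_softmax(fw$logits))
}

#' Score a subject set with a fitted feature model
#'
#' Deterministic: frames are sampled with a fixed per-subject seed derived
#' from `seed`, normalization uses the model's stored training statistics
#' and the network runs in eval mode.
#'
#' @param model A `maft_model`.
#' @param subjects List of [subject_record()]s carrying the model's feature.
#' @param seed Seed for the frame draw (default 1).
#' @return A [prediction_set()] with validation CCC/RMSE computed against
#'   the subjects' labels.
#' @export
evaluate_model <- function(model, subjects, seed = 1L) {
  if (length(subjects) == 0L) {
    abort("Empty subject list.", class = "maft_error_empty")
  }
  subjects <- subjects_with_feature(subjects, model$feature_name)
  d <- ncol(subjects[[1L]]$features[[model$feature_name]]$frames)
  if (d != model$encoder$cfg$input_dim) {
    abort(sprintf("Feature dimension %d does not match the checkpoint (%d).",
                  d, model$encoder$cfg$input_dim), class = "maft_error_value")
  }
  tc <- model$train_cfg
  spec <- sampling_spec(tc$n_frames, tc$segments, pad = tc$pad)
  mats <- prepare_frames(subjects, model$feature_name, spec, model$norm,
                         seed_base = as.integer(seed))
  pr <- predict_frames(model, mats)
  lab <- subject_labels(subjects)
  v_ccc <- tryCatch(ccc(lab$phq8_score, pr$scores), error = function(e) NA_real_)
  prediction_set(lab$subject_id, pr$scores, pr$probs,
                 feature_name = model$feature_name,
                 validation_ccc = v_ccc,
                 validation_rmse = rmse(lab$phq8_score, pr$scores))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: parameters, encoder and training
#' configuration, normalization statistics and a format version field.
#'
#' @param model A `maft_model`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "maft_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "maft_model") ||
      !identical(model$version, "maft-checkpoint-1")) {
    abort("Not a recognized model checkpoint.", class = "maft_error_format")
  }
  model
}

#' @export
print.maft_model <- function(x, ...) {
  cat(sprintf(paste0("<maft_model> feature '%s' (%s-level), %d encoder ",
                     "layer(s), d_model %d\n  dev CCC %.3f, dev RMSE %.3f\n"),
              x$feature_name, x$level, x$encoder$cfg$num_layers,
              x$encoder$cfg$d_model,
              validation_ccc(x$predictions),
              attr(x$predictions, "validation_rmse")))
  invisible(x)
}
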