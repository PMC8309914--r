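#' Score distribution emulating the usual screening-cohort imbalance
#'
#' Probability over integer PHQ-8 scores 0..24. The default mirrors the
#' class imbalance typical of depression-screening interview corpora
#' (roughly 47/22/16/10/4 percent across the five severity classes, skewed
#' strongly toward minimal depression), spread uniformly within each class.
#'
#' @param class_weights Non-negative weights for the five severity classes.
#' @return Named numeric vector of length 25 summing to 1.
#' @export
phq8_score_probs <- function(class_weights = c(77, 36, 26, 17, 7)) {
  if (length(class_weights) != 5L || any(class_weights < 0) ||
      sum(class_weights) <= 0) {
    abort("class_weights must be 5 non-negative numbers, not all zero.",
          class = "maft_error_value")
  }
  p <- rep(class_weights / sum(class_weights) / 5, each = 5L)
  names(p) <- 0:24
  p
}

#' Specification of one synthetic feature stream
#'
#' Each subject's stream is a stationary AR(1) process around a feature-level
#' baseline whose per-dimension mean is shifted by
#' `signal_strength * (score / 24) * direction`, with a fixed random
#' direction vector per feature. `signal_strength = 0` gives a pure-noise
#' feature carrying no severity information; `noise_sd = 0` removes the
#' stochastic part entirely so the temporal mean is an exact affine function
#' of the score.
#'
#' @param name Feature name.
#' @param level `"low"`, `"middle"` or `"high"` (drives sampling budgets).
#' @param d Feature dimension.
#' @param t_range Integer range (min, max) of sequence lengths.
#' @param signal_strength Severity signal strength in `[0, 1]`.
#' @param noise_sd Standard deviation of the AR(1) noise.
#' @param ar Temporal autocorrelation of the AR(1) noise, in `[0, 1)`.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, level = c("low", "middle", "high"), d = 8L,
                         t_range = c(60L, 80L), signal_strength = 0.9,
                         noise_sd = 0.6, ar = 0.5) {
  level <- match.arg(level)
  if (d < 1L || signal_strength < 0 || signal_strength > 1 || noise_sd < 0 ||
      ar < 0 || ar >= 1 || length(t_range) != 2L || t_range[1L] > t_range[2L] ||
      t_range[1L] < 1L) {
    abort("Invalid feature specification.", class = "maft_error_value")
  }
  structure(list(name = name, level = level, d = as.integer(d),
                 t_range = as.integer(t_range),
                 signal_strength = signal_strength, noise_sd = noise_sd,
                 ar = ar),
            class = "feature_spec")
}

default_feature_specs <- function() {
  list(
    feature_spec("acoustic_lld", "low", d = 8L, t_range = c(60L, 80L),
                 signal_strength = 0.9, noise_sd = 0.6, ar = 0.5),
    feature_spec("facial_au", "middle", d = 6L, t_range = c(60L, 80L),
                 signal_strength = 0.5, noise_sd = 0.8, ar = 0.5),
    feature_spec("deep_noise", "high", d = 4L, t_range = c(40L, 60L),
                 signal_strength = 0, noise_sd = 1, ar = 0.5)
  )
}

#' Synthetic cohort specification
#'
#' Defines a multimodal cohort with a latent severity planted in some
#' features: a strong-signal low-level stream, a medium-signal middle-level
#' stream and a pure-noise high-level stream by default, at desk-scale
#' cohort sizes (40 training / 16 development subjects).
#'
#' @param n_train,n_dev Number of training / development subjects.
#' @param score_probs Probability vector over scores 0..24; see
#'   [phq8_score_probs()].
#' @param feature_specs List of [feature_spec()]s; at least one must have
#'   positive signal strength.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_train = 40L, n_dev = 16L,
                        score_probs = phq8_score_probs(),
                        feature_specs = default_feature_specs(),
                        seed = 1L) {
  if (n_train < 2L || n_dev < 2L) {
    abort("Need at least 2 subjects per split.", class = "maft_error_value")
  }
  if (length(score_probs) != 25L || any(score_probs < 0) ||
      abs(sum(score_probs) - 1) > 1e-8) {
    abort("score_probs must be 25 non-negative numbers summing to 1.",
          class = "maft_error_value")
  }
  stopifnot(all(vapply(feature_specs, inherits, logical(1), "feature_spec")))
  if (!any(vapply(feature_specs, `[[`, numeric(1), "signal_strength") > 0)) {
    abort("At least one feature must carry signal.", class = "maft_error_value")
  }
  structure(list(n_train = as.integer(n_train), n_dev = as.integer(n_dev),
                 score_probs = score_probs, feature_specs = feature_specs,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

ar1_noise <- function(t, d, ar) {
  e <- matrix(rnorm(t * d), t, d)
  if (ar > 0 && t > 1L) {
    sc <- sqrt(1 - ar^2)
    for (s in 2:t) e[s, ] <- ar * e[s - 1L, ] + sc * e[s, ]
  }
  e
}

#' Generate a synthetic multimodal cohort
#'
#' Draws per-subject PHQ-8 scores from the specified distribution, then per
#' feature an AR(1) frame stream whose mean encodes the severity signal (see
#' [feature_spec()]). Splits are disjoint and the whole draw is a pure
#' function of the seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `train` and `dev`, each a list of [subject_record()]s.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_train + spec$n_dev
    ids <- sprintf("S%03d", seq_len(n))
    scores <- sample(0:24, n, replace = TRUE, prob = spec$score_probs)
    genders <- sample(c("F", "M"), n, replace = TRUE)
    # fixed per-feature geometry: a baseline and a severity direction
    geom <- lapply(spec$feature_specs, function(fs) {
      list(mu = rnorm(fs$d), dir = rnorm(fs$d))
    })
    subjects <- lapply(seq_len(n), function(i) {
      feats <- lapply(seq_along(spec$feature_specs), function(k) {
        fs <- spec$feature_specs[[k]]
        t <- sample(fs$t_range[1L]:fs$t_range[2L], 1L)
        base <- geom[[k]]$mu +
          fs$signal_strength * (scores[i] / 24) * geom[[k]]$dir
        frames <- matrix(base, t, fs$d, byrow = TRUE) +
          fs$noise_sd * ar1_noise(t, fs$d, fs$ar)
        feature_sequence(frames, fs$name, fs$level)
      })
      subject_record(ids[i], scores[i], gender = genders[i], features = feats)
    })
    list(train = subjects[seq_len(spec$n_train)],
         dev = subjects[spec$n_train + seq_len(spec$n_dev)])
  })
}

#' Write a cohort to disk in the package's CSV dialect
#'
#' Emits `labels_train.csv` / `labels_dev.csv` (columns `Participant_ID`,
#' `PHQ8_Score`, `PHQ8_Binary`, `Gender`), a `features.csv` manifest
#' (feature name, level, dimension) and one frame CSV per subject and
#' feature under `features/<feature>/<subject>.csv` — exactly the dialect
#' [read_feature_csv()] and [read_label_table()] read back.
#'
#' @param cohort As returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_split <- function(subjects, label_file) {
    lab <- tibble(
      Participant_ID = vapply(subjects, `[[`, character(1), "subject_id"),
      PHQ8_Score = vapply(subjects, `[[`, integer(1), "phq8_score"),
      PHQ8_Binary = vapply(subjects, `[[`, integer(1), "phq8_binary"),
      Gender = vapply(subjects, `[[`, character(1), "gender"))
    readr::write_csv(lab, file.path(dir, label_file), progress = FALSE)
    for (s in subjects) {
      for (f in s$features) {
        fdir <- file.path(dir, "features", f$feature_name)
        dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
        write_feature_csv(f, file.path(fdir, paste0(s$subject_id, ".csv")))
      }
    }
  }
  write_split(cohort$train, "labels_train.csv")
  write_split(cohort$dev, "labels_dev.csv")
  feats <- cohort$train[[1L]]$features
  manifest <- tibble(
    feature_name = vapply(feats, `[[`, character(1), "feature_name"),
    level = vapply(feats, `[[`, character(1), "level"),
    dim = vapply(feats, function(f) ncol(f$frames), integer(1)))
  readr::write_csv(manifest, file.path(dir, "features.csv"), progress = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the label files, manifest and feature CSVs.
#' @return List with `train` and `dev` lists of [subject_record()]s.
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "features.csv"),
                              col_types = "cci", progress = FALSE)
  read_split <- function(label_file) {
    lab <- read_label_table(file.path(dir, label_file))
    purrr::pmap(list(lab$subject_id, lab$phq8_score, lab$phq8_binary, lab$gender),
                function(id, score, bin, gender) {
      feats <- purrr::pmap(manifest, function(feature_name, level, dim) {
        read_feature_csv(
          file.path(dir, "features", feature_name, paste0(id, ".csv")),
          feature_name = feature_name, level = level)
      })
      subject_record(id, score, bin, gender, feats)
    })
  }
  list(train = read_split("labels_train.csv"),
       dev = read_split("labels_dev.csv"))
}
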