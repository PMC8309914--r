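#' Frame-level feature sequence
#'
#' The basic carrier of one feature type for one subject: a `t x d` numeric
#' matrix of frame-level descriptors (one row per frame, e.g. MFCC or facial
#' action-unit exports), tagged with the feature name and its expression level.
#' The level controls which frame-sampling budget applies downstream:
#' low/middle-level streams are long (tens of thousands of frames) and get the
#' large budget, high-level streams are short and get the small one.
#'
#' @param frames Numeric matrix, `t` frames by `d` dimensions. All entries
#'   must be finite.
#' @param feature_name Character scalar naming the feature type.
#' @param level One of `"low"`, `"middle"`, `"high"`.
#' @return An object of class `feature_sequence`.
#' @export
feature_sequence <- function(frames, feature_name, level = c("low", "middle", "high")) {
  level <- match.arg(level)
  if (!is.matrix(frames) || !is.numeric(frames)) {
    abort("`frames` must be a numeric matrix.", class = "maft_error_type")
  }
  if (nrow(frames) < 1L || ncol(frames) < 1L) {
    abort("`frames` must have at least one row and one column.",
          class = "maft_error_empty")
  }
  if (!all(is.finite(frames))) {
    abort("`frames` contains non-finite values (NA/NaN/Inf).",
          class = "maft_error_nonfinite")
  }
  structure(
    list(feature_name = as.character(feature_name), level = level,
         frames = unname(frames)),
    class = "feature_sequence"
  )
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> %s (%s-level): %d frames x %d dims\n",
              x$feature_name, x$level, nrow(x$frames), ncol(x$frames)))
  invisible(x)
}

#' @export
dim.feature_sequence <- function(x) dim(x$frames)

#' Read a frame-per-row feature CSV
#'
#' Reads an openSMILE/openFace-style export: one row per frame, numeric
#' columns, optionally preceded by declared non-numeric columns (frame index,
#' timestamp) which are dropped. The number of leading columns to drop is
#' declared explicitly rather than auto-detected.
#'
#' @param path Path to the CSV file.
#' @inheritParams feature_sequence
#' @param skip_cols Number of leading non-numeric columns to drop (default 0).
#' @param header Whether the file has a header row (default `TRUE`).
#' @param delim Field delimiter, `","` or `";"` (openSMILE exports vary).
#' @return A [feature_sequence()].
#' @export
read_feature_csv <- function(path, feature_name, level = c("low", "middle", "high"),
                             skip_cols = 0L, header = TRUE, delim = ",") {
  level <- match.arg(level)
  if (!file.exists(path)) {
    abort(sprintf("Feature file does not exist: %s", path),
          class = "maft_error_io")
  }
  if (file.size(path) == 0L) {
    abort(sprintf("Feature file is empty: %s", path), class = "maft_error_empty")
  }
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_names = header,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE, trim_ws = TRUE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("Malformed feature CSV %s: row %d (%s)", path,
                  probs$row[[1L]], probs$expected[[1L]]),
          class = "maft_error_format")
  }
  if (nrow(df) == 0L) {
    abort(sprintf("Feature file has no data rows: %s", path),
          class = "maft_error_empty")
  }
  # ragged rows shorter than the header materialise as trailing NAs
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0L)[1L]
    abort(sprintf("Malformed feature CSV %s: row %d has missing fields", path, bad),
          class = "maft_error_format")
  }
  skip_cols <- as.integer(skip_cols)
  if (skip_cols >= ncol(df)) {
    abort(sprintf("skip_cols = %d leaves no numeric columns (file has %d).",
                  skip_cols, ncol(df)), class = "maft_error_format")
  }
  if (skip_cols > 0L) df <- df[, -seq_len(skip_cols), drop = FALSE]
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(df))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-numeric value in %s at data row %d, numeric column %d",
                  path, idx[["row"]], idx[["col"]]),
          class = "maft_error_parse")
  }
  feature_sequence(num, feature_name = feature_name, level = level)
}

#' Write a feature sequence to CSV
#'
#' Values are written in shortest round-trip representation, so a write/read
#' cycle reproduces the matrix bit-identically.
#'
#' @param seq A [feature_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(seq, path) {
  stopifnot(inherits(seq, "feature_sequence"))
  df <- as.data.frame(seq$frames)
  names(df) <- paste0("V", seq_len(ncol(df)))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Severity-class bins for PHQ-8 scores
#'
#' Maps integer PHQ-8 totals to the standard five severity classes using
#' cut-points at 0, 5, 10, 15 and 20: minimal \[0-4\], mild \[5-9\], moderate
#' \[10-14\], moderately severe \[15-19\], severe \[20-24\]. Intervals are
#' closed integer ranges.
#'
#' @param score Integer vector of PHQ-8 scores in \[0, 24\].
#' @return Integer vector of class labels in `0:4`.
#' @export
#' @examples
#' bin_phq8(c(0, 4, 5, 10, 19, 24))
bin_phq8 <- function(score) {
  if (any(!is.finite(score)) || any(score != round(score))) {
    abort("PHQ-8 scores must be finite integers.", class = "maft_error_value")
  }
  if (any(score < 0 | score > 24)) {
    abort(sprintf("PHQ-8 score out of range [0, 24]: %s",
                  paste(score[score < 0 | score > 24], collapse = ", ")),
          class = "maft_error_value")
  }
  as.integer(findInterval(score, c(0, 5, 10, 15, 20)) - 1L)
}

#' Read a label table
#'
#' Expects columns `Participant_ID`, `PHQ8_Score`, `PHQ8_Binary`, `Gender`.
#' Scores are validated against the PHQ-8 range and the derived five-class
#' severity label is appended.
#'
#' @param path Path to the label CSV.
#' @return A tibble with columns `subject_id`, `phq8_score`, `phq8_binary`,
#'   `gender`, `severity_class`.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Label file does not exist: %s", path), class = "maft_error_io")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    Participant_ID = readr::col_character(),
    PHQ8_Score = readr::col_double(),
    PHQ8_Binary = readr::col_double(),
    Gender = readr::col_character()
  ), progress = FALSE)
  validate_label_table(tibble(
    subject_id = df$Participant_ID,
    phq8_score = as.integer(df$PHQ8_Score),
    phq8_binary = as.integer(df$PHQ8_Binary),
    gender = df$Gender
  ))
}

validate_label_table <- function(tbl) {
  dup <- tbl$subject_id[duplicated(tbl$subject_id)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate subject id(s): %s", paste(unique(dup), collapse = ", ")),
          class = "maft_error_value")
  }
  bad <- tbl$subject_id[tbl$phq8_score < 0L | tbl$phq8_score > 24L]
  if (length(bad) > 0L) {
    abort(sprintf("PHQ-8 score out of [0, 24] for subject(s): %s",
                  paste(bad, collapse = ", ")), class = "maft_error_value")
  }
  if (!all(tbl$phq8_binary %in% c(0L, 1L))) {
    abort("PHQ8_Binary must be 0 or 1.", class = "maft_error_value")
  }
  tbl$severity_class <- bin_phq8(tbl$phq8_score)
  tbl
}

#' Per-subject record
#'
#' Bundles a subject's identifiers, PHQ-8 labels and the map of feature-name
#' to [feature_sequence()]. The severity class is always derived from the
#' score via [bin_phq8()].
#'
#' @param subject_id Character scalar.
#' @param phq8_score Integer in \[0, 24\].
#' @param phq8_binary 0/1; defaults to `score >= 10`.
#' @param gender Optional character scalar.
#' @param features Named list of [feature_sequence()] objects.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, phq8_score, phq8_binary = NULL,
                           gender = NA_character_, features = list()) {
  phq8_score <- as.integer(phq8_score)
  if (length(phq8_score) != 1L || phq8_score < 0L || phq8_score > 24L) {
    abort(sprintf("phq8_score must be a single integer in [0, 24] (subject %s).",
                  subject_id), class = "maft_error_value")
  }
  if (is.null(phq8_binary)) phq8_binary <- as.integer(phq8_score >= 10L)
  if (length(features) > 0L) {
    stopifnot(all(vapply(features, inherits, logical(1), "feature_sequence")))
    names(features) <- vapply(features, `[[`, character(1), "feature_name")
  }
  structure(
    list(subject_id = as.character(subject_id), phq8_score = phq8_score,
         phq8_binary = as.integer(phq8_binary),
         severity_class = bin_phq8(phq8_score),
         gender = gender, features = features),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s: PHQ-8 %d (class %d), features: %s\n",
              x$subject_id, x$phq8_score, x$severity_class,
              paste(names(x$features), collapse = ", ")))
  invisible(x)
}

#' Assemble subject records from a label table and feature sequences
#'
#' @param labels A label tibble as returned by [read_label_table()].
#' @param features Named list (by subject id) of named lists of
#'   [feature_sequence()] objects. Subjects without an entry get an empty
#'   feature map.
#' @return List of [subject_record()] objects, in label-table order.
#' @export
build_subjects <- function(labels, features = list()) {
  labels <- validate_label_table(labels[, c("subject_id", "phq8_score",
                                            "phq8_binary", "gender")])
  purrr::pmap(
    list(labels$subject_id, labels$phq8_score, labels$phq8_binary, labels$gender),
    function(id, score, bin, gender) {
      subject_record(id, score, bin, gender, features[[id]] %||% list())
    }
  )
}

# subjects holding a given feature; warns (once) about the excluded ones
subjects_with_feature <- function(subjects, feature_name) {
  has <- vapply(subjects, function(s) feature_name %in% names(s$features),
                logical(1))
  if (!any(has)) {
    abort(sprintf("No subject carries feature '%s'.", feature_name),
          class = "maft_error_value")
  }
  if (!all(has)) {
    missing_ids <- vapply(subjects[!has], `[[`, character(1), "subject_id")
    warn(sprintf("Excluding %d subject(s) without feature '%s': %s",
                 sum(!has), feature_name, paste(missing_ids, collapse = ", ")))
  }
  subjects[has]
}

# label vectors for a subject list
subject_labels <- function(subjects) {
  tibble(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    phq8_score = vapply(subjects, `[[`, integer(1), "phq8_score"),
    severity_class = vapply(subjects, `[[`, integer(1), "severity_class")
  )
}
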