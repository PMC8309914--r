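#' Tidy a fitted feature model
#'
#' Returns the training history: one row per epoch with the combined loss,
#' the two task losses and the development CCC at evaluation epochs.
#'
#' @param x A `maft_model`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `loss`, `loss_regression`,
#'   `loss_classification`, `dev_ccc`.
#' @export
tidy.maft_model <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted feature model
#'
#' @param x A `maft_model`.
#' @param ... Unused.
#' @return A tibble with the feature name, level, development CCC and RMSE,
#'   and the main architecture/training sizes.
#' @export
glance.maft_model <- function(x, ...) {
  tibble(feature_name = x$feature_name, level = x$level,
         dev_ccc = validation_ccc(x$predictions),
         dev_rmse = attr(x$predictions, "validation_rmse"),
         epochs = x$train_cfg$epochs,
         num_layers = x$encoder$cfg$num_layers,
         d_model = x$encoder$cfg$d_model,
         n_frames = x$train_cfg$n_frames)
}

#' Plot the training history of a feature model
#'
#' Loss (and, on evaluation epochs, development CCC) against epoch.
#'
#' @param object A `maft_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maft_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("loss", "dev_ccc"),
                           names_to = "quantity", values_to = "value")
  h <- dplyr::filter(h, !is.na(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1L) +
    ggplot2::labs(title = sprintf("Training history: %s", object$feature_name),
                  x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a fusion result
#'
#' @param x A `maft_fusion` object.
#' @param ... Unused.
#' @return The weight table: one row per fused feature with its validation
#'   CCC and fusion weight.
#' @export
tidy.maft_fusion <- function(x, ...) {
  x$weights
}

#' One-row summary of a fusion result
#'
#' @param x A `maft_fusion` object.
#' @param ... Unused.
#' @return A tibble with the strategy, number of features fused and number
#'   of subjects scored.
#' @export
glance.maft_fusion <- function(x, ...) {
  tibble(strategy = x$strategy, n_features = x$m,
         n_subjects = nrow(x$scores))
}

#' Plot fusion weights
#'
#' @param object A `maft_fusion` object.
#' @param ... Unused.
#' @return A ggplot bar chart of per-feature weights, annotated with the
#'   validation CCCs that produced them.
#' @export
autoplot.maft_fusion <- function(object, ...) {
  w <- dplyr::arrange(object$weights, dplyr::desc(.data$weight))
  w$feature_name <- factor(w$feature_name, levels = w$feature_name)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$feature_name, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("CCC %.2f", .data$ccc)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(title = sprintf("%s fusion weights", object$strategy),
                  x = NULL, y = "weight") +
    ggplot2::theme_minimal()
}

#' One-row summary of a prediction set
#'
#' @param x A `maft_predictions` tibble.
#' @param ... Unused.
#' @return A tibble with the feature name, validation CCC/RMSE and size.
#' @export
glance.maft_predictions <- function(x, ...) {
  tibble(feature_name = feature_name(x),
         validation_ccc = validation_ccc(x),
         validation_rmse = attr(x, "validation_rmse"),
         n = nrow(x))
}

#' Plot predictions against true scores
#'
#' @param object A `maft_predictions` tibble.
#' @param truth Optional tibble with `subject_id` and `phq8_score` (e.g.
#'   from [read_label_table()]); when given, a predicted-vs-true scatter is
#'   drawn, otherwise a histogram of the predictions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maft_predictions <- function(object, truth = NULL, ...) {
  if (is.null(truth)) {
    return(ggplot2::ggplot(object, ggplot2::aes(x = .data$prediction)) +
             ggplot2::geom_histogram(bins = 15L) +
             ggplot2::labs(title = feature_name(object),
                           x = "predicted PHQ-8") +
             ggplot2::theme_minimal())
  }
  d <- dplyr::inner_join(as_tibble(object), truth, by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phq8_score, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(title = feature_name(object), x = "true PHQ-8",
                  y = "predicted PHQ-8") +
    ggplot2::theme_minimal()
}
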