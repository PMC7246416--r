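#' Confusion-matrix counts
#'
#' Closed eyes (label 1) is the positive class: TP counts correctly
#' recognized closed-eye windows, TN correctly recognized open-eye windows,
#' FP open windows called closed, FN closed windows called open.
#'
#' @param pred Predicted 0/1 vector.
#' @param truth Observed 0/1 vector of the same length.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("`pred` and `truth` must be 0/1", call. = FALSE)
  }
  structure(list(
    TP = sum(pred == 1 & truth == 1),
    FP = sum(pred == 1 & truth == 0),
    TN = sum(pred == 0 & truth == 0),
    FN = sum(pred == 0 & truth == 1)
  ), class = "confusion_counts")
}

#' F1 measure from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)`; 0 by convention when both are 0.
#'
#' @param precision,recall Values in [0, 1].
#' @return F1 in [0, 1].
#' @export
#' @examples
#' f1_measure(0.94, 0.90)
f1_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `f1 = 2 P R / (P + R)`. A zero denominator in
#' precision or recall yields 0 with a warning.
#'
#' @param counts A `confusion_counts`.
#' @param model Optional model name carried into the output row.
#' @return A one-row tibble (`model`, `accuracy`, `precision`, `recall`,
#'   `f1`), values unrounded.
#' @export
compute_metrics <- function(counts, model = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  prec <- if (counts$TP + counts$FP == 0) {
    warning("no positive predictions; precision set to 0", call. = FALSE)
    0
  } else counts$TP / (counts$TP + counts$FP)
  rec <- if (counts$TP + counts$FN == 0) {
    warning("no positive ground-truth labels; recall set to 0", call. = FALSE)
    0
  } else counts$TP / (counts$TP + counts$FN)
  tibble::tibble(
    model = model,
    accuracy = (counts$TP + counts$TN) / total,
    precision = prec, recall = rec,
    f1 = f1_measure(prec, rec)
  )
}

#' Round metrics for display
#'
#' Half-up rounding to 2 decimals, the precision used in published
#' eye-state benchmark tables. The unrounded values should be kept for any
#' further computation.
#'
#' @param metrics A metrics tibble from [compute_metrics()] or
#'   [run_benchmark()].
#' @return The tibble with metric columns rounded to 2 decimals.
#' @export
round_metrics <- function(metrics) {
  half_up <- function(x) floor(x * 100 + 0.5) / 100
  dplyr::mutate(metrics, dplyr::across(
    dplyr::any_of(c("accuracy", "precision", "recall", "f1")), half_up))
}

#' Published reference metrics for the UCI EEG eye-state task
#'
#' The reference comparison table for this classifier family on the UCI
#' "EEG Eye State" recording (117 s, 14-channel Emotiv, per-sample eye
#' labels): accuracy, precision, recall and F1 for decision tree, random
#' forest, logistic regression, SVM, factorization machine, LSTM and the
#' parallel FM+LSTM, each rounded to 2 decimals. Used for internal
#' consistency checks (the F1 column is the harmonic mean of the printed
#' precision and recall) and for side-by-side comparison of new runs; the
#' split and hyperparameters behind these numbers are not published, so
#' they are a reference point, not a reproduction target.
#'
#' @return Tibble with `model`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' eye_state_benchmark_reference()
eye_state_benchmark_reference <- function() {
  tibble::tibble(
    model = c("DT", "RF", "LR", "SVM", "FM", "LSTM", "FM+LSTM"),
    accuracy = c(0.82, 0.88, 0.64, 0.56, 0.76, 0.89, 0.93),
    precision = c(0.82, 0.88, 0.64, 0.59, 0.80, 0.90, 0.94),
    recall = c(0.82, 0.88, 0.62, 0.50, 0.71, 0.82, 0.90),
    f1 = c(0.82, 0.88, 0.63, 0.54, 0.75, 0.86, 0.92)
  )
}

#' Compare benchmark results against the published reference
#'
#' Joins a [run_benchmark()] table with [eye_state_benchmark_reference()]
#' and reports the per-metric differences. This is a report, not an
#' assertion: the reference run's split, windowing and hyperparameters are
#' unpublished, so agreement is not expected to be exact.
#'
#' @param metrics A metrics tibble with a `model` column.
#' @return Tibble with both sets of metrics and `delta_*` columns
#'   (run minus reference).
#' @export
compare_to_reference <- function(metrics) {
  ref <- eye_state_benchmark_reference()
  joined <- dplyr::inner_join(
    round_metrics(metrics), ref, by = "model", suffix = c("", "_ref")
  )
  dplyr::mutate(joined,
    delta_accuracy = .data$accuracy - .data$accuracy_ref,
    delta_precision = .data$precision - .data$precision_ref,
    delta_recall = .data$recall - .data$recall_ref,
    delta_f1 = .data$f1 - .data$f1_ref
  )
}

# Baseline learners: standard library implementations, seeded, default
# hyperparameters. They are comparison points, not contributions.
fit_baseline <- function(name, x_train, y_train, seed) {
  df <- as.data.frame(x_train)
  df$.y <- factor(y_train, levels = c(0, 1))
  with_seed(seed, switch(name,
    DT = rpart::rpart(.y ~ ., data = df, method = "class"),
    RF = randomForest::randomForest(.y ~ ., data = df),
    # suppress glm's perfect-separation warnings: expected on separable data
    LR = suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial())),
    SVM = e1071::svm(.y ~ ., data = df),
    stop(sprintf("unknown baseline '%s'", name), call. = FALSE)
  ))
}

predict_baseline <- function(name, fit, x_test) {
  df <- as.data.frame(x_test)
  switch(name,
    DT = as.integer(as.character(stats::predict(fit, df, type = "class"))),
    RF = as.integer(as.character(stats::predict(fit, df))),
    # suppress rank-deficiency chatter from collinear band features
    LR = as.integer(suppressWarnings(stats::predict(fit, df, type = "response")) >= 0.5),
    SVM = as.integer(as.character(stats::predict(fit, df)))
  )
}

#' Benchmark all classifiers on one windowed dataset
#'
#' Trains every requested model on the same chronological training split of
#' the same wavelet band-power features and evaluates all of them on the
#' same held-out windows. `DT`, `RF`, `LR` and `SVM` are standard library
#' baselines on the dense standardized features; `FM` and `LSTM` are the
#' in-package single-branch ablations; `FM+LSTM` is the parallel hybrid.
#'
#' @param features A `window_features` tibble from [featurize_recording()].
#' @param models Character vector of model names, default all seven in
#'   reference-table order.
#' @param config A [train_config()] governing the split, encoding and the
#'   FM/LSTM/hybrid training.
#' @return A `benchmark_result` tibble: one row per model with unrounded
#'   `accuracy`, `precision`, `recall`, `f1` plus `n_test`.
#' @export
run_benchmark <- function(features,
                          models = c("DT", "RF", "LR", "SVM", "FM", "LSTM", "FM+LSTM"),
                          config = train_config()) {
  known <- c("DT", "RF", "LR", "SVM", "FM", "LSTM", "FM+LSTM")
  bad <- setdiff(models, known)
  if (length(bad) > 0) {
    stop(sprintf("unknown model name(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  data <- assemble_model_data(features, config)
  truth <- data$labels[data$test_idx]
  x_train <- data$x_dense[data$train_idx, , drop = FALSE]
  x_test <- data$x_dense[data$test_idx, , drop = FALSE]
  y_train <- data$labels[data$train_idx]
  rows <- lapply(models, function(m) {
    pred <- if (m %in% c("DT", "RF", "LR", "SVM")) {
      fit <- fit_baseline(m, x_train, y_train, seed = config$seed)
      predict_baseline(m, fit, x_test)
    } else {
      mode <- switch(m, FM = "fm", LSTM = "lstm", `FM+LSTM` = "fm_lstm")
      cfg <- config
      cfg$mode <- mode
      fit <- train_hybrid(data, cfg)
      predict(fit, type = "class")
    }
    cm <- compute_metrics(confusion_counts(pred, truth), model = m)
    dplyr::mutate(cm, n_test = length(truth))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(match(out$model, known)), ]
  structure(out, class = c("benchmark_result", class(out)))
}

#' Plot a benchmark table as grouped bars
#'
#' @param object A `benchmark_result` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot with one bar group per model and one bar per metric.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "model", "accuracy", "precision", "recall", "f1"),
    -"model", names_to = "metric", values_to = "value")
  df$model <- factor(df$model, levels = unique(object$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Eye-state classification benchmark") +
    ggplot2::theme_minimal()
}

#' Write a benchmark table as CSV and Markdown
#'
#' @param result A `benchmark_result`.
#' @param csv_path,md_path Output paths (either may be `NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_benchmark <- function(result, csv_path = NULL, md_path = NULL) {
  rounded <- round_metrics(result)
  if (!is.null(csv_path)) readr::write_csv(rounded, csv_path, progress = FALSE)
  if (!is.null(md_path)) {
    lines <- c(
      "| Algorithm/model | Accuracy | Precision | Recall | F1-measure |",
      "|---|---|---|---|---|",
      sprintf("| %s | %.2f | %.2f | %.2f | %.2f |", rounded$model,
              rounded$accuracy, rounded$precision, rounded$recall, rounded$f1)
    )
    writeLines(lines, md_path)
  }
  invisible(result)
}
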