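#' Write an EEG recording to CSV
#'
#' One row per sample: one column per channel (microvolts) followed by an
#' `eyeDetection` label column (1 = closed, 0 = open). This is the same
#' dialect [read_eeg_table()] reads and mirrors the UCI EEG Eye State CSV
#' export.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(recording, path) {
  df <- as.data.frame(t(recording$data))
  names(df) <- recording$channel_names
  df$eyeDetection <- recording$labels
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write an EEG recording to ARFF
#'
#' Emits a minimal ARFF file: one numeric attribute per channel and a nominal
#' `eyeDetection {0,1}` class attribute, matching the layout of the UCI EEG
#' Eye State distribution.
#'
#' @inheritParams write_eeg_csv
#' @return `path`, invisibly.
#' @export
write_eeg_arff <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@RELATION eeg_eye_state", con)
  for (nm in recording$channel_names) {
    writeLines(sprintf("@ATTRIBUTE %s NUMERIC", nm), con)
  }
  writeLines("@ATTRIBUTE eyeDetection {0,1}", con)
  writeLines("@DATA", con)
  rows <- apply(recording$data, 2, function(col) {
    paste(format(col, digits = 17, trim = TRUE, scientific = FALSE), collapse = ",")
  })
  writeLines(paste(rows, recording$labels, sep = ","), con)
  invisible(path)
}

#' Read labeled EEG from an ARFF or CSV table
#'
#' Expects the UCI EEG Eye State layout: 14 (or any number of) numeric
#' channel columns and one binary class column. The class column is
#' `eyeDetection` when present, otherwise the last column; its values must
#' be 0 (eyes open) or 1 (eyes closed). Channel names are taken from the
#' header / attribute names.
#'
#' @param path Path to the file.
#' @param format `"arff"`, `"csv"` or `"auto"` (by file extension).
#' @return An `eeg_recording` (see [generate_recording()]). The sampling
#'   rate defaults to 128 Hz (the rate implied by the UCI recording's 117 s
#'   duration) unless overridden.
#' @param fs Sampling rate to attach, Hz.
#' @export
read_eeg_table <- function(path, format = c("auto", "arff", "csv"), fs = 128) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  df <- if (format == "arff") {
    foreign::read.arff(path)
  } else {
    as.data.frame(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  }
  if (ncol(df) < 2L) stop("expected at least one channel column plus a class column", call. = FALSE)
  label_col <- if ("eyeDetection" %in% names(df)) "eyeDetection" else names(df)[ncol(df)]
  raw_labels <- df[[label_col]]
  labels <- suppressWarnings(as.integer(as.character(raw_labels)))
  bad <- which(is.na(labels) | !(labels %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    stop(sprintf("class attribute '%s' must be binary 0/1; offending row %d has value '%s'",
                 label_col, bad[1], as.character(raw_labels[bad[1]])), call. = FALSE)
  }
  chan <- df[setdiff(names(df), label_col)]
  for (nm in names(chan)) {
    v <- chan[[nm]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      if (any(is.na(v2) & !is.na(v))) {
        stop(sprintf("channel attribute '%s' contains non-numeric values", nm), call. = FALSE)
      }
      chan[[nm]] <- v2
    }
    if (any(is.na(chan[[nm]]))) {
      stop(sprintf("channel attribute '%s' contains missing values", nm), call. = FALSE)
    }
  }
  new_eeg_recording(t(as.matrix(chan)), fs = fs, labels = labels,
                    channel_names = names(chan), provenance = path)
}

#' Slice a recording into fixed-length labeled windows
#'
#' Produces `floor((N - window_len) / hop) + 1` windows of `window_len`
#' samples starting every `hop` samples. Each window gets one binary label:
#' under the `"majority"` rule a window is labeled 1 (closed) only when
#' strictly more than half of its samples are labeled 1, so ties break to 0
#' and the rarer closed class is never inflated by ambiguity; `"last_sample"`
#' uses the label of the window's final sample.
#'
#' @param recording An `eeg_recording`.
#' @param window_len Window length in samples (default 1 s worth).
#' @param hop Hop between window starts in samples (default half a window,
#'   i.e. 50% overlap).
#' @param label_rule `"majority"` or `"last_sample"`.
#' @return A `windowed_dataset`: list with `windows` (list of channels x
#'   window_len matrices), `labels`, `starts` (1-based start sample of each
#'   window), `window_len`, `hop`, `fs`, `channel_names`, `provenance`.
#' @export
#' @examples
#' rec <- generate_recording(synth_config(duration = 5, seed = 1))
#' wd <- window_recording(rec)
#' length(wd$windows)
window_recording <- function(recording, window_len = round(recording$fs),
                             hop = max(1L, round(window_len / 2)),
                             label_rule = c("majority", "last_sample")) {
  label_rule <- match.arg(label_rule)
  n <- ncol(recording$data)
  window_len <- as.integer(window_len)
  hop <- as.integer(hop)
  if (hop < 1L || hop > window_len) stop("need 0 < hop <= window_len", call. = FALSE)
  if (window_len > n) {
    stop(sprintf("window_len (%d) exceeds recording length (%d): empty dataset",
                 window_len, n), call. = FALSE)
  }
  starts <- seq(1L, n - window_len + 1L, by = hop)
  windows <- lapply(starts, function(s) {
    recording$data[, s:(s + window_len - 1L), drop = FALSE]
  })
  labels <- vapply(starts, function(s) {
    lab <- recording$labels[s:(s + window_len - 1L)]
    if (label_rule == "majority") {
      as.integer(sum(lab) > window_len / 2)
    } else {
      lab[window_len]
    }
  }, integer(1))
  structure(list(
    windows = windows, labels = labels, starts = starts,
    window_len = window_len, hop = hop, fs = recording$fs,
    channel_names = recording$channel_names,
    provenance = recording$provenance
  ), class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %d samples (hop %d) @ %g Hz\n",
              length(x$windows), x$window_len, x$hop, x$fs))
  cat(sprintf("  labels: %.1f%% closed\n", 100 * mean(x$labels)))
  invisible(x)
}
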