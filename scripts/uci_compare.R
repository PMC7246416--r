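#!/usr/bin/env Rscript
# OPTIONAL real-data comparison. Runs the full benchmark on a locally
# downloaded copy of the UCI "EEG Eye State" recording and prints the
# side-by-side deltas against the published reference metrics. This is a
# report, not a test: the reference run's train/test split, windowing and
# hyperparameters are unpublished, so agreement is not asserted.
#
# Usage:
#   Rscript scripts/uci_compare.R /path/to/EEG_Eye_State.arff [seed]
#
# The dataset is available from
# http://archive.ics.uci.edu/ml/datasets/EEG+eye+state (ARFF; a CSV export
# with an `eyeDetection` column works too).

suppressPackageStartupMessages(library(wavefm))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript scripts/uci_compare.R <path-to-arff-or-csv> [seed]")
}
path <- args[[1]]
seed <- if (length(args) >= 2) as.integer(args[[2]]) else 1L

message("reading ", path)
rec <- read_eeg_table(path)
message(sprintf("%d channels x %d samples, %.1f%% closed",
                nrow(rec$data), ncol(rec$data), 100 * mean(rec$labels)))

# The raw recording contains a handful of large transient artifacts; clip
# channels to a robust range so the quantile bins are not dominated by them.
for (ch in seq_len(nrow(rec$data))) {
  q <- stats::quantile(rec$data[ch, ], c(0.001, 0.999))
  rec$data[ch, ] <- pmin(pmax(rec$data[ch, ], q[1]), q[2])
}

feats <- featurize_recording(rec)
bm <- run_benchmark(feats, config = train_config(seed = seed))
cat("\nThis run (rounded):\n")
print(round_metrics(bm))
cat("\nComparison against the published reference (delta = run - reference):\n")
print(as.data.frame(compare_to_reference(bm)))
cat("\nNote: differences are expected; the reference pipeline's split and\n")
cat("hyperparameters are not published.\n")
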