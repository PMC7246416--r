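test_that("confusion counts enumerate the four cells with closed as positive", {
  cc <- confusion_counts(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 2, TN = 2, FP = 0, FN = 0))
  cc2 <- confusion_counts(1 - c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(cc2$TP + cc2$TN, 0)
  cc3 <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unlist(cc3[c("TP", "FP", "TN", "FN")]), c(TP = 2, FP = 1, TN = 1, FN = 1))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("metrics follow their defining ratios including degenerate conventions", {
  perfect <- compute_metrics(confusion_counts(rep(c(1, 0), 5), rep(c(1, 0), 5)))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  m <- compute_metrics(confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1)))
  expect_equal(m$accuracy, 0.6)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  # all-negative predictions with positives present: precision 0 by convention
  expect_warning(m0 <- compute_metrics(confusion_counts(c(0, 0, 0), c(1, 1, 0))),
                 "precision")
  expect_equal(m0$precision, 0)
  expect_equal(m0$recall, 0)
  expect_equal(m0$f1, 0)
})

test_that("f1 is the harmonic mean with the printed reference rows as fixtures", {
  expect_equal(round(f1_measure(0.94, 0.90), 2), 0.92)
  expect_equal(round(f1_measure(0.80, 0.71), 2), 0.75)
  expect_equal(f1_measure(0.7, 0.7), 0.7)
  expect_equal(f1_measure(0, 0), 0)
  ref <- eye_state_benchmark_reference()
  expect_equal(round(f1_measure(ref$precision, ref$recall), 2), ref$f1)
})

test_that("benchmark rows are internally consistent and ordered", {
  feats <- separable_features(duration = 40, seed = 2)
  bm <- run_benchmark(feats, models = c("LR", "DT", "FM"),
                      config = train_config(epochs = 5, seed = 2))
  expect_equal(bm$model, c("DT", "LR", "FM"))  # canonical row order
  expect_equal(nrow(bm), 3)
  expect_true(all(vapply(bm[c("accuracy", "precision", "recall", "f1")],
                         function(v) all(v >= 0 & v <= 1), logical(1))))
  expect_equal(bm$f1, f1_measure(bm$precision, bm$recall), tolerance = 1e-12)
  expect_error(run_benchmark(feats, models = c("DT", "XGB")), "unknown model")
})

test_that("reference comparison reports deltas without asserting agreement", {
  fake <- tibble::tibble(model = c("FM+LSTM", "DT"),
                         accuracy = c(0.5, 0.99), precision = c(0.5, 0.99),
                         recall = c(0.5, 0.99), f1 = c(0.5, 0.99))
  cmp <- compare_to_reference(fake)
  expect_equal(nrow(cmp), 2)
  expect_true(all(c("delta_accuracy", "delta_f1") %in% names(cmp)))
  # wildly different metrics still just produce a report
  expect_equal(cmp$delta_accuracy[cmp$model == "FM+LSTM"], 0.5 - 0.93)
})

test_that("rounding is half-up at two decimals as in the reference table", {
  m <- tibble::tibble(model = "x", accuracy = 0.925, precision = 0.924999,
                      recall = 0.915, f1 = 0.91501)
  r <- round_metrics(m)
  expect_equal(unlist(r[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.93, precision = 0.92, recall = 0.92, f1 = 0.92))
})

test_that("benchmark output writers emit csv and markdown tables", {
  bm <- structure(tibble::tibble(
    model = c("DT", "FM+LSTM"), accuracy = c(0.8211, 0.93),
    precision = c(0.82, 0.94), recall = c(0.82, 0.90), f1 = c(0.82, 0.92),
    n_test = c(68L, 68L)), class = c("benchmark_result", class(tibble::tibble())))
  csvf <- tempfile(fileext = ".csv"); mdf <- tempfile(fileext = ".md")
  write_benchmark(bm, csvf, mdf)
  back <- readr::read_csv(csvf, show_col_types = FALSE)
  expect_equal(back$accuracy, c(0.82, 0.93))
  md <- readLines(mdf)
  expect_match(md[1], "Algorithm/model")
  expect_length(md, 4)
  expect_s3_class(autoplot(bm), "ggplot")
})
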