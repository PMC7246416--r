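feats60 <- separable_features(duration = 60, seed = 1)

test_that("logloss hits its anchors, symmetry and clipping", {
  expect_equal(logloss(0.5, 1), log(2))
  expect_equal(logloss(0.5, 0), log(2))
  expect_lte(logloss(1, 1), 1e-11)   # clipped at 1 - 1e-12
  expect_lte(logloss(0, 0), 1e-11)
  p <- runif(20)
  expect_equal(logloss(p, 1), logloss(1 - p, 0), tolerance = 1e-12)
  expect_error(logloss(0.5, 2), "0/1")
})

test_that("classification thresholds are monotone with ties going to closed", {
  expect_identical(classify(0.5, 0.5), 1L)
  expect_identical(classify(0.6225, 0.5), 1L)
  expect_identical(classify(0.49, 0.5), 0L)
  p <- runif(100)
  n_pred <- vapply(c(0.8, 0.5, 0.2), function(th) sum(classify(p, th)), integer(1))
  expect_true(all(diff(n_pred) >= 0))
  expect_error(classify(0.5, 1), "threshold")
})

test_that("zero-initialized hybrid predicts sigmoid(0.5) and saturates monotonically", {
  fm <- fm_params(12, k = 2, seed = 1)
  fm$V[] <- 0
  lstm <- lstm_params(4, 3, seed = 1)
  for (nm in c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o", "W_t", "b_t")) {
    lstm[[nm]][] <- 0
  }
  model <- list(fm = fm, lstm = lstm, fusion = "literal", mode = "fm_lstm")
  x <- numeric(12); x[c(2, 5)] <- 1
  seqm <- matrix(rnorm(12), 3, 4)
  p <- predict_proba(model, x, seqm)
  expect_equal(round(p, 4), 0.6225)
  # inject increasing FM biases: probability is monotone and saturates
  probs <- vapply(c(-30, -5, 0, 5, 30), function(b) {
    m <- model; m$fm$w0 <- b
    predict_proba(m, x, seqm)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_lt(probs[1], 1e-10)
  expect_gt(probs[5], 1 - 1e-10)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("fused end-to-end gradient matches finite differences", {
  set.seed(31)
  n_cols <- 9; l_seq <- 3; input <- 2; n_samp <- 4
  data <- structure(list(
    design = structure(list(
      active = cbind(sample(1:3, n_samp, TRUE), sample(4:6, n_samp, TRUE),
                     sample(7:9, n_samp, TRUE)),
      n_rows = n_samp, n_cols = n_cols, field_offsets = c(0L, 3L, 6L),
      feature_names = c("a", "b", "c")), class = "sparse_design"),
    seq_array = array(rnorm(l_seq * input * n_samp), c(l_seq, input, n_samp)),
    labels = c(1, 0, 1, 0)
  ), class = "model_data")
  cfg <- train_config(sequence_len = l_seq, latent_k = 2, hidden_size = 2)
  fm <- fm_params(n_cols, 2, seed = 32)
  fm$w <- rnorm(n_cols, sd = 0.3)
  lstm <- lstm_params(input, 2, seed = 33)
  loss_fn <- function(fm_, lstm_) {
    fwd <- wavefm:::hybrid_forward(fm_, lstm_, data, 1:n_samp, cfg)
    mean(logloss(fwd$p, data$labels))
  }
  fwd <- wavefm:::hybrid_forward(fm, lstm, data, 1:n_samp, cfg, keep_cache = TRUE)
  resid <- (fwd$p - data$labels) / n_samp
  g_fm <- list(w0 = 0, w = numeric(n_cols), V = matrix(0, n_cols, 2))
  for (j in 1:n_samp) {
    gi <- fm_gradient(data$design, fm, upstream = resid[j], row = j)
    g_fm$w0 <- g_fm$w0 + gi$w0
    g_fm$w[gi$idx] <- g_fm$w[gi$idx] + gi$w
    g_fm$V[gi$idx, ] <- g_fm$V[gi$idx, ] + gi$V
  }
  g_lstm <- wavefm:::lstm_gradients_batch(fwd$lstm_out, lstm, resid)
  h <- 1e-5
  for (nm in c("w0", "w", "V")) {
    for (idx in seq_along(fm[[nm]])) {
      fp <- fm; fp[[nm]][idx] <- fp[[nm]][idx] + h
      fmm <- fm; fmm[[nm]][idx] <- fmm[[nm]][idx] - h
      fd <- (loss_fn(fp, lstm) - loss_fn(fmm, lstm)) / (2 * h)
      expect_lt(rel_err(fd, g_fm[[nm]][idx]), 1e-5)
    }
  }
  for (nm in c("W_f", "W_c", "b_o", "W_t", "b_t")) {
    for (idx in seq_along(lstm[[nm]])) {
      lp <- lstm; lp[[nm]][idx] <- lp[[nm]][idx] + h
      lm <- lstm; lm[[nm]][idx] <- lm[[nm]][idx] - h
      fd <- (loss_fn(fm, lp) - loss_fn(fm, lm)) / (2 * h)
      expect_lt(rel_err(fd, g_lstm[[nm]][idx]), 1e-5)
    }
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  cfg <- train_config(epochs = 3, seed = 5)
  f1 <- train_hybrid(feats60, cfg)
  f2 <- train_hybrid(feats60, cfg)
  expect_identical(f1$fm, f2$fm)
  expect_identical(f1$lstm, f2$lstm)
  expect_identical(f1$trace, f2$trace)
})

test_that("full-batch gradient descent reduces the loss monotonically after burn-in", {
  fit <- train_hybrid(feats60, train_config(
    optimizer = "sgd", learning_rate = 0.05, epochs = 200, batch_size = Inf, seed = 1))
  tr <- tidy(fit)$train_loss
  expect_lt(tr[length(tr)], tr[1])
  expect_lte(max(diff(tr[10:length(tr)])), 1e-8)
})

test_that("the trained hybrid classifies held-out synthetic windows accurately", {
  fit <- train_hybrid(feats60, train_config(seed = 1))
  g <- glance(fit)
  expect_gte(g$test_accuracy, 0.90)
  expect_lt(g$train_loss, 0.1)
  p <- predict(fit, type = "prob")
  # confident logits saturate the sigmoid to the representable endpoints
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predict(fit, type = "class"), classify(p, 0.5))
})

test_that("single-class training data is rejected", {
  rec <- generate_recording(synth_config(duration = 30, seed = 2,
                                         mean_block_len = 1000))
  expect_length(unique(rec$labels), 1L)
  feats <- featurize_recording(rec)
  expect_error(train_hybrid(feats, train_config(epochs = 1)), "single class")
})

test_that("fm-only and lstm-only ablations run from the same trainer", {
  cfg <- train_config(epochs = 10, seed = 2)
  data <- assemble_model_data(feats60, cfg)
  for (mode in c("fm", "lstm")) {
    cfg_m <- cfg; cfg_m$mode <- mode
    fit <- train_hybrid(data, cfg_m)
    expect_s3_class(fit, "hybrid_fit")
    expect_equal(fit$mode, mode)
    expect_length(predict(fit), length(data$test_idx))
  }
  # logit fusion also trains
  cfg_l <- cfg; cfg_l$fusion <- "logit"
  fit_l <- train_hybrid(data, cfg_l)
  expect_lt(dplyr::last(tidy(fit_l)$train_loss), tidy(fit_l)$train_loss[1])
})

test_that("plain gradient descent concentrates linear weight on alpha-band bins", {
  # diagnostic uses sgd: adaptive optimizers normalize per-parameter step
  # sizes and erase the gradient-magnitude signal this proxy reads out
  hits <- 0
  for (s in 1:5) {
    feats <- separable_features(duration = 117, seed = s)
    fit <- train_hybrid(feats, train_config(
      mode = "fm", optimizer = "sgd", learning_rate = 0.5, epochs = 100,
      batch_size = Inf, seed = s))
    w <- fit$fm$w
    field_of <- rep(fit$bins$feature_names, times = fit$bins$n_bins_per_feature)
    if (grepl("alpha", field_of[which.max(abs(w))])) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- train_hybrid(feats60, train_config(epochs = 4, seed = 3))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "train_loss", "test_loss"))
  expect_equal(nrow(td), 4)
  g <- glance(fit)
  expect_equal(g$epochs, 4)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("checkpoints restore a model that predicts identically", {
  fit <- train_hybrid(feats60, train_config(epochs = 3, seed = 9))
  path <- tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  ck <- read_checkpoint(path)
  expect_equal(ck$fm$w, fit$fm$w, tolerance = 1e-14)
  expect_equal(ck$lstm$W_c, fit$lstm$W_c, tolerance = 1e-14)
  expect_equal(ck$bins$edges, fit$bins$edges)
  i <- fit$data$test_idx[1]
  p_orig <- predict(fit, indices = i)
  p_ck <- predict_proba(ck, fit$data$design, fit$data$seq_array[, , i], row = i)
  expect_equal(p_ck, p_orig, tolerance = 1e-12)
})
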