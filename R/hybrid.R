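#' Training configuration for the hybrid model
#'
#' Collects everything the trainer needs. Defaults: Adam at learning rate
#' 1e-2, 100 epochs, batches of 64, latent dimension 8, hidden size 32,
#' 10 quantile bins per feature, sequences of the last 8 windows, a
#' chronological 70/30 train/test split (no shuffling across the time
#' boundary, so overlapping windows never leak between splits), and the
#' literal fusion `sigmoid(y_FM + y_LSTM)` where `y_LSTM` is itself already
#' a sigmoid output.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Positive step size.
#' @param epochs Number of passes over the training split.
#' @param batch_size Minibatch size (`Inf` = full batch).
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param sequence_len Number of consecutive windows fed to the LSTM
#'   (default 8).
#' @param train_fraction Fraction of windows (chronologically first) used
#'   for training, in (0, 1).
#' @param latent_k FM latent dimension.
#' @param hidden_size LSTM hidden units.
#' @param n_bins Quantile bins per feature for the one-hot design.
#' @param fusion `"literal"` (sigmoid of the sum, with the LSTM branch
#'   already sigmoid-activated) or `"logit"` (sum the two pre-sigmoid
#'   scores, then one sigmoid).
#' @param mode `"fm_lstm"` (the hybrid), `"fm"` or `"lstm"` (single-branch
#'   ablations sharing the same data plumbing).
#' @param lstm_input `"dense"` (standardized band-feature vectors, default)
#'   or `"onehot"` (the sparse one-hot rows) as the LSTM's per-window input.
#' @param threshold Decision cutoff on the predicted probability
#'   (default 0.5); ties classify as closed.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 1e-2,
                         epochs = 100, batch_size = 64, seed = 1L,
                         sequence_len = 8, train_fraction = 0.7,
                         latent_k = 8, hidden_size = 32, n_bins = 10,
                         fusion = c("literal", "logit"),
                         mode = c("fm_lstm", "fm", "lstm"),
                         lstm_input = c("dense", "onehot"),
                         threshold = 0.5) {
  optimizer <- match.arg(optimizer)
  fusion <- match.arg(fusion)
  mode <- match.arg(mode)
  lstm_input <- match.arg(lstm_input)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)", call. = FALSE)
  structure(list(
    optimizer = optimizer, learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = batch_size, seed = as.integer(seed),
    sequence_len = as.integer(sequence_len), train_fraction = train_fraction,
    latent_k = as.integer(latent_k), hidden_size = as.integer(hidden_size),
    n_bins = as.integer(n_bins), fusion = fusion, mode = mode,
    lstm_input = lstm_input, threshold = threshold
  ), class = "train_config")
}

#' Binary cross-entropy (logloss)
#'
#' `-(y log p + (1 - y) log(1 - p))`, with `p` clipped to
#' `[1e-12, 1 - 1e-12]` so a saturated prediction never produces an
#' infinite loss.
#'
#' @param p Predicted probability (vector ok).
#' @param y Observed label(s) in {0, 1}.
#' @return Nonnegative loss, elementwise.
#' @export
#' @examples
#' logloss(0.5, 1)  # log(2)
logloss <- function(p, y) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Threshold a probability into an eye-state label
#'
#' Returns 1 (closed) when `p >= threshold`, so a tie at the threshold
#' classifies as closed.
#'
#' @param p Probability vector.
#' @param threshold Cutoff in (0, 1).
#' @return Integer 0/1 vector.
#' @export
classify <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)", call. = FALSE)
  as.integer(p >= threshold)
}

#' Fused FM+LSTM probability for one window
#'
#' The parallel fusion: the factorization machine scores the current
#' window's one-hot row, the LSTM scores the sequence of recent windows,
#' and the two branch outputs are summed and squashed,
#' `p = sigmoid(y_FM + y_LSTM)`. In the default literal fusion `y_LSTM` is
#' the LSTM's own sigmoid output in (0, 1) — the composition as published —
#' so a freshly zero-initialized model predicts `sigmoid(0.5) ~ 0.6225`.
#' With `fusion = "logit"` the LSTM's pre-sigmoid score is summed instead.
#'
#' @param model A `hybrid_fit` (or a bare list with `fm`, `lstm`, `fusion`,
#'   `mode`).
#' @param x One-hot input for the FM branch: a `sparse_design` row (pass
#'   `row`) or dense numeric vector.
#' @param sequence Matrix (sequence_len x input_size) for the LSTM branch.
#' @param row Row of `x` to score when `x` is a `sparse_design`.
#' @return Probability in (0, 1).
#' @export
predict_proba <- function(model, x, sequence, row = 1L) {
  mode <- model$mode %||% "fm_lstm"
  fusion <- model$fusion %||% "literal"
  y_fm <- if (mode != "lstm") fm_score(x, model$fm, row = row) else 0
  if (mode == "fm") return(as.numeric(sigmoid(y_fm)))
  fw <- lstm_forward(sequence, model$lstm, keep_cache = FALSE)
  y_lstm <- if (fusion == "literal") fw$y else fw$z_out
  if (mode == "lstm") return(fw$y)
  as.numeric(sigmoid(y_fm + y_lstm))
}

#' Assemble model-ready data from window features
#'
#' Chronological plumbing shared by the trainer and the benchmark harness:
#' widens the per-window band powers to a feature matrix, standardizes with
#' training-split statistics, fits quantile bins on the training rows only
#' and one-hot encodes everything, and builds the per-window sequences of
#' the trailing `sequence_len` windows. The first `sequence_len - 1` windows
#' have no full history and are dropped from both branches so every model
#' sees identical samples.
#'
#' @param features A `window_features` tibble from [featurize_recording()].
#' @param config A [train_config()].
#' @return A `model_data` list: `x_dense` (standardized features), `design`
#'   (`sparse_design`), `seq_array` (sequence_len x input x windows),
#'   `labels`, `train_idx`, `test_idx`, `bins`, `scaler`, `windows`.
#' @export
assemble_model_data <- function(features, config = train_config()) {
  fm_ <- feature_matrix(features)
  l_seq <- config$sequence_len
  n_all <- nrow(fm_$x)
  if (n_all < l_seq + 2) stop("too few windows for the requested sequence length", call. = FALSE)
  usable <- l_seq:n_all
  n_use <- length(usable)
  n_train <- floor(config$train_fraction * n_use)
  if (n_train < 1 || n_train >= n_use) stop("degenerate train/test split", call. = FALSE)
  train_windows <- usable[seq_len(n_train)]
  raw <- fm_$x
  mu <- colMeans(raw[train_windows, , drop = FALSE])
  sd_ <- apply(raw[train_windows, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  x_std <- sweep(sweep(raw, 2, mu), 2, sd_, "/")
  bins <- fit_bins(raw[train_windows, , drop = FALSE], n_bins = config$n_bins)
  design <- one_hot_encode(raw, bins)
  input_size <- if (config$lstm_input == "dense") ncol(raw) else design$n_cols
  seq_array <- array(0, dim = c(l_seq, input_size, n_use))
  for (ii in seq_along(usable)) {
    w <- usable[ii]
    rows <- (w - l_seq + 1):w
    seq_array[, , ii] <- if (config$lstm_input == "dense") {
      x_std[rows, , drop = FALSE]
    } else {
      m <- matrix(0, l_seq, design$n_cols)
      for (r in seq_along(rows)) m[r, design$active[rows[r], ]] <- 1
      m
    }
  }
  structure(list(
    x_dense = x_std[usable, , drop = FALSE],
    x_raw = raw[usable, , drop = FALSE],
    design = one_hot_encode(raw[usable, , drop = FALSE], bins),
    seq_array = seq_array,
    labels = fm_$labels[usable],
    train_idx = seq_len(n_train),
    test_idx = (n_train + 1):n_use,
    bins = bins, scaler = list(mean = mu, sd = sd_),
    windows = usable
  ), class = "model_data")
}

# Adam/SGD update helper operating on a named list of parameter arrays.
make_optimizer <- function(config, shapes) {
  state <- lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
  t_step <- 0
  list(
    step = function(params, grads) {
      if (config$optimizer == "sgd") {
        for (nm in names(grads)) params[[nm]] <- params[[nm]] - config$learning_rate * grads[[nm]]
        return(params)
      }
      t_step <<- t_step + 1
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (nm in names(grads)) {
        state[[nm]]$m <<- b1 * state[[nm]]$m + (1 - b1) * grads[[nm]]
        state[[nm]]$v <<- b2 * state[[nm]]$v + (1 - b2) * grads[[nm]]^2
        mhat <- state[[nm]]$m / (1 - b1^t_step)
        vhat <- state[[nm]]$v / (1 - b2^t_step)
        upd <- config$learning_rate * mhat / (sqrt(vhat) + eps)
        if (is.null(dim(params[[nm]]))) upd <- as.numeric(upd)
        params[[nm]] <- params[[nm]] - upd
      }
      params
    }
  )
}

# Batched forward over sample indices; returns branch outputs and cached
# LSTM states.
hybrid_forward <- function(fm, lstm, data, idx, config, keep_cache = FALSE) {
  y_fm <- if (config$mode != "lstm") {
    vapply(idx, function(i) fm_score(data$design, fm, row = i), numeric(1))
  } else rep(0, length(idx))
  lstm_out <- NULL
  y_lstm <- rep(0, length(idx))
  if (config$mode != "fm") {
    input_size <- dim(data$seq_array)[2]
    x_seq <- lapply(seq_len(config$sequence_len), function(t) {
      matrix(data$seq_array[t, , idx], nrow = input_size)
    })
    lstm_out <- lstm_forward_batch(x_seq, lstm, keep_cache = keep_cache)
    y_lstm <- if (config$fusion == "literal") lstm_out$y else lstm_out$z_out
  }
  p <- switch(config$mode,
    fm = sigmoid(y_fm),
    lstm = sigmoid(lstm_out$z_out),
    fm_lstm = sigmoid(y_fm + y_lstm)
  )
  list(p = as.numeric(p), y_fm = y_fm, lstm_out = lstm_out)
}

#' Train the parallel FM+LSTM eye-state model
#'
#' Joint gradient training of both branches against logloss: the fused
#' probability's error signal backpropagates through the sigmoid into the
#' factorization machine (via its sparse analytic gradients) and through
#' the LSTM (via backpropagation through time) simultaneously. The split is
#' chronological, batches are shuffled only within the training span, and
#' the run is fully seeded: the same configuration reproduces bit-identical
#' parameters.
#'
#' @param features A `window_features` tibble from [featurize_recording()],
#'   or a pre-assembled `model_data`.
#' @param config A [train_config()].
#' @return A `hybrid_fit`: list with `fm`, `lstm`, `config`, `bins`,
#'   `scaler`, `trace` (tibble: epoch, train_loss, test_loss), `data`
#'   (the `model_data` used), `mode`, `fusion`, `threshold`.
#' @export
#' @examples
#' \donttest{
#' rec <- generate_recording(synth_config(duration = 30, seed = 1))
#' fit <- train_hybrid(featurize_recording(rec),
#'                     train_config(epochs = 5, seed = 1))
#' glance(fit)
#' }
train_hybrid <- function(features, config = train_config()) {
  data <- if (inherits(features, "model_data")) features else
    assemble_model_data(features, config)
  labels <- data$labels
  if (length(unique(labels[data$train_idx])) < 2L) {
    stop("training split contains a single class; cannot train", call. = FALSE)
  }
  fm <- fm_params(data$design$n_cols, k = config$latent_k, seed = config$seed)
  input_size <- dim(data$seq_array)[2]
  lstm <- lstm_params(input_size, config$hidden_size, seed = config$seed + 1L)
  fm_names <- c("w0", "w", "V")
  lstm_names <- c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o", "W_t", "b_t")
  opt_fm <- make_optimizer(config, lapply(fm[fm_names], function(p) dim(p) %||% length(p)))
  opt_lstm <- make_optimizer(config, lapply(lstm[lstm_names], function(p) dim(p) %||% length(p)))
  n_train <- length(data$train_idx)
  bs <- min(config$batch_size, n_train)
  trace <- vector("list", config$epochs)
  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(data$train_idx)
      for (b0 in seq(1, n_train, by = bs)) {
        idx <- ord[b0:min(b0 + bs - 1, n_train)]
        fwd <- hybrid_forward(fm, lstm, data, idx, config, keep_cache = TRUE)
        resid <- (fwd$p - labels[idx]) / length(idx)   # d(mean logloss)/d(fused logit)
        if (config$mode != "lstm") {
          g <- list(w0 = 0, w = numeric(fm$n), V = matrix(0, fm$n, fm$k))
          for (jj in seq_along(idx)) {
            gi <- fm_gradient(data$design, fm, upstream = resid[jj], row = idx[jj])
            g$w0 <- g$w0 + gi$w0
            g$w[gi$idx] <- g$w[gi$idx] + gi$w
            g$V[gi$idx, ] <- g$V[gi$idx, ] + gi$V
          }
          fm[fm_names] <- opt_fm$step(fm[fm_names], g)
        }
        if (config$mode != "fm") {
          gl <- if (config$fusion == "literal" && config$mode == "fm_lstm") {
            lstm_gradients_batch(fwd$lstm_out, lstm, resid)
          } else {
            # lstm-only and logit fusion: residual applies to the pre-sigmoid
            # readout directly
            lstm_gradients_logit(fwd$lstm_out, lstm, resid)
          }
          lstm[lstm_names] <- opt_lstm$step(lstm[lstm_names], gl)
        }
      }
      tr <- hybrid_forward(fm, lstm, data, data$train_idx, config)
      te <- hybrid_forward(fm, lstm, data, data$test_idx, config)
      trace[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = mean(logloss(tr$p, labels[data$train_idx])),
        test_loss = mean(logloss(te$p, labels[data$test_idx]))
      )
    }
  })
  structure(list(
    fm = fm, lstm = lstm, config = config, bins = data$bins,
    scaler = data$scaler, trace = dplyr::bind_rows(trace), data = data,
    mode = config$mode, fusion = config$fusion, threshold = config$threshold
  ), class = "hybrid_fit")
}

#' @export
print.hybrid_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<hybrid_fit> mode=%s fusion=%s | %d epochs, final train loss %.4f, test loss %.4f\n",
              x$mode, x$fusion, nrow(x$trace), last$train_loss, last$test_loss))
  invisible(x)
}

#' Predict probabilities or labels from a fitted hybrid model
#'
#' @param object A `hybrid_fit`.
#' @param newdata Optional `model_data`; defaults to the data the model was
#'   trained on.
#' @param indices Sample indices to predict (default: the held-out test
#'   split).
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @return Numeric probabilities or integer 0/1 labels.
#' @export
predict.hybrid_fit <- function(object, newdata = NULL, indices = NULL,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  data <- newdata %||% object$data
  indices <- indices %||% data$test_idx
  p <- hybrid_forward(object$fm, object$lstm, data, indices, object$config)$p
  if (type == "prob") p else classify(p, object$threshold)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch loss trace of a fitted hybrid model
#'
#' @param x A `hybrid_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `test_loss`.
#' @method tidy hybrid_fit
#' @export
tidy.hybrid_fit <- function(x, ...) x$trace

#' One-row summary of a fitted hybrid model
#'
#' @param x A `hybrid_fit`.
#' @param ... Unused.
#' @return Tibble with mode, fusion, epochs, final losses and held-out
#'   accuracy.
#' @method glance hybrid_fit
#' @export
glance.hybrid_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  pred <- predict(x, type = "class")
  truth <- x$data$labels[x$data$test_idx]
  tibble::tibble(
    mode = x$mode, fusion = x$fusion, epochs = nrow(x$trace),
    train_loss = last$train_loss, test_loss = last$test_loss,
    test_accuracy = mean(pred == truth),
    n_train = length(x$data$train_idx), n_test = length(x$data$test_idx)
  )
}

#' Plot the training loss trace
#'
#' @param object A `hybrid_fit`.
#' @param ... Unused.
#' @return A ggplot of train and held-out logloss per epoch.
#' @method autoplot hybrid_fit
#' @export
autoplot.hybrid_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "split", values_to = "logloss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$logloss,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "logloss", color = NULL,
                  title = sprintf("%s training trace", object$mode)) +
    ggplot2::theme_minimal()
}

#' Checkpoint a fitted hybrid model to JSON
#'
#' Stores both parameter bundles (FM bias/linear/latent arrays, LSTM gate
#' matrices and readout), the fitted bin edges, the feature scaler and the
#' training configuration as a flat JSON bundle with explicit shapes, so a
#' fit can be restored in a fresh session at full serialization precision
#' (the windowed data itself is not stored).
#'
#' @param fit A `hybrid_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "hybrid_fit"))
  pack <- function(x) list(dim = dim(x) %||% length(x), data = as.numeric(x))
  lstm_names <- c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o",
                  "W_t", "b_t")
  jsonlite::write_json(list(
    fm = c(lapply(fit$fm[c("w0", "w", "V")], pack),
           list(n = fit$fm$n, k = fit$fm$k)),
    lstm = c(lapply(fit$lstm[lstm_names], pack),
             list(hidden_size = fit$lstm$hidden_size,
                  input_size = fit$lstm$input_size)),
    bins = list(edges = fit$bins$edges, feature_names = fit$bins$feature_names),
    scaler = fit$scaler,
    config = unclass(fit$config),
    mode = fit$mode, fusion = fit$fusion, threshold = fit$threshold
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a checkpointed hybrid model
#'
#' @param path Path written by [write_checkpoint()].
#' @return A list with `fm` (`fm_params`), `lstm` (`lstm_params`), `bins`
#'   (`bin_spec`), `scaler`, `config` (`train_config`), `mode`, `fusion`,
#'   `threshold` — sufficient for [predict_proba()] on new windows.
#' @export
read_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  unpack <- function(p) {
    d <- unlist(p$dim)
    v <- as.numeric(unlist(p$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  fm <- structure(list(
    w0 = unpack(raw$fm$w0), w = unpack(raw$fm$w), V = unpack(raw$fm$V),
    n = as.integer(raw$fm$n), k = as.integer(raw$fm$k)
  ), class = "fm_params")
  lstm_names <- c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o",
                  "W_t", "b_t")
  lstm <- structure(c(
    lapply(raw$lstm[lstm_names], unpack),
    list(hidden_size = as.integer(raw$lstm$hidden_size),
         input_size = as.integer(raw$lstm$input_size))
  ), class = "lstm_params")
  edges <- lapply(raw$bins$edges, function(e) as.numeric(unlist(e)))
  n_per <- vapply(edges, length, integer(1)) + 1L
  bins <- structure(list(
    edges = edges,
    feature_names = as.character(unlist(raw$bins$feature_names)),
    n_bins_per_feature = n_per,
    field_offsets = c(0L, cumsum(n_per))[seq_along(edges)],
    n_cols = sum(n_per)
  ), class = "bin_spec")
  cfg <- raw$config
  cfg$batch_size <- if (is.character(cfg$batch_size)) Inf else cfg$batch_size
  config <- do.call(train_config, cfg)
  list(fm = fm, lstm = lstm, bins = bins,
       scaler = lapply(raw$scaler, function(v) as.numeric(unlist(v))),
       config = config, mode = raw$mode, fusion = raw$fusion,
       threshold = raw$threshold)
}
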