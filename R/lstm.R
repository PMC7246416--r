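#' Activation functions
#'
#' `sigmoid(x) = 1/(1 + e^{-x})` maps to (0,1) and gates the LSTM;
#' `tanh_act(x) = (1 - e^{-2x})/(1 + e^{-2x})` maps to (-1,1) and squashes
#' the candidate and cell output. Both saturate instead of overflowing for
#' |x| up to several hundred.
#'
#' @param x Numeric vector/matrix.
#' @return Values in (0,1) for `sigmoid`, (-1,1) for `tanh_act`.
#' @export
#' @examples
#' sigmoid(0)
#' tanh_act(0)
#' @name activations
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  dim(out) <- dim(x)
  out
}

#' @rdname activations
#' @export
tanh_act <- function(x) tanh(x)  # base tanh is the stable evaluation of (1-e^{-2x})/(1+e^{-2x})

#' Initialize LSTM parameters
#'
#' A single-layer LSTM with forget (`f`), input (`i`) and output (`o`)
#' sigmoid gates and a tanh candidate, each acting on the concatenation
#' `[h_{t-1}, x_t]`, followed by a scalar affine+sigmoid readout of the
#' final hidden state. Weights start at small Gaussian values; the forget
#' gate bias starts at +1 (the standard stabilizer that begins training
#' with the cell remembering).
#'
#' @param input_size Length of each input vector x_t.
#' @param hidden_size Number of hidden units (default 32).
#' @param init_sd SD of the Gaussian weight initialization (default 0.1).
#' @param forget_bias Initial forget-gate bias (default 1).
#' @param seed RNG seed.
#' @return An `lstm_params` with gate matrices `W_f, W_i, W_c, W_o`
#'   (hidden x (hidden+input)), biases `b_f, b_i, b_c, b_o`, readout
#'   `W_t` (1 x hidden) and `b_t`, plus sizes.
#' @export
lstm_params <- function(input_size, hidden_size = 32, init_sd = 0.1,
                        forget_bias = 1, seed = 1L) {
  stopifnot(input_size >= 1, hidden_size >= 1)
  h <- as.integer(hidden_size); d <- as.integer(input_size)
  with_seed(seed, {
    mk <- function() matrix(stats::rnorm(h * (h + d), sd = init_sd), h, h + d)
    structure(list(
      W_f = mk(), W_i = mk(), W_c = mk(), W_o = mk(),
      b_f = rep(forget_bias, h), b_i = numeric(h), b_c = numeric(h),
      b_o = numeric(h),
      W_t = matrix(stats::rnorm(h, sd = init_sd), 1, h), b_t = 0,
      hidden_size = h, input_size = d
    ), class = "lstm_params")
  })
}

#' @export
print.lstm_params <- function(x, ...) {
  cat(sprintf("<lstm_params> input %d -> hidden %d -> scalar sigmoid output\n",
              x$input_size, x$hidden_size))
  invisible(x)
}

# Zero state; `batch` columns.
lstm_zero_state <- function(params, batch = 1L) {
  list(h = matrix(0, params$hidden_size, batch),
       c = matrix(0, params$hidden_size, batch))
}

as_batch_matrix <- function(x, nrow_expect, what) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) != nrow_expect) {
    stop(sprintf("%s has %d rows, expected %d", what, nrow(x), nrow_expect),
         call. = FALSE)
  }
  x
}

#' One LSTM cell step
#'
#' Applies the gate equations
#' `f = sigmoid(W_f [h, x] + b_f)`, `i = sigmoid(W_i [h, x] + b_i)`,
#' `c_tilde = tanh(W_c [h, x] + b_c)`, `C_t = f * C_{t-1} + i * c_tilde`,
#' `o = sigmoid(W_o [h, x] + b_o)`, `H_t = o * tanh(C_t)` (all elementwise).
#'
#' @param x_t Input vector (length `input_size`) or matrix
#'   (`input_size` x batch).
#' @param state List with `h` and `c` (vectors or hidden x batch matrices);
#'   defaults to zeros.
#' @param params An [lstm_params()].
#' @return List with `state` (new `h`, `c`) and `gates`
#'   (`f`, `i`, `o`, `c_tilde`).
#' @export
lstm_cell_step <- function(x_t, state = NULL, params) {
  stopifnot(inherits(params, "lstm_params"))
  x_t <- as_batch_matrix(x_t, params$input_size, "x_t")
  if (is.null(state)) state <- lstm_zero_state(params, ncol(x_t))
  h <- as_batch_matrix(state$h, params$hidden_size, "state$h")
  c_prev <- as_batch_matrix(state$c, params$hidden_size, "state$c")
  if (ncol(h) != ncol(x_t) || ncol(c_prev) != ncol(x_t)) {
    stop("state and input batch sizes differ", call. = FALSE)
  }
  z <- rbind(h, x_t)
  f <- sigmoid(params$W_f %*% z + params$b_f)
  i <- sigmoid(params$W_i %*% z + params$b_i)
  c_tilde <- tanh_act(params$W_c %*% z + params$b_c)
  c_new <- f * c_prev + i * c_tilde
  o <- sigmoid(params$W_o %*% z + params$b_o)
  h_new <- o * tanh_act(c_new)
  list(state = list(h = h_new, c = c_new),
       gates = list(f = f, i = i, o = o, c_tilde = c_tilde))
}

# Batched forward over a sequence. x_seq: list of T (input x batch)
# matrices. Returns y (length batch), plus the cache needed for BPTT.
lstm_forward_batch <- function(x_seq, params, keep_cache = TRUE) {
  batch <- ncol(x_seq[[1]])
  state <- lstm_zero_state(params, batch)
  cache <- if (keep_cache) vector("list", length(x_seq)) else NULL
  for (t in seq_along(x_seq)) {
    step <- lstm_cell_step(x_seq[[t]], state, params)
    if (keep_cache) {
      cache[[t]] <- list(x = x_seq[[t]], h_prev = state$h, c_prev = state$c,
                         gates = step$gates, c_new = step$state$c)
    }
    state <- step$state
  }
  z_out <- drop(params$W_t %*% state$h) + params$b_t
  list(y = as.numeric(sigmoid(z_out)), z_out = as.numeric(z_out),
       h_final = state$h, cache = cache)
}

#' LSTM forward pass over a sequence
#'
#' Runs the cell over `t = 1..T` from zero initial state and applies the
#' readout `y = sigmoid(W_t H_T + b_t)` to the final hidden state. With all
#' parameters zero the output is exactly 0.5 for any sequence (every gate
#' sits at sigmoid(0)).
#'
#' @param sequence Numeric matrix with one row per time step and
#'   `input_size` columns (a single vector is treated as one step).
#' @param params An [lstm_params()].
#' @param keep_cache Keep per-step activations for [lstm_gradients()].
#' @return List with `y` (scalar in (0,1)), `z_out` (pre-sigmoid readout),
#'   `h_final` and (optionally) `cache`.
#' @export
#' @examples
#' p <- lstm_params(input_size = 3, hidden_size = 4, seed = 1)
#' lstm_forward(matrix(rnorm(15), 5, 3), p)$y
lstm_forward <- function(sequence, params, keep_cache = TRUE) {
  stopifnot(inherits(params, "lstm_params"))
  if (is.null(dim(sequence))) sequence <- matrix(sequence, nrow = 1)
  if (nrow(sequence) < 1L) stop("empty sequence", call. = FALSE)
  if (ncol(sequence) != params$input_size) {
    stop(sprintf("sequence has %d columns, params expect %d",
                 ncol(sequence), params$input_size), call. = FALSE)
  }
  x_seq <- lapply(seq_len(nrow(sequence)), function(t) matrix(sequence[t, ], ncol = 1))
  out <- lstm_forward_batch(x_seq, params, keep_cache = keep_cache)
  out$y <- out$y[1]
  out$z_out <- out$z_out[1]
  out
}

# Batched BPTT. upstream: length-batch vector of dL/dy. Returns summed
# parameter gradients over the batch.
lstm_gradients_batch <- function(forward, params, upstream, on_logit = FALSE) {
  cache <- forward$cache
  if (is.null(cache)) stop("forward pass was run without cache", call. = FALSE)
  h_n <- params$hidden_size
  batch <- ncol(forward$h_final)
  upstream <- rep_len(upstream, batch)
  dz_out <- if (on_logit) {
    upstream                                             # upstream is dL/dz_out
  } else {
    y <- sigmoid(forward$z_out)
    upstream * y * (1 - y)                               # through the readout sigmoid
  }
  g <- list(
    W_f = 0 * params$W_f, W_i = 0 * params$W_i, W_c = 0 * params$W_c,
    W_o = 0 * params$W_o,
    b_f = numeric(h_n), b_i = numeric(h_n), b_c = numeric(h_n), b_o = numeric(h_n),
    W_t = matrix(0, 1, h_n), b_t = 0
  )
  g$W_t <- matrix(forward$h_final %*% dz_out, 1, h_n)
  g$b_t <- sum(dz_out)
  dh <- t(params$W_t) %*% matrix(dz_out, 1, batch)
  dc <- matrix(0, h_n, batch)
  for (t in rev(seq_along(cache))) {
    st <- cache[[t]]
    tc <- tanh_act(st$c_new)
    f <- st$gates$f; i <- st$gates$i; o <- st$gates$o; ct <- st$gates$c_tilde
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    df <- dc * st$c_prev
    di <- dc * ct
    dct <- dc * i
    dc_prev <- dc * f
    da_f <- df * f * (1 - f)
    da_i <- di * i * (1 - i)
    da_o <- do_ * o * (1 - o)
    da_c <- dct * (1 - ct^2)
    z <- rbind(st$h_prev, st$x)
    g$W_f <- g$W_f + da_f %*% t(z); g$b_f <- g$b_f + rowSums(da_f)
    g$W_i <- g$W_i + da_i %*% t(z); g$b_i <- g$b_i + rowSums(da_i)
    g$W_c <- g$W_c + da_c %*% t(z); g$b_c <- g$b_c + rowSums(da_c)
    g$W_o <- g$W_o + da_o %*% t(z); g$b_o <- g$b_o + rowSums(da_o)
    dh <- t(params$W_f[, seq_len(h_n), drop = FALSE]) %*% da_f +
      t(params$W_i[, seq_len(h_n), drop = FALSE]) %*% da_i +
      t(params$W_c[, seq_len(h_n), drop = FALSE]) %*% da_c +
      t(params$W_o[, seq_len(h_n), drop = FALSE]) %*% da_o
    dc <- dc_prev
  }
  g
}

# Gradients when the loss residual applies to the pre-sigmoid readout
# (lstm-only training and logit fusion).
lstm_gradients_logit <- function(forward, params, upstream) {
  lstm_gradients_batch(forward, params, upstream, on_logit = TRUE)
}

#' Backpropagation through time
#'
#' Exact gradients of `upstream * y_LSTM` with respect to every parameter,
#' computed by reverse accumulation through the gate equations over the
#' whole sequence.
#'
#' @param sequence As in [lstm_forward()].
#' @param params An [lstm_params()].
#' @param upstream Scalar chain-rule multiplier (dL/dy).
#' @param forward Optional cached result of `lstm_forward(sequence, params)`;
#'   recomputed when omitted.
#' @return List of gradients with the same shapes/names as the trainable
#'   fields of `params` (`W_f, W_i, W_c, W_o, b_f, b_i, b_c, b_o, W_t, b_t`).
#' @export
lstm_gradients <- function(sequence, params, upstream = 1, forward = NULL) {
  if (is.null(forward)) forward <- lstm_forward(sequence, params, keep_cache = TRUE)
  if (is.null(forward$cache)) stop("forward pass was run without cache", call. = FALSE)
  lstm_gradients_batch(forward, params, upstream)
}
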