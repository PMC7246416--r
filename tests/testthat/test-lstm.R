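lstm_param_names <- c("W_f", "W_i", "W_c", "W_o", "b_f", "b_i", "b_c", "b_o",
                      "W_t", "b_t")

zeroed_lstm <- function(input_size, hidden_size) {
  p <- lstm_params(input_size, hidden_size, seed = 1)
  for (nm in lstm_param_names) p[[nm]][] <- 0
  p
}

test_that("activations hit their anchors and satisfy the tanh identity", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(tanh_act(0), 0)
  x <- seq(-20, 20, by = 0.5)
  expect_equal(tanh_act(x), 2 * sigmoid(2 * x) - 1, tolerance = 1e-12)
  # saturation without overflow
  expect_equal(sigmoid(700), 1)
  expect_equal(sigmoid(-700), 0)
})

test_that("zero-parameter cell and network sit at their analytic fixed points", {
  p <- zeroed_lstm(4, 3)
  st <- lstm_cell_step(rnorm(4), NULL, p)
  expect_true(all(st$gates$f == 0.5) && all(st$gates$i == 0.5) && all(st$gates$o == 0.5))
  expect_true(all(st$gates$c_tilde == 0))
  expect_true(all(st$state$c == 0) && all(st$state$h == 0))
  expect_equal(lstm_forward(matrix(rnorm(20), 5, 4), p)$y, 0.5)
  # zero weights with nonzero previous cell: C_t = 0.5 * c_prev
  p1 <- zeroed_lstm(1, 1)
  st1 <- lstm_cell_step(0.3, list(h = 0, c = 2), p1)
  expect_equal(as.numeric(st1$state$c), 1)
  expect_equal(as.numeric(st1$state$h), 0.5 * tanh_act(1))
})

test_that("gates and candidate stay inside their activation ranges", {
  set.seed(13)
  for (rep in 1:25) {
    # moderate draws: far from linear, but below float saturation of sigmoid
    p <- lstm_params(3, 4, init_sd = 0.5, seed = rep)
    st <- lstm_cell_step(rnorm(3), list(h = rnorm(4), c = rnorm(4)), p)
    gates <- c(st$gates$f, st$gates$i, st$gates$o)
    expect_true(all(gates > 0 & gates < 1))
    expect_true(all(abs(st$gates$c_tilde) < 1))
    expect_true(all(abs(st$state$h) < 1))
  }
})

test_that("a length-one sequence equals one cell step plus the readout", {
  p <- lstm_params(4, 3, seed = 5)
  x <- rnorm(4)
  step <- lstm_cell_step(x, NULL, p)
  manual <- sigmoid(drop(p$W_t %*% step$state$h) + p$b_t)
  expect_equal(lstm_forward(matrix(x, 1, 4), p)$y, as.numeric(manual))
  expect_error(lstm_forward(matrix(numeric(0), 0, 4), p), "empty")
  expect_error(lstm_forward(matrix(rnorm(10), 5, 2), p), "columns")
})

test_that("hidden state settles under a repeated constant input", {
  set.seed(14)
  settled <- 0
  for (rep in 1:20) {
    p <- lstm_params(3, 4, seed = 40 + rep)
    x <- matrix(rep(rnorm(3), 40), nrow = 40, byrow = TRUE)
    state <- NULL
    deltas <- numeric(0)
    h_prev <- matrix(0, 4, 1)
    for (t in 1:40) {
      out <- lstm_cell_step(x[t, ], state, p)
      state <- out$state
      deltas <- c(deltas, sqrt(sum((state$h - h_prev)^2)))
      h_prev <- state$h
    }
    # after burn-in the update magnitude should shrink
    if (mean(tail(deltas, 5)) <= mean(deltas[6:10]) + 1e-12) settled <- settled + 1
  }
  expect_gte(settled, 18)
})

test_that("backpropagation through time matches finite differences", {
  set.seed(15)
  for (rep in 1:10) {
    p <- lstm_params(4, 3, seed = 50 + rep)
    seqm <- matrix(rnorm(20), 5, 4)
    up <- rnorm(1)
    g <- lstm_gradients(seqm, p, upstream = up)
    fun <- function(q) up * lstm_forward(seqm, q, keep_cache = FALSE)$y
    for (nm in lstm_param_names) {
      for (idx in seq_along(p[[nm]])) {
        expect_lt(rel_err(fd_partial(fun, p, nm, idx), g[[nm]][idx]), 1e-5)
      }
    }
  }
})

test_that("gradient anchors: zero upstream and the readout bias chain rule", {
  p <- lstm_params(3, 2, seed = 60)
  seqm <- matrix(rnorm(12), 4, 3)
  g0 <- lstm_gradients(seqm, p, upstream = 0)
  expect_true(all(vapply(lstm_param_names, function(nm) all(g0[[nm]] == 0), logical(1))))
  fw <- lstm_forward(seqm, p)
  g <- lstm_gradients(seqm, p, upstream = 1.3, forward = fw)
  sig <- sigmoid(fw$z_out)
  expect_equal(g$b_t, 1.3 * sig * (1 - sig), tolerance = 1e-12)
})

test_that("forward pass is deterministic and batch-order independent", {
  p <- lstm_params(3, 4, seed = 70)
  seqs <- lapply(1:6, function(i) matrix(rnorm(15), 5, 3))
  y_single <- vapply(seqs, function(s) lstm_forward(s, p, keep_cache = FALSE)$y, numeric(1))
  x_seq <- lapply(1:5, function(t) vapply(seqs, function(s) s[t, ], numeric(3)))
  y_batch <- wavefm:::lstm_forward_batch(x_seq, p, keep_cache = FALSE)$y
  expect_equal(y_batch, y_single, tolerance = 1e-12)
  perm <- c(4, 2, 6, 1, 5, 3)
  x_seq_p <- lapply(x_seq, function(m) m[, perm])
  y_perm <- wavefm:::lstm_forward_batch(x_seq_p, p, keep_cache = FALSE)$y
  expect_equal(y_perm, y_single[perm], tolerance = 1e-12)
})
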