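#' Initialize factorization machine parameters
#'
#' A second-order factorization machine scores an input \eqn{x} as
#' \deqn{y_{FM}(x) = w_0 + \sum_i w_i x_i +
#'   \sum_{i<j} \langle v_i, v_j \rangle x_i x_j,}
#' with the pairwise interaction weight factorized as the inner product of
#' per-feature latent vectors \eqn{v_i \in R^k}. The factorization is what
#' lets interactions be learned from sparse one-hot data where most feature
#' pairs never co-occur. Bias and linear weights start at zero; latent
#' factors start at small Gaussian values so interactions can break symmetry.
#'
#' @param n Number of input columns (one-hot design width or dense feature
#'   count).
#' @param k Latent dimension (default 8).
#' @param init_sd Standard deviation of the latent-factor initialization.
#' @param seed RNG seed for the latent draw.
#' @return An `fm_params`: list with `w0` (scalar), `w` (length n), `V`
#'   (n x k matrix), `n`, `k`.
#' @export
fm_params <- function(n, k = 8, init_sd = 0.01, seed = 1L) {
  stopifnot(n >= 1, k >= 1)
  V <- with_seed(seed, matrix(stats::rnorm(n * k, sd = init_sd), n, k))
  structure(list(w0 = 0, w = numeric(n), V = V, n = as.integer(n),
                 k = as.integer(k)), class = "fm_params")
}

#' @export
print.fm_params <- function(x, ...) {
  cat(sprintf("<fm_params> n=%d inputs, k=%d latent factors\n", x$n, x$k))
  invisible(x)
}

# Normalize input to (values, indices): one-hot row of a sparse_design,
# or a dense numeric vector.
fm_input <- function(x, params, row = 1L) {
  if (inherits(x, "sparse_design")) {
    if (x$n_cols != params$n) {
      stop(sprintf("design has %d columns, params expect %d", x$n_cols, params$n),
           call. = FALSE)
    }
    list(idx = x$active[row, ], val = rep(1, ncol(x$active)))
  } else {
    x <- as.numeric(x)
    if (length(x) != params$n) {
      stop(sprintf("input length %d, params expect %d", length(x), params$n),
           call. = FALSE)
    }
    idx <- which(x != 0)
    list(idx = idx, val = x[idx])
  }
}

#' Factorization machine score
#'
#' Evaluates the second-order FM model through the exact O(nk)
#' linearization
#' \deqn{\sum_{i<j} \langle v_i, v_j\rangle x_i x_j = \frac12 \sum_f
#'   \Big[\big(\sum_i V_{if} x_i\big)^2 - \sum_i V_{if}^2 x_i^2\Big],}
#' touching only the active entries of a sparse row, so a one-hot row costs
#' O(F k) regardless of the design width.
#'
#' @param x A `sparse_design` (scored row by row via `row`) or a dense
#'   numeric vector of length `params$n`.
#' @param params An [fm_params()].
#' @param row Row of the sparse design to score (default 1).
#' @return Scalar score \eqn{y_{FM}} (a raw real number, not a probability).
#' @export
#' @examples
#' p <- fm_params(6, k = 2, seed = 1)
#' fm_score(c(1, 0, 0, 1, 0, 0), p)
fm_score <- function(x, params, row = 1L) {
  stopifnot(inherits(params, "fm_params"))
  inp <- fm_input(x, params, row)
  if (length(inp$idx) == 0L) return(params$w0)
  Va <- params$V[inp$idx, , drop = FALSE]
  s <- colSums(Va * inp$val)          # sum_i V_if x_i per factor f
  s2 <- colSums(Va^2 * inp$val^2)     # sum_i V_if^2 x_i^2
  params$w0 + sum(params$w[inp$idx] * inp$val) + 0.5 * sum(s^2 - s2)
}

#' Gradient of the factorization machine score
#'
#' Returns the exact partials of \eqn{y_{FM}} scaled by an upstream factor
#' (the chain-rule multiplier from the loss): \eqn{\partial y/\partial w_0 =
#' 1}, \eqn{\partial y/\partial w_i = x_i}, and
#' \eqn{\partial y/\partial V_{if} = x_i \sum_j V_{jf} x_j - V_{if} x_i^2}.
#' Gradients of inactive features are identically zero and are returned
#' sparsely.
#'
#' @inheritParams fm_score
#' @param upstream Scalar multiplier applied to every partial.
#' @return List with `w0` (scalar), `idx` (active indices), `w` (gradient
#'   for `w[idx]`), `V` (gradient rows for `V[idx, ]`).
#' @export
fm_gradient <- function(x, params, upstream = 1, row = 1L) {
  stopifnot(inherits(params, "fm_params"))
  inp <- fm_input(x, params, row)
  if (length(inp$idx) == 0L) {
    return(list(w0 = upstream, idx = integer(0), w = numeric(0),
                V = matrix(0, 0, params$k)))
  }
  Va <- params$V[inp$idx, , drop = FALSE]
  s <- colSums(Va * inp$val)
  gV <- upstream * (outer(inp$val, s) - Va * inp$val^2)
  list(w0 = upstream, idx = inp$idx, w = upstream * inp$val, V = gV)
}
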