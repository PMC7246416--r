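# Independent reference implementations used to cross-check the package's
# fast paths. These deliberately use the naive definitional form of each
# quantity.

# Nested-loop Riemann discretization of the CWT: for every scale and shift,
# sum the full signal against the conjugated, shifted, scaled wavelet.
cwt_oracle <- function(signal, spec) {
  n <- length(signal)
  coeffs <- matrix(0i, length(spec$scales), n)
  t_idx <- seq_len(n)
  for (si in seq_along(spec$scales)) {
    a <- spec$scales[si]
    for (tau in t_idx) {
      psi <- wavefm:::morlet_psi((t_idx - tau) / a, spec$omega0)
      coeffs[si, tau] <- a^(-0.5) * sum(signal * Conj(psi)) / spec$fs
    }
  }
  coeffs
}

# Explicit double-loop second-order FM score: w0 + sum_i w_i x_i +
# sum_{i<j} <v_i, v_j> x_i x_j.
fm_score_bruteforce <- function(x, params) {
  n <- length(x)
  y <- params$w0 + sum(params$w * x)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        y <- y + sum(params$V[i, ] * params$V[j, ]) * x[i] * x[j]
      }
    }
  }
  y
}

# Central finite differences of a scalar-valued function of one parameter
# bundle entry. h = 1e-4 balances truncation against roundoff for outputs
# of order 1: both error terms sit near 1e-9.
fd_partial <- function(fun, params, name, index, h = 1e-4) {
  p_plus <- params; p_plus[[name]][index] <- p_plus[[name]][index] + h
  p_minus <- params; p_minus[[name]][index] <- p_minus[[name]][index] - h
  (fun(p_plus) - fun(p_minus)) / (2 * h)
}

# Relative error; differences below the finite-difference noise floor count
# as exact so vanishing gradients compare on the absolute scale.
rel_err <- function(a, b, floor = 1e-8) {
  d <- abs(a - b)
  ifelse(d < floor, 0, d / pmax(abs(a), abs(b), floor))
}

# Small separable synthetic feature set shared by training tests: strong
# alpha contrast, low noise.
separable_features <- function(duration = 60, seed = 1) {
  rec <- generate_recording(synth_config(
    duration = duration, seed = seed, noise_sd = 1,
    band_gains_open = c(delta = 20, theta = 10, alpha = 10, beta = 5),
    band_gains_closed = c(delta = 20, theta = 10, alpha = 30, beta = 5)
  ))
  featurize_recording(rec)
}
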