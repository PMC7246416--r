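#' Canonical EEG frequency bands
#'
#' The four classical EEG rhythms used throughout the package: delta
#' (1--3.5 Hz), theta (3.5--7.5 Hz), alpha (7.5--12.5 Hz) and beta
#' (12.5--30 Hz). Alpha power is the band most strongly modulated by eye
#' closure, which is what the classifier ultimately exploits.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz), one row per
#'   band in delta/theta/alpha/beta order.
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    f_lo = c(1, 3.5, 7.5, 12.5),
    f_hi = c(3.5, 7.5, 12.5, 30)
  )
}

#' Configuration for the synthetic EEG generator
#'
#' Describes a band-structured multi-channel EEG recording: each channel is a
#' sum of one sinusoid per canonical band (delta/theta/alpha/beta) plus
#' Gaussian noise, with per-band amplitudes that depend on the eye state.
#' Eye-state dependence enters only through the band gains; by default the
#' alpha gain is three times larger with eyes closed, mimicking the posterior
#' alpha rhythm that appears on eye closure.
#'
#' @param n_channels Number of EEG channels (default 14, the Emotiv headset
#'   layout of the UCI EEG Eye State recording).
#' @param fs Sampling rate in Hz; must exceed 60 Hz so the beta band
#'   (up to 30 Hz) is below Nyquist. Default 128.
#' @param duration Recording length in seconds. Default 117, the length of
#'   the UCI recording.
#' @param band_gains_open,band_gains_closed Named numeric vectors
#'   (`delta`, `theta`, `alpha`, `beta`) of per-band sinusoid amplitudes in
#'   microvolts for each eye state.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (microvolts).
#' @param amp_cap Maximum absolute amplitude in microvolts; scalp EEG stays
#'   below roughly 300 uV and the generated signal is rescaled if it ever
#'   exceeds this cap. Default 300.
#' @param mean_block_len Mean duration (seconds) of an open or closed block
#'   in the alternating state schedule. Default 10 s, a typical instructed
#'   eyes-open/eyes-closed paradigm block.
#' @param seed Integer RNG seed; the same configuration always generates the
#'   identical recording.
#' @return A `synth_config` list.
#' @seealso [generate_recording()], [make_state_schedule()]
#' @export
synth_config <- function(n_channels = 14,
                         fs = 128,
                         duration = 117,
                         band_gains_open = c(delta = 20, theta = 10, alpha = 10, beta = 5),
                         band_gains_closed = c(delta = 20, theta = 10, alpha = 30, beta = 5),
                         noise_sd = 2,
                         amp_cap = 300,
                         mean_block_len = 10,
                         seed = 1L) {
  band_names <- eeg_bands()$band
  check_gains <- function(g, what) {
    if (!is.numeric(g) || length(g) != 4L || !all(band_names %in% names(g))) {
      stop(sprintf("`%s` must be a numeric vector named %s", what,
                   paste(band_names, collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(g)) || any(g < 0)) {
      stop(sprintf("`%s` must be finite and nonnegative", what), call. = FALSE)
    }
    g[band_names]
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 60) {
    stop("`fs` must exceed 60 Hz so the beta band is below Nyquist", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (!is.numeric(amp_cap) || amp_cap <= 0) stop("`amp_cap` must be positive", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (!is.numeric(mean_block_len) || mean_block_len <= 0) {
    stop("`mean_block_len` must be positive", call. = FALSE)
  }
  structure(list(
    n_channels = as.integer(n_channels),
    fs = fs,
    duration = duration,
    band_gains_open = check_gains(band_gains_open, "band_gains_open"),
    band_gains_closed = check_gains(band_gains_closed, "band_gains_closed"),
    noise_sd = noise_sd,
    amp_cap = amp_cap,
    mean_block_len = mean_block_len,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d channels, %g Hz, %g s, seed %d\n",
              x$n_channels, x$fs, x$duration, x$seed))
  cat("  gains open  :", paste(sprintf("%s=%g", names(x$band_gains_open),
                                       x$band_gains_open), collapse = " "), "\n")
  cat("  gains closed:", paste(sprintf("%s=%g", names(x$band_gains_closed),
                                       x$band_gains_closed), collapse = " "), "\n")
  invisible(x)
}

#' Alternating open/closed eye-state schedule
#'
#' Draws a piecewise-constant binary label sequence: block durations are
#' exponential with the given mean (truncated below at 0.5 s so no block
#' degenerates to a couple of samples), states alternate, and the starting
#' state is a seeded coin flip. Label 1 means eyes closed, 0 eyes open.
#'
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param mean_block_len Mean block duration in seconds.
#' @param seed Integer RNG seed.
#' @return Integer vector of length `round(duration * fs)` with values 0/1.
#' @export
#' @examples
#' table(make_state_schedule(20, 128, mean_block_len = 5, seed = 1))
make_state_schedule <- function(duration, fs, mean_block_len, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (!is.numeric(mean_block_len) || mean_block_len <= 0) {
    stop("`mean_block_len` must be positive", call. = FALSE)
  }
  n <- round(duration * fs)
  with_seed(seed, {
    state <- sample(0:1, 1L)   # coin flip for the starting state
    labels <- integer(0)
    while (length(labels) < n) {
      block_s <- max(0.5, stats::rexp(1, rate = 1 / mean_block_len))
      block_n <- max(1L, round(block_s * fs))
      labels <- c(labels, rep.int(state, block_n))
      state <- 1L - state
    }
    labels[seq_len(n)]
  })
}

#' Generate a labeled synthetic EEG recording
#'
#' Each channel is a sum over the four canonical bands of
#' `gain(state, band) * sin(2 pi f_c t + phi_c)` where the frequency `f_c` is
#' drawn uniformly inside the band and the phase uniformly on `[0, 2 pi)`,
#' both independently per channel, plus white Gaussian noise. If the summed
#' signal ever exceeds `amp_cap` in magnitude the whole recording is rescaled
#' by a single global factor so the cap holds. The same seed always yields a
#' bit-identical recording.
#'
#' @param config A [synth_config()].
#' @return An `eeg_recording`: list with `data` (channels x samples matrix,
#'   microvolts), `fs`, `labels` (per-sample 0/1, 1 = eyes closed) and
#'   `channel_names`.
#' @export
#' @examples
#' rec <- generate_recording(synth_config(duration = 5, seed = 42))
#' dim(rec$data)
generate_recording <- function(config) {
  if (!inherits(config, "synth_config")) {
    config <- do.call(synth_config, as.list(config))
  }
  bands <- eeg_bands()
  n <- round(config$duration * config$fs)
  labels <- make_state_schedule(config$duration, config$fs,
                                config$mean_block_len, seed = config$seed)
  t_sec <- (seq_len(n) - 1) / config$fs
  closed <- labels == 1L
  data <- with_seed(config$seed + 1L, {
    m <- matrix(0, nrow = config$n_channels, ncol = n)
    for (ch in seq_len(config$n_channels)) {
      sig <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        f <- stats::runif(1, bands$f_lo[b], bands$f_hi[b])
        phi <- stats::runif(1, 0, 2 * pi)
        gain <- ifelse(closed,
                       config$band_gains_closed[[bands$band[b]]],
                       config$band_gains_open[[bands$band[b]]])
        sig <- sig + gain * sin(2 * pi * f * t_sec + phi)
      }
      sig <- sig + config$noise_sd * stats::rnorm(n)
      m[ch, ] <- sig
    }
    m
  })
  peak <- max(abs(data))
  if (peak > config$amp_cap) data <- data * (config$amp_cap / peak)
  new_eeg_recording(data, config$fs, labels,
                    channel_names = paste0("CH", seq_len(config$n_channels)),
                    provenance = "synthetic")
}

new_eeg_recording <- function(data, fs, labels, channel_names, provenance = "unknown") {
  stopifnot(is.matrix(data), ncol(data) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (any(!is.finite(data))) stop("EEG data must be finite", call. = FALSE)
  structure(list(
    data = data, fs = fs, labels = labels,
    channel_names = channel_names, provenance = provenance
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$provenance))
  cat(sprintf("  labels: %.1f%% closed (label 1)\n", 100 * mean(x$labels)))
  invisible(x)
}

#' Tidy view of an EEG recording
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A long tibble with columns `time` (s), `channel`, `value` (uV)
#'   and `label`.
#' @method as_tibble eeg_recording
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    time = rep((seq_len(n) - 1) / x$fs, each = nrow(x$data)),
    channel = rep(x$channel_names, times = n),
    value = as.vector(x$data),
    label = rep(x$labels, each = nrow(x$data))
  )
}
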