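#' Morlet wavelet specification
#'
#' Defines the analysing wavelet and scale grid for the continuous wavelet
#' transform. The mother wavelet is the zero-mean-corrected complex Morlet
#' \deqn{\psi(t) = \pi^{-1/4} (e^{i\omega_0 t} - e^{-\omega_0^2/2})
#'   e^{-t^2/2},}
#' whose correction term makes \eqn{\hat\psi(0) = 0} exactly so the
#' admissibility integral converges. With \eqn{\omega_0 \ge 5} the correction
#' is numerically negligible but still applied. A scale \eqn{a} (in samples)
#' maps to the equivalent frequency \eqn{f = \omega_0 f_s / (2\pi a)} Hz,
#' which is what makes the delta/theta/alpha/beta band readout direct.
#'
#' @param fs Sampling rate of the signals to analyse, Hz.
#' @param scales Optional increasing positive vector of scales in samples.
#'   When omitted, a log-spaced grid with `voices` scales per octave covering
#'   `f_range` is built.
#' @param omega0 Center frequency of the mother wavelet (dimensionless,
#'   default 6).
#' @param f_range Frequency span (Hz) the default scale grid must cover.
#' @param voices Scales per octave for the default grid (default 16).
#' @return A `wavelet_spec` with fields `family`, `omega0`, `scales`, `fs`
#'   and the derived `freqs` (Hz, one per scale).
#' @export
#' @examples
#' spec <- wavelet_spec(fs = 128)
#' range(spec$freqs)
wavelet_spec <- function(fs, scales = NULL, omega0 = 6,
                         f_range = c(1, 32), voices = 16) {
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (!is.numeric(omega0) || omega0 < 5) {
    stop("`omega0` must be >= 5 (small-correction regime)", call. = FALSE)
  }
  if (is.null(scales)) {
    n_oct <- log2(f_range[2] / f_range[1])
    freqs <- f_range[2] / 2^(seq(0, n_oct, by = 1 / voices))
    scales <- sort(omega0 * fs / (2 * pi * freqs))
  }
  scales <- as.numeric(scales)
  if (any(scales <= 0) || any(diff(scales) <= 0)) {
    stop("`scales` must be strictly increasing and positive", call. = FALSE)
  }
  structure(list(
    family = "morlet", omega0 = omega0, scales = scales, fs = fs,
    freqs = omega0 * fs / (2 * pi * scales)
  ), class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> Morlet omega0=%g, %d scales (%.3g-%.3g samples, %.3g-%.3g Hz) @ %g Hz\n",
              x$omega0, length(x$scales), min(x$scales), max(x$scales),
              min(x$freqs), max(x$freqs), x$fs))
  invisible(x)
}

# Mother wavelet in the time domain (t dimensionless).
morlet_psi <- function(t, omega0 = 6) {
  kappa <- exp(-omega0^2 / 2)
  pi^(-1 / 4) * (exp(1i * omega0 * t) - kappa) * exp(-t^2 / 2)
}

# Fourier transform of the mother wavelet, convention
# psihat(w) = integral psi(t) exp(-i w t) dt.
morlet_psi_hat <- function(w, omega0 = 6) {
  kappa <- exp(-omega0^2 / 2)
  sqrt(2 * pi) * pi^(-1 / 4) * (exp(-(w - omega0)^2 / 2) - kappa * exp(-w^2 / 2))
}

# Half-width (samples) of the truncated wavelet kernel at scale a. The
# Gaussian envelope is below exp(-32) ~ 1e-14 beyond this, so truncation is
# invisible at double precision.
kernel_halfwidth <- function(a) ceiling(8 * a)

# Cone-of-influence half-width: e-folding time of the envelope, sqrt(2) * a.
coi_halfwidth <- function(a) sqrt(2) * a

#' Continuous wavelet transform
#'
#' Computes, for every scale \eqn{a} and shift \eqn{\tau} (both in samples),
#' \deqn{W(a, \tau) = a^{-1/2} \sum_t f(t)\, \overline{\psi}\!\left(
#'   \frac{t - \tau}{a}\right) / f_s,}
#' the Riemann discretization of the CWT integral, evaluated with zero
#' padding at the edges. The implementation is FFT-based (one circular
#' correlation per scale) and exactly linear in the input.
#'
#' @param signal Real numeric vector.
#' @param spec A [wavelet_spec()].
#' @return A `scalogram`: list with complex `coeffs` (scales x time), the
#'   `scales`, `freqs`, `fs`, `omega0` and a logical `valid` matrix marking
#'   coefficients outside the per-scale cone of influence of the edges.
#' @export
#' @examples
#' spec <- wavelet_spec(fs = 128, f_range = c(4, 32), voices = 8)
#' sg <- cwt(sin(2 * pi * 10 * (0:511) / 128), spec)
#' dim(sg$coeffs)
cwt <- function(signal, spec) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (!is.numeric(signal) || any(!is.finite(signal))) {
    stop("`signal` must be a finite numeric vector", call. = FALSE)
  }
  n <- length(signal)
  too_long <- spec$scales[2 * coi_halfwidth(spec$scales) > n]
  if (length(too_long) > 0L) {
    stop(sprintf(
      "signal of %d samples is shorter than the effective support of scale(s) %s",
      n, paste(signif(too_long, 4), collapse = ", ")), call. = FALSE)
  }
  m_max <- kernel_halfwidth(max(spec$scales))
  len <- stats::nextn(n + 2L * m_max + 1L, 2)
  f_hat <- stats::fft(c(signal, rep(0, len - n)))
  coeffs <- matrix(0i, nrow = length(spec$scales), ncol = n)
  valid <- matrix(TRUE, nrow = length(spec$scales), ncol = n)
  for (si in seq_along(spec$scales)) {
    a <- spec$scales[si]
    m <- kernel_halfwidth(a)
    u <- seq(-m, m)
    kern <- Conj(morlet_psi(u / a, spec$omega0))
    kpad <- complex(length.out = len)
    kpad[(u %% len) + 1L] <- kern
    g <- stats::fft(kpad)
    # correlation theorem: FT of sum_u kern[u] f[tau+u] is F[w] * G[-w]
    g_rev <- c(g[1], rev(g[-1]))
    cc <- stats::fft(f_hat * g_rev, inverse = TRUE) / len
    coeffs[si, ] <- cc[seq_len(n)] * a^(-1 / 2) / spec$fs
    coi <- coi_halfwidth(a)
    idx <- seq_len(n) - 1
    valid[si, ] <- idx >= coi & (n - 1 - idx) >= coi
  }
  structure(list(coeffs = coeffs, scales = spec$scales, freqs = spec$freqs,
                 fs = spec$fs, omega0 = spec$omega0, valid = valid),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales x %d samples @ %g Hz (%.3g-%.3g Hz)\n",
              nrow(x$coeffs), ncol(x$coeffs), x$fs, min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Tidy view of a scalogram
#'
#' @param x A `scalogram`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `freq` (Hz), `scale`, `power`
#'   (|coefficient|^2) and `valid` (outside the cone of influence).
#' @method as_tibble scalogram
#' @export
as_tibble.scalogram <- function(x, ...) {
  n <- ncol(x$coeffs)
  tibble::tibble(
    time = rep((seq_len(n) - 1) / x$fs, each = nrow(x$coeffs)),
    freq = rep(x$freqs, times = n),
    scale = rep(x$scales, times = n),
    power = as.vector(Mod(x$coeffs)^2),
    valid = as.vector(x$valid)
  )
}

#' Admissibility constant of the analysing wavelet
#'
#' Evaluates \eqn{C_\psi = \int_0^\infty |\hat\psi(w)|^2 / w \, dw} by
#' trapezoidal quadrature. The constant must be finite for the inverse
#' transform to exist, which requires \eqn{\hat\psi(0) = 0}; a wavelet with
#' nonzero mean makes the integrand blow up like \eqn{1/w} and is rejected.
#' The value depends only on the mother wavelet, not on `fs` or the scale
#' grid.
#'
#' @param spec A [wavelet_spec()].
#' @param psi_hat Optional override: a function of `w` returning the
#'   wavelet's Fourier transform (used to check admissibility of other
#'   kernels).
#' @param n_grid Number of quadrature nodes (default 8192).
#' @param w_max Upper integration limit (default `omega0 + 12`, beyond which
#'   the Gaussian tail is below double-precision resolution).
#' @return Positive scalar \eqn{C_\psi}.
#' @export
#' @examples
#' admissibility_constant(wavelet_spec(fs = 128))
admissibility_constant <- function(spec, psi_hat = NULL, n_grid = 8192,
                                   w_max = NULL) {
  omega0 <- if (inherits(spec, "wavelet_spec")) spec$omega0 else 6
  if (is.null(psi_hat)) psi_hat <- function(w) morlet_psi_hat(w, omega0)
  if (is.null(w_max)) w_max <- omega0 + 12
  if (Mod(psi_hat(0)) > 1e-6) {
    stop("wavelet is not admissible: |psi_hat(0)| > 0, the integral of |psi_hat|^2/w diverges",
         call. = FALSE)
  }
  w <- seq(0, w_max, length.out = n_grid)
  integrand <- Mod(psi_hat(w))^2 / w
  integrand[1] <- 0  # psi_hat(0) = 0, so the integrand has limit 0 at w = 0
  h <- w[2] - w[1]
  h * (sum(integrand) - (integrand[1] + integrand[n_grid]) / 2)
}

#' Inverse continuous wavelet transform
#'
#' Reconstructs the signal from its scalogram by discretizing the CWT
#' resolution-of-identity with trapezoidal weights over scale and uniform
#' steps over shift:
#' \deqn{f(t) = \frac{2 f_s}{C_\psi} \,\mathrm{Re} \sum_a
#'   \frac{\Delta a}{a^2} \sum_\tau W(a, \tau)\, a^{-1/2}
#'   \psi\!\left(\frac{t - \tau}{a}\right).}
#' The factor 2 and the real part account for the analysing wavelet being
#' (near-)analytic: its spectrum lives on positive frequencies only, so the
#' scalogram of a real signal determines only its positive-frequency half,
#' whose doubled real part is the signal. Accuracy depends on scale-grid
#' density (use at least 16 voices per octave) and on the scalogram covering
#' the signal's band; edge regions inside the cone of influence are not
#' reconstructed faithfully.
#'
#' @param scalogram A `scalogram` produced by [cwt()].
#' @param spec The same [wavelet_spec()] used for the forward transform.
#' @return Real numeric vector of the original length.
#' @export
inverse_cwt <- function(scalogram, spec) {
  stopifnot(inherits(scalogram, "scalogram"), inherits(spec, "wavelet_spec"))
  if (length(scalogram$scales) != length(spec$scales) ||
      max(abs(scalogram$scales - spec$scales)) > 1e-9) {
    stop("scalogram and spec scale grids do not match", call. = FALSE)
  }
  scales <- spec$scales
  n <- ncol(scalogram$coeffs)
  c_psi <- admissibility_constant(spec)
  d <- diff(scales)
  w_a <- c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  m_max <- kernel_halfwidth(max(scales))
  len <- stats::nextn(n + 2L * m_max + 1L, 2)
  acc <- complex(length.out = len)
  for (si in seq_along(scales)) {
    a <- scales[si]
    m <- kernel_halfwidth(a)
    u <- seq(-m, m)
    kern <- morlet_psi(u / a, spec$omega0)
    kpad <- complex(length.out = len)
    kpad[(u %% len) + 1L] <- kern
    w_hat <- stats::fft(c(scalogram$coeffs[si, ], complex(length.out = len - n)))
    # plain convolution: sum_tau W[tau] psi((t - tau)/a)
    acc <- acc + (w_a[si] * a^(-5 / 2)) * (w_hat * stats::fft(kpad))
  }
  out <- Re(stats::fft(acc, inverse = TRUE) / len)[seq_len(n)]
  out * 2 * spec$fs / c_psi
}

#' Per-band scalogram power features
#'
#' Averages squared coefficient magnitude over the scales whose equivalent
#' frequency falls in each canonical band and over the time axis. Columns
#' inside the cone of influence are excluded from the average; if every
#' column of a band is edge-contaminated (very short signals) all columns
#' are used instead.
#'
#' @param scalogram A `scalogram`.
#' @param bands A tibble like [eeg_bands()] (`band`, `f_lo`, `f_hi`).
#' @param cols Optional integer vector restricting the time columns averaged
#'   over (used when featurizing windows of a longer recording).
#' @return A tibble with columns `band` and `power` (one row per band).
#' @export
#' @examples
#' spec <- wavelet_spec(fs = 128)
#' sg <- cwt(sin(2 * pi * 10 * (0:511) / 128), spec)
#' band_features(sg)
band_features <- function(scalogram, bands = eeg_bands(), cols = NULL) {
  stopifnot(inherits(scalogram, "scalogram"))
  if (is.null(cols)) cols <- seq_len(ncol(scalogram$coeffs))
  power <- vapply(seq_len(nrow(bands)), function(b) {
    in_band <- scalogram$freqs >= bands$f_lo[b] & scalogram$freqs < bands$f_hi[b] |
      (b == nrow(bands) & scalogram$freqs == bands$f_hi[b])
    if (!any(in_band)) {
      stop(sprintf("no scales cover band %s [%g, %g) Hz",
                   bands$band[b], bands$f_lo[b], bands$f_hi[b]), call. = FALSE)
    }
    p <- Mod(scalogram$coeffs[in_band, cols, drop = FALSE])^2
    ok <- scalogram$valid[in_band, cols, drop = FALSE]
    if (!any(ok)) ok[] <- TRUE
    mean(p[ok])
  }, numeric(1))
  tibble::tibble(band = bands$band, power = power)
}

#' Wavelet band-power features for every window of a recording
#'
#' Runs the CWT once per channel over the full recording, then averages
#' per-band power over each window's time span. Computing the transform on
#' the whole signal (rather than window by window) keeps the slow delta-band
#' wavelets inside their support and confines edge effects to the recording
#' boundaries instead of every window boundary.
#'
#' @param recording An `eeg_recording`.
#' @param window_len,hop,label_rule Passed to [window_recording()].
#' @param spec A [wavelet_spec()]; default covers 1--32 Hz at 16
#'   voices/octave at the recording's sampling rate.
#' @param bands Band definition tibble, default [eeg_bands()].
#' @return A `window_features` tibble with columns `window`, `start`,
#'   `time` (window start, s), `label`, `channel`, `band`, `power`, plus
#'   attributes `fs`, `window_len`, `hop` and `channel_names`.
#' @export
#' @examples
#' rec <- generate_recording(synth_config(duration = 10, seed = 1))
#' head(featurize_recording(rec))
featurize_recording <- function(recording, window_len = round(recording$fs),
                                hop = max(1L, round(window_len / 2)),
                                label_rule = "majority",
                                spec = NULL, bands = eeg_bands()) {
  if (is.null(spec)) spec <- wavelet_spec(fs = recording$fs)
  wd <- window_recording(recording, window_len = window_len, hop = hop,
                         label_rule = label_rule)
  n_win <- length(wd$starts)
  per_channel <- lapply(seq_len(nrow(recording$data)), function(ch) {
    sg <- cwt(recording$data[ch, ], spec)
    pw <- Mod(sg$coeffs)^2
    band_rows <- lapply(seq_len(nrow(bands)), function(b) {
      in_band <- sg$freqs >= bands$f_lo[b] & sg$freqs < bands$f_hi[b] |
        (b == nrow(bands) & sg$freqs == bands$f_hi[b])
      if (!any(in_band)) {
        stop(sprintf("no scales cover band %s [%g, %g) Hz",
                     bands$band[b], bands$f_lo[b], bands$f_hi[b]), call. = FALSE)
      }
      # per-time-column masked sums, so window averages are cheap cumsums
      ok <- sg$valid[in_band, , drop = FALSE]
      s_t <- colSums(pw[in_band, , drop = FALSE] * ok)
      c_t <- colSums(ok)
      s_all <- colSums(pw[in_band, , drop = FALSE])
      c_all <- rep(sum(in_band), ncol(pw))
      vapply(seq_len(n_win), function(wi) {
        cols <- wd$starts[wi]:(wd$starts[wi] + wd$window_len - 1L)
        cnt <- sum(c_t[cols])
        if (cnt > 0) sum(s_t[cols]) / cnt else sum(s_all[cols]) / sum(c_all[cols])
      }, numeric(1))
    })
    tibble::tibble(
      window = rep(seq_len(n_win), times = nrow(bands)),
      band = rep(bands$band, each = n_win),
      power = unlist(band_rows)
    )
  })
  out <- dplyr::bind_rows(
    purrr::imap(per_channel, function(df, ch) {
      dplyr::mutate(df, channel = recording$channel_names[ch], .after = "window")
    })
  )
  out <- dplyr::arrange(out, .data$window, .data$channel, .data$band)
  out <- dplyr::mutate(out,
    start = wd$starts[.data$window],
    time = (wd$starts[.data$window] - 1) / recording$fs,
    label = wd$labels[.data$window],
    .after = "window"
  )
  structure(tibble::as_tibble(out),
            fs = recording$fs, window_len = wd$window_len, hop = wd$hop,
            channel_names = recording$channel_names,
            class = c("window_features", class(tibble::tibble())))
}

#' Widen window features into a windows x features matrix
#'
#' @param features A `window_features` tibble from [featurize_recording()].
#' @return List with `x` (windows x (channel, band) feature matrix, columns
#'   named `channel.band`), `labels` (per-window 0/1) and `windows` (window
#'   indices).
#' @export
feature_matrix <- function(features) {
  wide <- tidyr::pivot_wider(
    dplyr::select(features, "window", "label", "channel", "band", "power"),
    names_from = c("channel", "band"), values_from = "power", names_sep = "."
  )
  x <- as.matrix(dplyr::select(wide, -"window", -"label"))
  rownames(x) <- wide$window
  list(x = x, labels = wide$label, windows = wide$window)
}
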