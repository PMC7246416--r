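test_that("spec validation enforces ordered scales and the omega0 floor", {
  expect_error(wavelet_spec(fs = 128, scales = c(4, 2)), "increasing")
  expect_error(wavelet_spec(fs = 128, scales = c(-1, 2)), "increasing|positive")
  expect_error(wavelet_spec(fs = 128, omega0 = 3), "omega0")
  sp <- wavelet_spec(fs = 128)
  expect_equal(sp$freqs, sp$omega0 * 128 / (2 * pi * sp$scales))
})

test_that("fast CWT equals the nested-loop oracle and is linear", {
  spec <- wavelet_spec(fs = 128, f_range = c(4, 32), voices = 5)
  expect_lte(length(spec$scales), 16)
  set.seed(10)
  for (rep in 1:5) {
    x <- rnorm(200)
    expect_lt(max(Mod(cwt(x, spec)$coeffs - cwt_oracle(x, spec))), 1e-8)
  }
  f1 <- rnorm(512); f2 <- rnorm(512)
  spec2 <- wavelet_spec(fs = 128, f_range = c(2, 32), voices = 8)
  lin <- cwt(f1 + f2, spec2)$coeffs - (cwt(f1, spec2)$coeffs + cwt(f2, spec2)$coeffs)
  expect_lt(max(Mod(lin)), 1e-10)
  expect_true(all(cwt(rep(0, 256), spec)$coeffs == 0))
})

test_that("peak scale localizes tone frequencies within one grid step", {
  fs <- 128
  spec <- wavelet_spec(fs = fs, f_range = c(1, 32), voices = 16)
  grid_ratio <- 2^(1 / 16)
  for (f0 in c(2, 6, 10, 20)) {
    n <- 1024
    x <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
    sg <- cwt(x, spec)
    pw <- Mod(sg$coeffs)^2
    pw[!sg$valid] <- NA
    peak <- sg$freqs[which.max(rowMeans(pw, na.rm = TRUE))]
    expect_gt(peak, f0 / grid_ratio)
    expect_lt(peak, f0 * grid_ratio)
  }
})

test_that("short signals are rejected with the offending scale named", {
  spec <- wavelet_spec(fs = 128, f_range = c(1, 32))
  expect_error(cwt(rnorm(64), spec), "shorter than the effective support")
})

test_that("admissibility constant is positive, grid-stable and spec-independent", {
  c1 <- admissibility_constant(wavelet_spec(fs = 128), n_grid = 8192)
  c2 <- admissibility_constant(wavelet_spec(fs = 128), n_grid = 16384)
  expect_gt(c1, 0)
  expect_lt(abs(c1 - c2) / c1, 1e-3)
  # independent of sampling rate and scale grid
  c3 <- admissibility_constant(wavelet_spec(fs = 512, f_range = c(2, 16)))
  expect_equal(c1, c3)
  # a nonzero-mean kernel (plain Gaussian) is rejected
  expect_error(
    admissibility_constant(wavelet_spec(fs = 128),
                           psi_hat = function(w) sqrt(2 * pi) * exp(-w^2 / 2)),
    "admissib")
})

test_that("inverse transform round-trips a band-limited signal", {
  fs <- 128; n <- 1024
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 5 * t) + 0.7 * sin(2 * pi * 10 * t + 1) + 0.5 * sin(2 * pi * 20 * t + 2)
  spec <- wavelet_spec(fs = fs, f_range = c(2, 40), voices = 32)
  sg <- cwt(x, spec)
  xr <- inverse_cwt(sg, spec)
  edge <- ceiling(wavefm:::coi_halfwidth(max(spec$scales)))
  idx <- (edge + 1):(n - edge)
  rel_l2 <- sqrt(sum((xr[idx] - x[idx])^2) / sum(x[idx]^2))
  expect_lt(rel_l2, 0.05)
  # zero scalogram reconstructs zero, and the inverse is linear
  sg0 <- sg; sg0$coeffs[] <- 0
  expect_true(all(inverse_cwt(sg0, spec) == 0))
  sgA <- sg; sgB <- sg
  sgB$coeffs <- sgB$coeffs * (1 + 0.3i)
  sgS <- sg; sgS$coeffs <- sgA$coeffs + sgB$coeffs
  expect_lt(max(abs(inverse_cwt(sgS, spec) -
                    (inverse_cwt(sgA, spec) + inverse_cwt(sgB, spec)))), 1e-10)
  expect_error(inverse_cwt(sg, wavelet_spec(fs = fs, f_range = c(2, 40), voices = 16)),
               "grids do not match")
})

test_that("band features isolate a tone's band and scale quadratically", {
  fs <- 128
  spec <- wavelet_spec(fs = fs)
  x <- sin(2 * pi * 10 * (0:1023) / fs)
  bf <- band_features(cwt(x, spec))
  expect_equal(bf$band[which.max(bf$power)], "alpha")
  expect_gt(bf$power[bf$band == "alpha"], 2 * max(bf$power[bf$band != "alpha"]))
  bf0 <- band_features(cwt(rep(0, 1024), spec))
  expect_true(all(bf0$power == 0))
  bf2 <- band_features(cwt(2 * x, spec))
  expect_equal(bf2$power, 4 * bf$power, tolerance = 1e-8)
  expect_true(all(bf$power >= 0))
  # a grid not covering delta errors out by name
  spec_hi <- wavelet_spec(fs = fs, f_range = c(8, 32))
  expect_error(band_features(cwt(x, spec_hi)), "delta")
})

test_that("featurize_recording agrees with per-window band averages", {
  rec <- generate_recording(synth_config(duration = 20, seed = 6, n_channels = 2))
  spec <- wavelet_spec(fs = rec$fs)
  feats <- featurize_recording(rec, spec = spec)
  # independently recompute one interior window x channel from the scalogram
  wd <- window_recording(rec)
  wi <- 10L
  cols <- wd$starts[wi]:(wd$starts[wi] + wd$window_len - 1L)
  sg <- cwt(rec$data[2, ], spec)
  expected <- band_features(sg, cols = cols)
  got <- dplyr::arrange(
    dplyr::filter(feats, window == wi, channel == rec$channel_names[2]), band)
  expect_equal(got$power, dplyr::arrange(expected, band)$power, tolerance = 1e-12)
  expect_identical(got$label[1], wd$labels[wi])
})
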