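test_that("WAV round trip preserves calibrated pressures to one LSB", {
  tr <- make_tone(440, 0.1, amplitude = 3.2)
  path <- tempfile(fileext = ".wav")
  write_wav(tr, path, pa_full_scale = 4)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 96e3)
  expect_lt(max(abs(back$samples - tr$samples)), 4 / 32767)
  # full-scale sine
  fs_tr <- make_tone(1000, 0.05, amplitude = 1)
  p2 <- tempfile(fileext = ".wav")
  write_wav(fs_tr, p2, pa_full_scale = 1)
  expect_lt(max(abs(read_wav(p2)$samples - fs_tr$samples)), 1 / 32767)
  # silence stays exactly zero
  p3 <- tempfile(fileext = ".wav")
  write_wav(pressure_trace(numeric(200), 96e3), p3, pa_full_scale = 1)
  expect_true(all(read_wav(p3)$samples == 0))
  # clipping refused, naming the peak
  expect_error(write_wav(make_tone(100, 0.01, amplitude = 5), tempfile(),
                         pa_full_scale = 4), "clipping.*5")
  # 3.557 Pa at 4 Pa full scale lands on the expected code
  q <- round(spl_to_pressure(105) / 4 * 32767)
  expect_equal(q, 29132, tolerance = 3 / 29132)
})

test_that("STFT-Hilbert envelope recovers tones and AM modulation", {
  fs <- 96e3
  t <- (0:(fs * 0.05 - 1)) / fs
  # stationary tone: constant envelope within 1%
  x <- 2.5 * cos(2 * pi * 40e3 * t)
  env <- stft_hilbert_envelope(pressure_trace(x, fs))
  mid <- 1024:(length(env$samples) - 1024)
  expect_lt(max(abs(env$samples[mid] - 2.5)) / 2.5, 0.01)
  # closed-form AM: modulation depth error < 2%
  xm <- (1 + 0.5 * cos(2 * pi * 100 * t)) * cos(2 * pi * 40e3 * t)
  em <- stft_hilbert_envelope(pressure_trace(xm, fs))
  expected <- 1 + 0.5 * cos(2 * pi * 100 * t[seq_along(em$samples)])
  expect_lt(max(abs(em$samples[mid] - expected[mid])) / 0.5, 0.02)
  # equal tones at 40/39.8 kHz beat at 200 Hz
  xb <- cos(2 * pi * 40e3 * t) + cos(2 * pi * 39.8e3 * t + pi / 2)
  eb <- stft_hilbert_envelope(pressure_trace(xb, fs))
  expect_equal(dominant_frequency(eb, 50, 1000), 200, tolerance = 0.01)
  # linearity: envelope commutes with amplitude scaling
  e1 <- stft_hilbert_envelope(pressure_trace(xm, fs))
  e2 <- stft_hilbert_envelope(pressure_trace(3 * xm, fs))
  expect_equal(e2$samples, 3 * e1$samples, tolerance = 1e-12)
  # matches the full-signal analytic envelope for a stationary tone
  full <- Mod(analytic_signal(x))
  expect_lt(max(abs(env$samples[mid] - full[mid])) / 2.5, 0.01)
  expect_error(stft_hilbert_envelope(pressure_trace(x[1:100], fs)),
               "shorter than one")
})

test_that("dominant frequency picking is accurate and validated", {
  expect_equal(dominant_frequency(make_tone(200, 0.5), 50, 1000), 200,
               tolerance = 1e-2)
  # beat identity across several pairs (property-style)
  fs <- 96e3
  t <- (0:(fs * 0.1 - 1)) / fs
  for (df in c(100, 200, 400, 730)) {
    x <- cos(2 * pi * 40e3 * t) + cos(2 * pi * (40e3 - df) * t)
    env <- stft_hilbert_envelope(pressure_trace(x, fs))
    expect_equal(dominant_frequency(env, 50, 1000), df, tolerance = 0.02)
  }
  # weak harmonic does not steal the peak
  y <- sin(2 * pi * 200 * t) + 0.1 * sin(2 * pi * 400 * t)
  expect_equal(dominant_frequency(pressure_trace(y, fs), 50, 1000), 200,
               tolerance = 1e-2)
  expect_error(dominant_frequency(make_tone(200, 0.5), 50e3, 60e3),
               "Nyquist")
})

test_that("SPL spectrum normalization, Parseval, and C-weighting", {
  fs <- 96e3
  tone <- make_tone(1000, 0.1, amplitude = 1)
  sp <- spl_spectrum(tone)
  k <- which.max(sp$magnitudes[-1]) + 1
  expect_equal(sp$frequencies[k], 1000)
  expect_equal(sp$magnitudes[k], 1, tolerance = 1e-6)
  # 1 Pa amplitude = 0.7071 Pa RMS -> 90.97 dB
  expect_equal(sp$spl[k], 90.97, tolerance = 1e-4)
  # 20 uPa RMS tone sits at 0 dB
  ref <- make_tone(1000, 0.1, amplitude = 20e-6 * sqrt(2))
  expect_equal(max(spl_spectrum(ref)$spl), 0, tolerance = 1e-6)
  # Parseval under the single-sided peak-amplitude normalization
  set.seed(42)
  x <- rnorm(4096)
  spx <- spl_spectrum(pressure_trace(x, fs))
  m <- spx$magnitudes
  lhs <- mean(x^2)
  rhs <- m[1]^2 + m[length(m)]^2 + sum(m[2:(length(m) - 1)]^2) / 2
  expect_equal(lhs, rhs, tolerance = 1e-6)
  # C-weighting: ~0 dB at 1 kHz, strong cut far below
  expect_equal(c_weighting_db(1000), 0, tolerance = 1e-3)
  expect_lt(c_weighting_db(10), -10)
  expect_equal(spl_spectrum(tone, weighting = "C")$spl[k], sp$spl[k],
               tolerance = 1e-4)
})

test_that("harmonic roll-off statistics match closed forms", {
  # synthetic line spectrum with amplitudes 1/f^2 -> 20 log10(1/4) per octave
  fs <- 96e3
  f0 <- 100
  t <- (0:(fs - 1)) / fs
  x <- numeric(length(t))
  for (k in 1:60) x <- x + (1 / k^2) * sin(2 * pi * k * f0 * t)
  ro <- harmonic_rolloff(spl_spectrum(pressure_trace(x, fs)), f0, 6000)
  expect_equal(ro$mean, 20 * log10(1 / 4), tolerance = 1e-3)
  expect_equal(ro$std, 0, tolerance = 1e-3)
  # flat harmonic spectrum -> 0 +/- 0
  xf <- numeric(length(t))
  for (k in 1:60) xf <- xf + sin(2 * pi * k * f0 * t)
  rf <- harmonic_rolloff(spl_spectrum(pressure_trace(xf, fs)), f0, 6000)
  expect_equal(rf$mean, 0, tolerance = 1e-3)
  # invariant under global gain
  r2 <- harmonic_rolloff(spl_spectrum(pressure_trace(7.7 * x, fs)), f0, 6000)
  expect_equal(r2$mean, ro$mean, tolerance = 1e-9)
  expect_error(harmonic_rolloff(spl_spectrum(pressure_trace(x, fs)), f0, 150),
               "two harmonics")
})

test_that("spectral correlation behaves as a normalized similarity", {
  tr <- rosenberg_pulse_train(glottal_pulse_params(100), 0.5)
  sa <- spl_spectrum(tr)
  expect_equal(spectral_correlation(sa, sa, c(50, 8000)), 1.0)
  # rescaling either spectrum changes nothing
  sb <- sa
  sb$magnitudes <- sa$magnitudes * 123
  expect_equal(spectral_correlation(sa, sb, c(50, 8000)), 1.0)
  # anti-correlated shape
  sc <- sa
  grid_m <- sa$magnitudes
  sc$magnitudes <- max(grid_m) + min(grid_m) - grid_m
  expect_lt(spectral_correlation(sa, sc, c(50, 8000)), -0.99)
  sd0 <- sa
  sd0$magnitudes <- rep(1, length(sa$magnitudes))
  expect_error(spectral_correlation(sa, sd0, c(50, 8000)), "degenerate")
})

test_that("self-noise level measures overall SPL with optional weighting", {
  # 2 Pa RMS tone -> 100 dB
  tone <- make_tone(500, 0.2, amplitude = 2 * sqrt(2))
  expect_equal(self_noise_level(tone), 100, tolerance = 1e-6)
  # 20 uPa RMS -> 0 dB
  lo <- make_tone(500, 0.2, amplitude = 20e-6 * sqrt(2))
  expect_equal(self_noise_level(lo), 0, tolerance = 1e-6)
  # silence -> below reference sentinel
  expect_identical(self_noise_level(pressure_trace(numeric(64), 96e3)), -Inf)
  # C-weighting at 1 kHz is transparent
  t1k <- make_tone(1000, 0.2, amplitude = 1)
  expect_equal(self_noise_level(t1k, "C"), self_noise_level(t1k),
               tolerance = 1e-3)
})
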