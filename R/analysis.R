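#' Analytic signal via the FFT (full-signal Hilbert transform)
#'
#' Zeroes the negative-frequency half of the spectrum and doubles the
#' positive half; the magnitude of the result is the signal envelope.
#' Provided as an independent cross-check of the windowed estimator
#' [stft_hilbert_envelope()].
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(as.complex(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

.hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

#' Envelope demodulation via a short-time Hilbert transform
#'
#' Windowed (STFT-style) discrete Hilbert transform: each Hann-windowed
#' frame is converted to its analytic signal with the FFT, the frames are
#' overlap-added, normalized by the accumulated window weight, and the
#' magnitude taken. For an amplitude-modulated carrier whose modulation is
#' slow relative to the window this recovers the modulation envelope; for a
#' stationary tone of amplitude A it returns a constant A (to well under
#' 1%). This is how the beat (difference) frequency is demodulated from the
#' recorded ultrasonic waveform.
#'
#' @param trace a [pressure_trace()] (the carrier must fit several periods
#'   per window).
#' @param window_len frame length in samples (default 1024, about 10.7 ms at
#'   96 kHz).
#' @param hop frame hop in samples (default `window_len / 4`, 75% overlap;
#'   must be at most `window_len / 2`).
#' @return a [pressure_trace()] holding the envelope (trimmed to the region
#'   covered by complete frames).
#' @export
stft_hilbert_envelope <- function(trace, window_len = 1024L,
                                  hop = window_len %/% 4L) {
  stopifnot(inherits(trace, "pressure_trace"))
  x <- trace$samples
  n <- length(x)
  window_len <- as.integer(window_len)
  hop <- as.integer(hop)
  if (n < window_len) stop("trace shorter than one analysis window")
  if (hop > window_len %/% 2L) stop("hop must be at most window_len / 2")
  w <- .hann(window_len)
  starts <- seq.int(1L, n - window_len + 1L, by = hop)
  acc <- complex(n)
  wsum <- numeric(n)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1L)] * w
    acc[s:(s + window_len - 1L)] <- acc[s:(s + window_len - 1L)] +
      analytic_signal(seg)
    wsum[s:(s + window_len - 1L)] <- wsum[s:(s + window_len - 1L)] + w
  }
  last <- starts[length(starts)] + window_len - 1L
  keep <- seq_len(last)
  keep <- keep[wsum[keep] > 1e-8]
  env <- Mod(acc[keep]) / wsum[keep]
  pressure_trace(env, trace$sample_rate,
                 label = paste0(trace$label, "_envelope"))
}

#' Dominant frequency within a band
#'
#' Frequency of the largest spectral magnitude between `f_min` and `f_max`
#' (DC excluded; `f_min` must be positive), refined by parabolic
#' interpolation over the peak bin and its neighbours. The trace mean is
#' removed and the spectrum zero-padded (`zero_pad`-fold) before peak
#' picking; for a non-stationary signal this is simply the peak of the
#' average spectrum.
#'
#' @param trace a [pressure_trace()].
#' @param f_min,f_max band limits in Hz (`0 < f_min < f_max <= Nyquist`).
#' @param zero_pad zero-padding factor for the FFT grid (default 4).
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(trace, f_min, f_max, zero_pad = 4) {
  stopifnot(inherits(trace, "pressure_trace"), f_min > 0, f_max > f_min)
  fs <- trace$sample_rate
  if (f_max > fs / 2) stop("f_max exceeds the Nyquist frequency")
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  nfft <- 2^ceiling(log2(max(n * zero_pad, 16)))
  X <- stats::fft(c(x, numeric(nfft - n)))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  half <- seq_len(nfft %/% 2 + 1)
  mag <- Mod(X[half])
  fr <- freqs[half]
  band <- which(fr >= f_min & fr <= f_max)
  if (length(band) == 0L) stop("empty frequency band")
  k <- band[which.max(mag[band])]
  if (k > 1L && k < length(mag)) {
    lm <- log(pmax(mag[(k - 1):(k + 1)], .Machine$double.xmin))
    denom <- lm[1] - 2 * lm[2] + lm[3]
    shift <- if (abs(denom) > 0) 0.5 * (lm[1] - lm[3]) / denom else 0
    shift <- max(-1, min(1, shift))
  } else {
    shift <- 0
  }
  (k - 1 + shift) * fs / nfft
}

#' Single-sided SPL spectrum
#'
#' Magnitude spectrum scaled so each bin carries the peak pressure amplitude
#' (Pa) of that component (`2 |X_k| / n`; DC and Nyquist unscaled), and the
#' per-bin sound pressure level using the RMS convention
#' `SPL = 20 log10((mag / sqrt(2)) / 20 uPa)`. With `weighting = "C"` the
#' standard C-weighting curve is added to the SPL column.
#'
#' @param trace a calibrated [pressure_trace()] (samples in Pa).
#' @param weighting `"none"` or `"C"`.
#' @return an object of class `spectrum_result` with `frequencies`,
#'   `magnitudes` (Pa), `spl` (dB), `weighting`, `sample_rate`.
#' @export
spl_spectrum <- function(trace, weighting = c("none", "C")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(trace, "pressure_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 2L) stop("trace too short for a spectrum")
  X <- stats::fft(x)
  half <- seq_len(n %/% 2 + 1)
  mag <- Mod(X[half]) / n
  scale2 <- rep(2, length(half))
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[length(half)] <- 1
  mag <- mag * scale2
  freqs <- (half - 1) * trace$sample_rate / n
  spl <- 20 * log10(pmax(mag / sqrt(2), .Machine$double.xmin) / 20e-6)
  if (weighting == "C") spl <- spl + c_weighting_db(freqs)
  structure(list(frequencies = freqs, magnitudes = mag, spl = spl,
                 weighting = weighting, sample_rate = trace$sample_rate,
                 label = trace$label),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> '%s': %d bins to %g Hz, weighting %s\n",
              x$label, length(x$frequencies), max(x$frequencies), x$weighting))
  invisible(x)
}

#' @export
plot.spectrum_result <- function(x, ...) {
  graphics::plot(x$frequencies, x$spl, type = "l", xlab = "frequency (Hz)",
                 ylab = sprintf("SPL (dB%s re 20 uPa)",
                                if (x$weighting == "C") "C" else ""),
                 main = x$label, ...)
  invisible(x)
}

#' Standard C-weighting curve
#'
#' `C(f) = 20 log10(R_C(f)) + 0.0619` with
#' `R_C(f) = 12194^2 f^2 / ((f^2 + 20.6^2)(f^2 + 12194^2))`; approximately
#' 0 dB over 50 Hz -- 5 kHz, normalized to 0 dB at 1 kHz.
#'
#' @param f frequency in Hz (vectorized; the DC bin maps to -Inf).
#' @return weighting in dB.
#' @export
c_weighting_db <- function(f) {
  f2 <- f^2
  rc <- (12194^2 * f2) / ((f2 + 20.6^2) * (f2 + 12194^2))
  20 * log10(pmax(rc, .Machine$double.xmin)) + 0.0619
}

#' Harmonic roll-off statistics
#'
#' Reads the SPL at each harmonic `k * f0` (the spectral peak within
#' `+/- f0/4` of the nominal harmonic), then computes the per-octave drop
#' `SPL(2f) - SPL(f)` over every harmonic pair `(f, 2f)` with both members
#' in band, returning the mean and standard deviation. A natural voicing
#' source rolls off at about -12 dB/octave; the estimate is invariant under
#' global gain changes.
#'
#' @param spectrum a `spectrum_result` (see [spl_spectrum()]).
#' @param f0 fundamental frequency in Hz.
#' @param f_max_band upper band edge in Hz.
#' @return an object of class `rolloff_result`: `mean`, `std` (dB/octave),
#'   `pairs_used`, `harmonic_spl` (named vector).
#' @export
harmonic_rolloff <- function(spectrum, f0, f_max_band) {
  stopifnot(inherits(spectrum, "spectrum_result"), f0 > 0)
  kmax <- floor(f_max_band / f0)
  if (kmax < 2L) stop("need at least two harmonics of f0 in band")
  spl_at <- vapply(seq_len(kmax), function(k) {
    sel <- which(abs(spectrum$frequencies - k * f0) <= f0 / 4)
    if (length(sel) == 0L) return(NA_real_)
    max(spectrum$spl[sel])
  }, numeric(1))
  pairs <- which(!is.na(spl_at[seq_len(kmax %/% 2)]) &
                   !is.na(spl_at[2 * seq_len(kmax %/% 2)]))
  if (length(pairs) < 1L) stop("no usable harmonic pair (f, 2f) in band")
  drops <- spl_at[2 * pairs] - spl_at[pairs]
  structure(list(mean = mean(drops),
                 std = if (length(drops) > 1L) stats::sd(drops) else 0,
                 pairs_used = length(drops),
                 harmonic_spl = stats::setNames(spl_at,
                                                paste0("h", seq_len(kmax)))),
            class = "rolloff_result")
}

#' @export
print.rolloff_result <- function(x, ...) {
  cat(sprintf("<rolloff_result> %.2f +/- %.2f dB/octave over %d pairs\n",
              x$mean, x$std, x$pairs_used))
  invisible(x)
}

#' Correlation between two normalized spectra
#'
#' Both spectra are linearly resampled onto a common frequency grid spanning
#' `f_band`, peak-normalized, and the Pearson correlation of the magnitudes
#' returned. Invariant under separate positive rescaling of either
#' spectrum.
#'
#' @param spec_a,spec_b `spectrum_result` objects covering `f_band`.
#' @param f_band numeric pair (low, high) in Hz.
#' @param n_grid number of points on the common grid.
#' @return correlation coefficient in \[-1, 1\].
#' @export
spectral_correlation <- function(spec_a, spec_b, f_band, n_grid = 1024L) {
  stopifnot(inherits(spec_a, "spectrum_result"),
            inherits(spec_b, "spectrum_result"),
            length(f_band) == 2L, f_band[1] < f_band[2])
  for (s in list(spec_a, spec_b)) {
    if (max(s$frequencies) < f_band[2]) {
      stop("spectrum does not cover the requested band")
    }
  }
  grid <- seq(f_band[1], f_band[2], length.out = n_grid)
  ga <- stats::approx(spec_a$frequencies, spec_a$magnitudes, xout = grid)$y
  gb <- stats::approx(spec_b$frequencies, spec_b$magnitudes, xout = grid)$y
  if (max(ga) <= 0 || max(gb) <= 0 ||
      stats::sd(ga) == 0 || stats::sd(gb) == 0) {
    stop("degenerate (constant or empty) spectrum in band")
  }
  stats::cor(ga / max(ga), gb / max(gb))
}

#' Overall (optionally C-weighted) sound pressure level of a trace
#'
#' Unweighted: `20 log10(RMS / 20 uPa)`. C-weighted: the weighting is
#' applied per frequency bin and the weighted RMS recovered through
#' Parseval's identity. A silent trace returns `-Inf` ("below reference").
#'
#' @param trace a calibrated [pressure_trace()].
#' @param weighting `"none"` or `"C"`.
#' @return level in dB (dBC when weighted).
#' @export
self_noise_level <- function(trace, weighting = c("none", "C")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(trace, "pressure_trace"))
  x <- trace$samples
  n <- length(x)
  if (n == 0L || all(x == 0)) return(-Inf)
  if (weighting == "none") {
    rms <- sqrt(mean(x^2))
  } else {
    X <- stats::fft(x)
    freqs <- (seq_len(n) - 1) * trace$sample_rate / n
    freqs[freqs > trace$sample_rate / 2] <-
      trace$sample_rate - freqs[freqs > trace$sample_rate / 2]
    w <- 10^(c_weighting_db(freqs) / 20)
    rms <- sqrt(sum((Mod(X) * w)^2) / n^2)
  }
  if (rms == 0) return(-Inf)
  20 * log10(rms / 20e-6)
}
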