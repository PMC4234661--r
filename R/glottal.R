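#' Rosenberg type-C glottal pulse parameters
#'
#' The Rosenberg type-C pulse is a piecewise-sinusoidal model of the glottal
#' flow cycle: a raised-cosine opening phase of duration `tp_fraction` of the
#' period, a quarter-cosine closing phase of `tn_fraction`, and closure for
#' the remainder. The function is continuous with a discontinuous first
#' derivative at closure, which produces the asymptotic -12 dB/octave
#' harmonic roll-off characteristic of natural voicing.
#'
#' @param f0 fundamental frequency in Hz.
#' @param tp_fraction opening time as a fraction of the period (default
#'   0.40).
#' @param tn_fraction closing time as a fraction of the period (default
#'   0.16).
#' @param level_db peak amplitude in dB SPL re 20 uPa (default 105). The
#'   level is treated as peak pressure; all waveform comparisons downstream
#'   are peak-normalized, so this choice only sets the absolute scale.
#' @param sample_rate sampling rate in Hz (default 96 kHz; must be at least
#'   10 f0).
#' @return an object of class `glottal_pulse_params`.
#' @export
glottal_pulse_params <- function(f0, tp_fraction = 0.40, tn_fraction = 0.16,
                                 level_db = 105, sample_rate = 96e3) {
  stopifnot(f0 > 0, tp_fraction > 0, tn_fraction > 0)
  if (tp_fraction + tn_fraction > 1) {
    stop("tp_fraction + tn_fraction must not exceed 1")
  }
  if (sample_rate < 10 * f0) stop("sample_rate must be at least 10 * f0")
  structure(list(f0 = f0, tp_fraction = tp_fraction,
                 tn_fraction = tn_fraction, level_db = level_db,
                 sample_rate = sample_rate),
            class = "glottal_pulse_params")
}

#' Synthesize a Rosenberg type-C glottal pulse train
#'
#' Per period `T = 1/f0`, with `Tp = tp_fraction * T` and
#' `Tn = tn_fraction * T`:
#' \deqn{g(t) = A/2 (1 - \cos(\pi t / T_p)), \quad 0 \le t \le T_p}
#' \deqn{g(t) = A \cos(\pi (t - T_p) / (2 T_n)), \quad T_p < t \le T_p + T_n}
#' and zero otherwise (each period starts at glottal opening). `A` is the
#' peak pressure from the dB SPL level.
#'
#' @param params a [glottal_pulse_params()].
#' @param duration train duration in seconds.
#' @return a [pressure_trace()] at `params$sample_rate`.
#' @export
rosenberg_pulse_train <- function(params, duration) {
  stopifnot(inherits(params, "glottal_pulse_params"), duration > 0)
  fs <- params$sample_rate
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  period <- 1 / params$f0
  tau <- t %% period
  tp <- params$tp_fraction * period
  tn <- params$tn_fraction * period
  a <- spl_to_pressure(params$level_db)
  g <- numeric(n)
  open <- tau <= tp
  g[open] <- a / 2 * (1 - cos(pi * tau[open] / tp))
  closing <- tau > tp & tau <= tp + tn
  g[closing] <- a * cos(pi * (tau[closing] - tp) / (2 * tn))
  pressure_trace(g, fs, label = sprintf("rosenberg_%gHz", params$f0))
}
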