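#' Sampled pressure trace
#'
#' A calibrated time series of acoustic pressure in pascal, as recorded by a
#' simulation microphone or synthesized directly (e.g. a glottal pulse
#' train).
#'
#' @param samples numeric vector of pressure samples (Pa).
#' @param sample_rate sampling rate in Hz.
#' @param label text label (microphone or source id).
#' @return an object of class `pressure_trace`.
#' @export
pressure_trace <- function(samples, sample_rate, label = "trace") {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (length(samples) > 0 && !all(is.finite(samples))) {
    stop("pressure trace contains non-finite samples")
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 label = label),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<pressure_trace> '%s': %d samples @ %g Hz (%.4g s), peak %.4g Pa\n",
              x$label, length(x$samples), x$sample_rate, dur,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
as.data.frame.pressure_trace <- function(x, ...) {
  n <- length(x$samples)
  data.frame(time_s = (seq_len(n) - 1) / x$sample_rate, pressure_pa = x$samples)
}

#' @export
plot.pressure_trace <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::plot(df$time_s, df$pressure_pa, type = "l",
                 xlab = "time (s)", ylab = "pressure (Pa)", main = x$label, ...)
  invisible(x)
}

#' Trace time axis
#' @param trace a [pressure_trace()].
#' @return time of each sample in seconds (first sample at one sample period
#'   for simulation recordings, see [run_simulation()]).
#' @export
trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sample_rate
}
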