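#' Write a pressure trace as 16-bit PCM WAV with a calibration sidecar
#'
#' 16-bit PCM cannot carry physical units, so the pascal-per-full-scale
#' calibration factor is stored in a JSON sidecar (`<path>.json`) and applied
#' by [read_wav()]; the round trip recovers pressures to within one
#' quantization step (full scale / 32767).
#'
#' @param trace a [pressure_trace()].
#' @param path output `.wav` path.
#' @param pa_full_scale pressure (Pa) mapped to digital full scale. Defaults
#'   to the trace peak; traces whose peak exceeds it are refused (clipping)
#'   with the peak in the message.
#' @return invisibly `path`.
#' @export
write_wav <- function(trace, path, pa_full_scale = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  peak <- if (length(trace$samples)) max(abs(trace$samples)) else 0
  if (is.null(pa_full_scale)) pa_full_scale <- if (peak > 0) peak else 1
  if (peak > pa_full_scale * (1 + 1e-12)) {
    stop(sprintf("clipping: trace peak %.6g Pa exceeds full scale %.6g Pa",
                 peak, pa_full_scale))
  }
  x <- as.integer(pmin(32767, pmax(-32767,
                                   round(trace$samples / pa_full_scale * 32767))))
  fs <- as.integer(round(trace$sample_rate))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  jsonlite::write_json(list(pa_per_full_scale = pa_full_scale,
                            sample_rate = trace$sample_rate,
                            label = trace$label),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated 16-bit PCM WAV
#'
#' Reads a mono RIFF/PCM16 file and applies the pascal-per-full-scale factor
#' from the JSON sidecar written by [write_wav()] (or supplied directly).
#'
#' @param path `.wav` path.
#' @param pa_full_scale calibration override; taken from `<path>.json` when
#'   `NULL`.
#' @return a [pressure_trace()].
#' @export
read_wav <- function(path, pa_full_scale = NULL) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  label <- sub("\\.wav$", "", basename(path))
  if (is.null(pa_full_scale)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      pa_full_scale <- meta$pa_per_full_scale
      label <- meta$label %||% label
    } else {
      stop("no calibration: missing sidecar ", sidecar,
           " and no pa_full_scale given")
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                      endian = "little")
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(fs) || is.null(samples)) stop("malformed WAV: ", path)
  if (!identical(bits, 16L)) stop("only 16-bit PCM supported, got ", bits)
  if (!identical(channels, 1L)) stop("only mono WAV supported")
  pressure_trace(samples / 32767 * pa_full_scale, fs, label = label)
}
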