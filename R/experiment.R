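#' Stability report for a simulation setup
#'
#' Collects the numbers that decide whether a time step is usable: the
#' Courant bound from the fastest material, the chosen dt and its status,
#' the solver sampling frequency `1/dt` and its ratio to the output rate,
#' and the shortest wavelength with its points-per-voxel sampling.
#'
#' @param registry a [tissue_registry()] (or `material_fields`).
#' @param delta spatial step (m), default 1 mm.
#' @param dt chosen time step (s), default 122.5 ns.
#' @param f_max highest source frequency (Hz), default 40 kHz.
#' @param output_rate microphone output rate (Hz), default 96 kHz.
#' @param n_steps optional iteration count; when given, the simulated
#'   duration `n_steps * dt` is included.
#' @return an object of class `stability_report` (also a plain list, so it
#'   serializes directly to JSON).
#' @export
stability_report <- function(registry, delta = 1e-3, dt = 122.5e-9,
                             f_max = 40e3, output_rate = 96e3,
                             n_steps = NULL) {
  max_dt <- max_stable_timestep(registry, delta, scheme = "yee22")
  max_dt24 <- max_stable_timestep(registry, delta, scheme = "yee24")
  c_min <- if (inherits(registry, "tissue_registry")) {
    min(registry$entries$speed_m_s)
  } else if (inherits(registry, "material_fields")) {
    min(registry$c)
  } else {
    min(registry)
  }
  samp <- withCallingHandlers(
    check_spatial_sampling(c_min, f_max, delta),
    warning = function(w) invokeRestart("muffleWarning"))
  rep <- list(
    delta_m = delta,
    dt_s = dt,
    max_stable_dt_s = max_dt,
    max_stable_dt_yee24_s = max_dt24,
    status = if (dt <= max_dt) "ok" else "failure: dt exceeds Courant bound",
    sampling_frequency_hz = 1 / dt,
    output_rate_hz = output_rate,
    output_ratio = round(1 / (dt * output_rate)),
    min_wavelength_m = samp$wavelength,
    points_per_wavelength = samp$points_per_wavelength)
  if (!is.null(n_steps)) rep$simulated_time_s <- n_steps * dt
  structure(rep, class = c("stability_report", "list"))
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report\n")
  cat(sprintf("  spatial step        : %g mm\n", x$delta_m * 1e3))
  cat(sprintf("  Courant bound       : %.2f ns (yee24: %.2f ns)\n",
              x$max_stable_dt_s * 1e9, x$max_stable_dt_yee24_s * 1e9))
  cat(sprintf("  chosen dt           : %.2f ns -> %s\n", x$dt_s * 1e9,
              x$status))
  cat(sprintf("  sampling frequency  : %.2f MHz (%dx the %g kHz output)\n",
              x$sampling_frequency_hz / 1e6, x$output_ratio,
              x$output_rate_hz / 1e3))
  cat(sprintf("  shortest wavelength : %.4g mm (%.3g points per wavelength)\n",
              x$min_wavelength_m * 1e3, x$points_per_wavelength))
  if (!is.null(x$simulated_time_s)) {
    cat(sprintf("  simulated time      : %.4g ms\n", x$simulated_time_s * 1e3))
  }
  invisible(x)
}

#' Configuration for a desk-scale beat-frequency experiment
#'
#' Two ultrasonic disc sources on the y = 4 mm plane of a homogeneous
#' soft-tissue block, 20 mm apart, emitting along +y: source 1 at `f1` and
#' 0 deg, source 2 at `f1 - beat_hz` and 90 deg, both at 105 dB SPL, with
#' microphones on the midline 20--30 mm beyond the sources. The run length
#' must cover at least three beat periods and the beat frequency must lie
#' inside the analysis band.
#'
#' @param beat_hz target difference frequency (100, 200 or 400 Hz in the
#'   reference experiments).
#' @param f1 source-1 frequency (Hz), default 40 kHz.
#' @param dims phantom voxel counts, default 64^3 at 1 mm.
#' @param duration simulated time in seconds; default
#'   `max(0.015, 3 / beat_hz)`.
#' @param level_db drive level, dB SPL.
#' @param separation_mm source separation along x.
#' @param output_rate microphone rate (Hz).
#' @param analysis_band envelope search band (Hz).
#' @param courant_fraction fraction of the fourth-order stencil stability
#'   bound that dt may not exceed when choosing the decimation factor.
#' @return an object of class `beat_experiment_config`.
#' @export
beat_experiment_config <- function(beat_hz, f1 = 40e3,
                                   dims = c(64L, 64L, 64L), duration = NULL,
                                   level_db = 105, separation_mm = 20,
                                   output_rate = 96e3,
                                   analysis_band = c(50, 1000),
                                   courant_fraction = 0.95) {
  stopifnot(beat_hz >= 0, f1 > beat_hz)
  if (beat_hz > 0 &&
      (beat_hz < analysis_band[1] || beat_hz > analysis_band[2])) {
    stop("beat frequency must lie inside the analysis band")
  }
  if (is.null(duration)) {
    duration <- if (beat_hz > 0) max(0.015, 3 / beat_hz) else 0.015
  }
  if (beat_hz > 0 && duration < 3 / beat_hz) {
    stop("run length must cover at least 3 beat periods")
  }
  spacing <- 1e-3
  bound24 <- max_stable_timestep(1540, spacing, scheme = "yee24")
  decimation <- ceiling(1 / (output_rate * courant_fraction * bound24))
  dt <- 1 / (output_rate * decimation)
  mm <- spacing * 1e3
  cx <- (dims[1] - 1) / 2 * mm
  cz <- (dims[3] - 1) / 2 * mm
  src_y <- 4
  sources <- list(
    source_spec(c(cx - separation_mm / 2, src_y, cz), frequency = f1,
                phase_deg = 0, level_db = level_db, axis = "y"),
    source_spec(c(cx + separation_mm / 2, src_y, cz),
                frequency = f1 - beat_hz, phase_deg = 90,
                level_db = level_db, axis = "y"))
  depths <- seq(20, 30, by = 5)
  depths <- depths[src_y + depths <= (dims[2] - 2) * mm]  # keep inside domain
  if (length(depths) == 0L) stop("domain too shallow for any microphone")
  mics <- lapply(depths, function(d) {
    microphone_spec(c(cx, src_y + d, cz), label = sprintf("mic_y%d", d))
  })
  structure(list(beat_hz = beat_hz, f1 = f1, f2 = f1 - beat_hz,
                 dims = as.integer(dims), spacing = spacing,
                 duration = duration, dt = dt, decimation = decimation,
                 level_db = level_db, sources = sources,
                 microphones = mics, output_rate = output_rate,
                 analysis_band = analysis_band),
            class = "beat_experiment_config")
}

#' Run a beat-frequency experiment
#'
#' Runs the FDTD simulation of a [beat_experiment_config()], demodulates
#' each microphone with [stft_hilbert_envelope()], and reports the dominant
#' envelope frequency plus the across-microphone mean (and standard error)
#' of the audible-output SPL (the level of the envelope's oscillating part,
#' i.e. of the demodulated beat).
#'
#' @param config a [beat_experiment_config()].
#' @param registry tissue registry; defaults to the bundled one.
#' @param progress print solver progress.
#' @return list with `traces`, `envelopes`, `per_mic_beat_hz`,
#'   `measured_beat_hz` (median across microphones; `NA` with a "no beat"
#'   message when the envelope has no modulation), `level_mean_db`,
#'   `level_stderr_db`, `config`.
#' @export
run_beat_experiment <- function(config, registry = default_tissue_registry(),
                                progress = FALSE) {
  stopifnot(inherits(config, "beat_experiment_config"))
  grid <- make_soft_tissue_phantom(config$dims, config$spacing)
  n_steps <- config$decimation *
    ceiling(config$duration / (config$dt * config$decimation))
  sim_cfg <- simulation_config(dt = config$dt, n_steps = n_steps,
                               output_rate = config$output_rate,
                               boundary = "mur")
  res <- run_simulation(grid, registry, sim_cfg, config$sources,
                        config$microphones, progress = progress)
  win <- min(1024L, length(res$traces[[1]]$samples))
  envelopes <- lapply(res$traces, stft_hilbert_envelope,
                      window_len = win, hop = max(1L, win %/% 4L))
  band <- config$analysis_band
  per_mic <- vapply(envelopes, function(env) {
    # judge modulation depth away from the window-edge transients
    n <- length(env$samples)
    interior <- env$samples[max(1L, win %/% 2L):(n - min(n %/% 4L, win %/% 2L))]
    ac <- stats::sd(interior)
    dc <- mean(interior)
    if (dc <= 0 || ac / dc < 0.02) return(NA_real_)  # no modulation
    dominant_frequency(env, band[1], band[2])
  }, numeric(1))
  measured <- if (all(is.na(per_mic))) {
    message("no beat: envelope carries no modulation in the analysis band")
    NA_real_
  } else {
    stats::median(per_mic, na.rm = TRUE)
  }
  levels <- vapply(envelopes, function(env) {
    ac <- env$samples - mean(env$samples)
    self_noise_level(pressure_trace(ac, env$sample_rate, env$label))
  }, numeric(1))
  list(traces = res$traces, envelopes = envelopes,
       per_mic_beat_hz = per_mic, measured_beat_hz = measured,
       level_mean_db = mean(levels),
       level_stderr_db = stats::sd(levels) / sqrt(length(levels)),
       config = config)
}

.as_trace <- function(x) {
  if (inherits(x, "pressure_trace")) x else read_wav(x)
}

#' Compare voicing excitations
#'
#' The full comparison chain for excitation waveforms: peak-normalized time
#' waveforms, magnitude spectra, SPL spectra, harmonic roll-off statistics,
#' and pairwise correlations of the peak-normalized spectral magnitudes.
#' Typical inputs are a Rosenberg glottal pulse train (the natural-voicing
#' reference), a demodulated device simulation, and optionally a recording
#' of a classic electrolarynx.
#'
#' @param glottal,device traces or paths to calibrated WAV files (see
#'   [read_wav()]); must share one sample rate.
#' @param el optional third excitation (classic electrolarynx recording).
#' @param f0 fundamental frequency (Hz) used for the roll-off estimate.
#' @param f_band analysis band (Hz) for spectra, correlation and roll-off.
#' @param weighting SPL weighting for the roll-off statistics.
#' @param out_dir optional directory; when given, the report is written as
#'   `comparison.json` plus per-excitation spectrum CSVs.
#' @return list with `waveforms` (peak-normalized), `spectra`, `rolloff`
#'   (one `rolloff_result` per excitation), `correlations` (named numeric).
#' @export
compare_excitations <- function(glottal, device, el = NULL, f0,
                                f_band = c(50, 8000),
                                weighting = c("none", "C"), out_dir = NULL) {
  weighting <- match.arg(weighting)
  traces <- list(glottal = .as_trace(glottal), device = .as_trace(device))
  if (!is.null(el)) traces$electrolarynx <- .as_trace(el)
  rates <- vapply(traces, function(tr) tr$sample_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("sample rate mismatch between excitations: ",
         paste(rates, collapse = ", "))
  }
  waveforms <- lapply(traces, function(tr) {
    peak <- max(abs(tr$samples))
    if (peak == 0) stop("silent excitation: ", tr$label)
    pressure_trace(tr$samples / peak, tr$sample_rate, tr$label)
  })
  spectra <- lapply(traces, spl_spectrum, weighting = weighting)
  rolloff <- lapply(spectra, harmonic_rolloff, f0 = f0,
                    f_max_band = f_band[2])
  nm <- names(spectra)
  correlations <- c()
  if (length(spectra) >= 2L) {
    for (i in seq_len(length(spectra) - 1L)) {
      for (j in seq((i + 1L), length(spectra))) {
        correlations[paste(nm[i], nm[j], sep = "_vs_")] <-
          spectral_correlation(spectra[[i]], spectra[[j]], f_band)
      }
    }
  }
  report <- list(waveforms = waveforms, spectra = spectra,
                 rolloff = rolloff, correlations = correlations,
                 f0 = f0, f_band = f_band, weighting = weighting)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in nm) {
      utils::write.csv(
        data.frame(frequency_hz = spectra[[k]]$frequencies,
                   magnitude_pa = spectra[[k]]$magnitudes,
                   spl_db = spectra[[k]]$spl),
        file.path(out_dir, paste0("spectrum_", k, ".csv")),
        row.names = FALSE)
    }
    jsonlite::write_json(
      list(f0 = f0, f_band = f_band, weighting = weighting,
           correlations = as.list(correlations),
           rolloff = lapply(rolloff, function(r) {
             list(mean_db_per_octave = r$mean, std_db_per_octave = r$std,
                  pairs_used = r$pairs_used)
           })),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
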