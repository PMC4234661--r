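# Shared fixtures: small grids, initial pulses and a lossless registry.

lossless_registry <- function(speed = 1540, density = 1000) {
  tissue_registry(data.frame(id = 255L, name = "lossless soft tissue",
                             density_kg_m3 = density, speed_m_s = speed,
                             atten_db_cm_mhz = 0))
}

# plane Gaussian pulse along x, uniform over the cross-section
plane_pulse <- function(dims, center, width = 8) {
  p0 <- array(0, dims)
  g <- exp(-((seq_len(dims[1]) - center) / width)^2)
  for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) p0[, j, k] <- g
  }
  p0
}

gaussian_ball <- function(dims, center = (dims + 1) / 2, width2 = 18) {
  p0 <- array(0, dims)
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      for (k in seq_len(dims[3])) {
        p0[i, j, k] <- exp(-((i - center[1])^2 + (j - center[2])^2 +
                               (k - center[3])^2) / width2)
      }
    }
  }
  p0
}

make_tone <- function(freq, duration, fs = 96e3, amplitude = 1, phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  pressure_trace(amplitude * sin(2 * pi * freq * t + phase), fs,
                 label = sprintf("tone_%g", freq))
}
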