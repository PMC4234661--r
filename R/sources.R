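#' Hard disc source specification
#'
#' Transducers are modeled as sinusoidal hard sources: every voxel of a
#' one-voxel-thick disc normal to the emission axis has its pressure
#' overwritten with `A * sin(2 pi f t + phase)` each step, with `A` derived
#' from the drive level in dB SPL. A foam baffle of the given thickness is
#' painted into the material fields directly behind the disc (opposite the
#' emission direction) to mimic the hemispherical radiation of a real
#' transducer.
#'
#' @param center_mm disc centre (x, y, z) in mm (voxel `[1,1,1]` is 0 mm).
#' @param frequency drive frequency in Hz.
#' @param phase_deg drive phase in degrees.
#' @param level_db drive amplitude in dB SPL re 20 uPa (105 dB ~ 3.557 Pa).
#' @param radius_mm disc radius in mm (default 6).
#' @param axis emission axis, `"x"`, `"y"` or `"z"`.
#' @param direction emission direction along the axis, `+1` or `-1`.
#' @param baffle_mm baffle thickness in mm (0 disables it).
#' @param baffle list with `density` (kg/m^3), `speed` (m/s), `attenuation`
#'   (dB/cm/MHz) of the baffle material; defaults to closed-cell
#'   polypropylene-foam-like values.
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(center_mm, frequency, phase_deg = 0, level_db = 105,
                        radius_mm = 6, axis = c("y", "x", "z"), direction = 1,
                        baffle_mm = 4,
                        baffle = list(density = 50, speed = 400,
                                      attenuation = 100)) {
  axis <- match.arg(axis)
  stopifnot(length(center_mm) == 3L, frequency > 0, radius_mm >= 0,
            direction %in% c(-1, 1), baffle_mm >= 0)
  structure(list(center_mm = as.numeric(center_mm), frequency = frequency,
                 phase_deg = phase_deg, level_db = level_db,
                 radius_mm = radius_mm, axis = axis, direction = direction,
                 baffle_mm = baffle_mm, baffle = baffle),
            class = "source_spec")
}

#' Microphone specification
#'
#' @param position_mm (x, y, z) position in mm.
#' @param label optional text label for the recorded trace.
#' @return an object of class `microphone_spec`.
#' @export
microphone_spec <- function(position_mm, label = NULL) {
  stopifnot(length(position_mm) == 3L)
  if (is.null(label)) {
    label <- sprintf("mic_%g_%g_%g", position_mm[1], position_mm[2],
                     position_mm[3])
  }
  structure(list(position_mm = as.numeric(position_mm), label = label),
            class = "microphone_spec")
}

# mm position -> 1-based voxel index triple
.mm_to_index <- function(pos_mm, spacing) {
  as.integer(round(pos_mm / (spacing * 1e3))) + 1L
}

# Linear indices of the one-voxel-thick disc (and baffle slab) of a source.
.prepare_source <- function(src, dims, spacing) {
  mm <- spacing * 1e3
  ctr <- .mm_to_index(src$center_mm, spacing)
  ax <- match(src$axis, c("x", "y", "z"))
  perp <- setdiff(1:3, ax)
  if (ctr[ax] < 1L || ctr[ax] > dims[ax]) stop("source disc outside domain")
  u <- (seq_len(dims[perp[1]]) - ctr[perp[1]]) * mm
  v <- (seq_len(dims[perp[2]]) - ctr[perp[2]]) * mm
  inside <- which(outer(u^2, v^2, "+") <= src$radius_mm^2, arr.ind = TRUE)
  if (nrow(inside) == 0L) inside <- cbind(ctr[perp[1]], ctr[perp[2]])
  span_u <- range(inside[, 1]); span_v <- range(inside[, 2])
  if (span_u[1] < 1L || span_u[2] > dims[perp[1]] ||
      span_v[1] < 1L || span_v[2] > dims[perp[2]]) {
    stop("source disc outside domain")
  }
  coords <- matrix(0L, nrow(inside), 3L)
  coords[, perp[1]] <- inside[, 1]
  coords[, perp[2]] <- inside[, 2]
  coords[, ax] <- ctr[ax]
  lin <- coords[, 1] + dims[1] * (coords[, 2] - 1L) +
    dims[1] * dims[2] * (coords[, 3] - 1L)
  # baffle slab behind the disc
  nb <- as.integer(round(src$baffle_mm / mm))
  baffle_lin <- integer(0)
  if (nb > 0L) {
    offs <- -src$direction * seq_len(nb)
    planes <- ctr[ax] + offs
    planes <- planes[planes >= 1L & planes <= dims[ax]]
    for (pl in planes) {
      cb <- coords
      cb[, ax] <- pl
      baffle_lin <- c(baffle_lin,
                      cb[, 1] + dims[1] * (cb[, 2] - 1L) +
                        dims[1] * dims[2] * (cb[, 3] - 1L))
    }
  }
  list(idx = as.integer(lin), baffle_idx = as.integer(baffle_lin),
       amplitude = spl_to_pressure(src$level_db),
       omega = 2 * pi * src$frequency, phase = src$phase_deg * pi / 180)
}

#' Overwrite the source discs with the drive signal (hard source)
#'
#' Sets `p = A sin(2 pi f t + phase)` at every voxel of each source disc.
#' Exposed for step-by-step use; [run_simulation()] does this internally
#' after each pressure update.
#'
#' @param state a `simulation_state`.
#' @param sources list of [source_spec()] (a single spec is accepted).
#' @param t simulation time in seconds.
#' @param spacing voxel spacing in metres.
#' @return the state, invisibly (fields are updated in place).
#' @export
inject_sources <- function(state, sources, t, spacing = 1e-3) {
  if (inherits(sources, "source_spec")) sources <- list(sources)
  dims <- state$dims
  for (src in sources) {
    prep <- .prepare_source(src, dims, spacing)
    cpp_inject(state$p, prep$idx,
               prep$amplitude * sin(prep$omega * t + prep$phase))
  }
  invisible(state)
}
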