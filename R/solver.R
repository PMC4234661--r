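#' Simulation configuration
#'
#' Bundles the time stepping and recording parameters of a run. The
#' microphone decimation factor is `round(1 / (dt * output_rate))`: every
#' `decimation`-th time step is kept, so the actual trace rate is
#' `1 / (dt * decimation)` (exactly `output_rate` when `dt` is chosen as an
#' integer fraction of it).
#'
#' @param dt time step in seconds.
#' @param n_steps number of leap-frog steps.
#' @param output_rate nominal microphone sampling rate in Hz (default
#'   96 kHz).
#' @param boundary `"mur"` (first-order absorbing) or `"rigid"` (closed
#'   box).
#' @param mur_faces which faces carry the absorbing update when
#'   `boundary = "mur"`; subset of `c("x0","x1","y0","y1","z0","z1")`.
#'   Faces not listed behave as rigid walls (useful for quasi-1D setups).
#' @param f_ref reference frequency (Hz) at which tissue attenuation is
#'   converted to the damping coefficient sigma.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(dt, n_steps, output_rate = 96e3,
                              boundary = c("mur", "rigid"),
                              mur_faces = c("x0", "x1", "y0", "y1",
                                            "z0", "z1"),
                              f_ref = 40e3) {
  boundary <- match.arg(boundary)
  all_faces <- c("x0", "x1", "y0", "y1", "z0", "z1")
  mur_faces <- match.arg(mur_faces, all_faces, several.ok = TRUE)
  stopifnot(dt > 0, n_steps >= 0, output_rate > 0, f_ref > 0)
  decimation <- max(1L, as.integer(round(1 / (dt * output_rate))))
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 output_rate = output_rate, decimation = decimation,
                 boundary = boundary,
                 mur_face_mask = all_faces %in% mur_faces,
                 f_ref = f_ref),
            class = "simulation_config")
}

#' Allocate a zero simulation state
#'
#' The state holds the scalar pressure field at integer nodes and the three
#' particle-velocity components at half-offset nodes, plus the previous
#' pressure field needed by the Mur boundary update. It is an environment:
#' the stepping functions modify it in place.
#'
#' @param dims integer triple (nx, ny, nz) of pressure nodes.
#' @return an object of class `simulation_state` with fields `p`, `vx`,
#'   `vy`, `vz`, `p_prev`, `step`, `dims`.
#' @export
simulation_state <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 2L))
  st <- new.env(parent = emptyenv())
  st$p <- array(0, dim = dims)
  st$p_prev <- array(0, dim = dims)
  st$vx <- array(0, dim = c(dims[1] - 1L, dims[2], dims[3]))
  st$vy <- array(0, dim = c(dims[1], dims[2] - 1L, dims[3]))
  st$vz <- array(0, dim = c(dims[1], dims[2], dims[3] - 1L))
  st$step <- 0L
  st$dims <- dims
  class(st) <- "simulation_state"
  st
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state> %d x %d x %d, step %d, max |p| = %.4g Pa\n",
              x$dims[1], x$dims[2], x$dims[3], x$step, max(abs(x$p))))
  invisible(x)
}

# Material coefficients precomputed at the staggered nodes:
#  - per velocity node: damping factor a and gradient factor b (semi-implicit
#    sigma treatment), with rho and sigma arithmetic means of the two
#    adjacent pressure nodes
#  - per pressure node: kappa * dt
#  - per boundary face: the Mur coefficient (c dt - delta)/(c dt + delta)
.avg_half <- function(x, axis) {
  d <- dim(x)
  switch(axis,
         x = (x[-d[1], , , drop = FALSE] + x[-1, , , drop = FALSE]) / 2,
         y = (x[, -d[2], , drop = FALSE] + x[, -1, , drop = FALSE]) / 2,
         z = (x[, , -d[3], drop = FALSE] + x[, , -1, drop = FALSE]) / 2)
}

#' Precompute solver coefficients
#'
#' @param fields a `material_fields` object (see
#'   [derive_material_fields()]).
#' @param dt time step in seconds.
#' @return an object of class `solver_coefficients`.
#' @export
solver_coefficients <- function(fields, dt) {
  stopifnot(inherits(fields, "material_fields"), dt > 0)
  comp <- function(axis) {
    rho <- .avg_half(fields$rho, axis)
    sig <- .avg_half(fields$sigma, axis)
    s <- sig * dt / (2 * rho)
    list(a = (1 - s) / (1 + s), b = (dt / rho) / (1 + s), rho = rho)
  }
  cx <- comp("x"); cy <- comp("y"); cz <- comp("z")
  d <- fields$dims
  mur <- function(cface) (cface * dt - fields$spacing) / (cface * dt + fields$spacing)
  structure(list(
    ax = cx$a, bx = cx$b, rho_x = cx$rho,
    ay = cy$a, by = cy$b, rho_y = cy$rho,
    az = cz$a, bz = cz$b, rho_z = cz$rho,
    kdt = fields$kappa * dt,
    mur_x0 = mur(fields$c[1, , ]), mur_x1 = mur(fields$c[d[1], , ]),
    mur_y0 = mur(fields$c[, 1, ]), mur_y1 = mur(fields$c[, d[2], ]),
    mur_z0 = mur(fields$c[, , 1]), mur_z1 = mur(fields$c[, , d[3]]),
    dt = dt, delta = fields$spacing, dims = d),
    class = "solver_coefficients")
}

.check_state_finite <- function(state, when) {
  if (!cpp_all_finite(state$p)) {
    stop(sprintf("instability: non-finite pressure field at step %d (%s)",
                 state$step, when))
  }
  invisible(TRUE)
}

#' Advance the particle-velocity fields by one time step
#'
#' Updates v from the pressure gradient with the fourth-order staggered
#' stencil `(27 (nearest pair) - (next pair)) / (24 delta)`, falling back to
#' the second-order stencil within one node of the domain faces, with the
#' loss term applied semi-implicitly. Density and sigma at a velocity node
#' are arithmetic means of the two adjacent pressure nodes.
#'
#' @param state a [simulation_state()] (modified in place).
#' @param fields a `material_fields` object.
#' @param dt time step (s).
#' @param coef optional precomputed [solver_coefficients()] (must match
#'   `fields` and `dt`); computing them once outside a loop is much faster.
#' @param check if `TRUE`, raise an instability error when the update
#'   produces non-finite values.
#' @return the state, invisibly.
#' @export
step_velocity <- function(state, fields, dt, coef = NULL, check = TRUE) {
  if (is.null(coef)) coef <- solver_coefficients(fields, dt)
  cpp_step_velocity(state$p, state$vx, state$vy, state$vz,
                    coef$ax, coef$bx, coef$ay, coef$by, coef$az, coef$bz,
                    state$dims, coef$delta)
  if (check && !cpp_all_finite(state$vx)) {
    stop(sprintf("instability: non-finite velocity field at step %d",
                 state$step))
  }
  invisible(state)
}

#' Advance the pressure field by one time step
#'
#' `p <- p - dt * kappa * div(v)` with the same (2,4)/(2,2) stencil policy as
#' [step_velocity()]. The pre-update pressure is saved into `state$p_prev`
#' for the Mur boundary update. The state's step counter is incremented.
#'
#' @inheritParams step_velocity
#' @return the state, invisibly.
#' @export
step_pressure <- function(state, fields, dt, coef = NULL, check = TRUE) {
  if (is.null(coef)) coef <- solver_coefficients(fields, dt)
  cpp_copy(state$p, state$p_prev)
  cpp_step_pressure(state$p, state$vx, state$vy, state$vz, coef$kdt,
                    state$dims, coef$delta)
  state$step <- state$step + 1L
  if (check) .check_state_finite(state, "after pressure update")
  invisible(state)
}

#' Apply the first-order Mur absorbing boundary
#'
#' Updates the pressure on all six domain faces from the one-way wave
#' equation using the local sound speed, absorbing normally incident plane
#' waves. Must be called after [step_pressure()] (it uses the pre-update
#' field stored in `state$p_prev`).
#'
#' @inheritParams step_velocity
#' @param faces logical vector of length 6 (x0, x1, y0, y1, z0, z1)
#'   selecting which faces are absorbing; others stay rigid.
#' @return the state, invisibly.
#' @export
apply_mur_boundary <- function(state, fields, dt, coef = NULL,
                               faces = rep(TRUE, 6)) {
  if (is.null(coef)) coef <- solver_coefficients(fields, dt)
  cpp_apply_mur(state$p, state$p_prev, state$dims,
                as.matrix(coef$mur_x0), as.matrix(coef$mur_x1),
                as.matrix(coef$mur_y0), as.matrix(coef$mur_y1),
                as.matrix(coef$mur_z0), as.matrix(coef$mur_z1),
                as.logical(faces))
  invisible(state)
}

#' Total acoustic energy of the state
#'
#' `E = sum(p^2 / (2 kappa) + rho |v|^2 / 2) * delta^3`, with density taken
#' at the staggered velocity nodes. Used as a conservation / dissipation
#' oracle: lossless closed boxes conserve it, sigma > 0 makes it
#' non-increasing once sources are off.
#'
#' @param state a [simulation_state()].
#' @param fields a `material_fields` object.
#' @return energy in joules.
#' @export
acoustic_energy <- function(state, fields) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(fields, "material_fields"))
  d3 <- fields$spacing^3
  pot <- sum(state$p^2 / (2 * fields$kappa))
  kin <- sum(.avg_half(fields$rho, "x") * state$vx^2) / 2 +
    sum(.avg_half(fields$rho, "y") * state$vy^2) / 2 +
    sum(.avg_half(fields$rho, "z") * state$vz^2) / 2
  (pot + kin) * d3
}

#' Run a full FDTD simulation
#'
#' Leap-frog loop over `config$n_steps` steps: velocity update, pressure
#' update, hard-source injection, boundary update, then microphone
#' recording every `config$decimation` steps. Identical inputs give
#' identical traces. The pressure field is checked for non-finite values
#' every `check_every` steps; a failure raises an instability error naming
#' the step.
#'
#' The Courant pre-check is a warning (not an error) so that deliberately
#' unstable configurations can be used to exercise the runtime instability
#' detector; note the fourth-order stencil is stable only up to 6/7 of the
#' classic bound (see [max_stable_timestep()]).
#'
#' @param grid a [voxel_grid()].
#' @param registry a [tissue_registry()] covering the grid labels.
#' @param config a [simulation_config()].
#' @param sources list of [source_spec()] (may be empty).
#' @param microphones list of [microphone_spec()].
#' @param initial_pressure optional 3D array of initial pressure (Pa).
#' @param check_every how often (in steps) to test the field for
#'   non-finite values.
#' @param progress print progress every ~10% of the run.
#' @return list with `traces` (one [pressure_trace()] per microphone;
#'   sample k is the pressure at step `k * decimation`, so a zero-step run
#'   yields empty traces), `state` (final fields), `fields`, `config`.
#' @export
run_simulation <- function(grid, registry, config, sources = list(),
                           microphones = list(), initial_pressure = NULL,
                           check_every = 25L, progress = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(config, "simulation_config"))
  if (inherits(sources, "source_spec")) sources <- list(sources)
  if (inherits(microphones, "microphone_spec")) microphones <- list(microphones)
  if (any(grid$dims < 8L)) stop("solver grids must be at least 8 voxels per axis")

  fields <- derive_material_fields(grid, registry, f_ref = config$f_ref)
  prep <- lapply(sources, .prepare_source, dims = grid$dims,
                 spacing = grid$spacing)
  for (i in seq_along(sources)) {
    if (length(prep[[i]]$baffle_idx) > 0L) {
      b <- sources[[i]]$baffle
      fields <- override_material(fields, prep[[i]]$baffle_idx,
                                  b$density, b$speed, b$attenuation)
    }
  }

  bound22 <- max_stable_timestep(fields, grid$spacing, scheme = "yee22")
  bound24 <- max_stable_timestep(fields, grid$spacing, scheme = "yee24")
  if (config$dt > bound22) {
    warning(sprintf(
      "dt = %.4g s exceeds the Courant bound %.4g s: the run will be unstable",
      config$dt, bound22))
  } else if (config$dt > bound24) {
    warning(sprintf(
      "dt = %.4g s exceeds the fourth-order stencil bound %.4g s (6/7 of the classic bound)",
      config$dt, bound24))
  }
  if (length(sources) > 0L) {
    f_max <- max(vapply(sources, function(s) s$frequency, numeric(1)))
    check_spatial_sampling(min(fields$c), f_max, grid$spacing)
  }

  mic_idx <- vapply(microphones, function(m) {
    ijk <- .mm_to_index(m$position_mm, grid$spacing)
    if (any(ijk < 1L) || any(ijk > grid$dims)) {
      stop("microphone outside domain: ", m$label)
    }
    ijk[1] + grid$dims[1] * (ijk[2] - 1L) +
      grid$dims[1] * grid$dims[2] * (ijk[3] - 1L)
  }, numeric(1))

  coef <- solver_coefficients(fields, config$dt)
  state <- simulation_state(grid$dims)
  if (!is.null(initial_pressure)) {
    stopifnot(all(dim(initial_pressure) == grid$dims))
    cpp_copy(as.numeric(initial_pressure), state$p)
  }
  for (i in seq_along(prep)) {
    cpp_inject(state$p, prep[[i]]$idx,
               prep[[i]]$amplitude * sin(prep[[i]]$phase))
  }

  n_out <- config$n_steps %/% config$decimation
  rec <- matrix(0, nrow = n_out, ncol = max(1L, length(mic_idx)))
  mur_x0 <- as.matrix(coef$mur_x0); mur_x1 <- as.matrix(coef$mur_x1)
  mur_y0 <- as.matrix(coef$mur_y0); mur_y1 <- as.matrix(coef$mur_y1)
  mur_z0 <- as.matrix(coef$mur_z0); mur_z1 <- as.matrix(coef$mur_z1)
  use_mur <- config$boundary == "mur"
  face_mask <- config$mur_face_mask %||% rep(TRUE, 6)
  report_at <- if (progress) {
    unique(pmax(1L, as.integer(seq(0.1, 1, by = 0.1) * config$n_steps)))
  } else integer(0)

  for (n in seq_len(config$n_steps)) {
    cpp_step_velocity(state$p, state$vx, state$vy, state$vz,
                      coef$ax, coef$bx, coef$ay, coef$by, coef$az, coef$bz,
                      state$dims, coef$delta)
    cpp_copy(state$p, state$p_prev)
    cpp_step_pressure(state$p, state$vx, state$vy, state$vz, coef$kdt,
                      state$dims, coef$delta)
    state$step <- n
    t_now <- n * config$dt
    for (i in seq_along(prep)) {
      cpp_inject(state$p, prep[[i]]$idx,
                 prep[[i]]$amplitude * sin(prep[[i]]$omega * t_now +
                                             prep[[i]]$phase))
    }
    if (use_mur) {
      cpp_apply_mur(state$p, state$p_prev, state$dims,
                    mur_x0, mur_x1, mur_y0, mur_y1, mur_z0, mur_z1,
                    face_mask)
    }
    if (n %% config$decimation == 0L && length(mic_idx) > 0L) {
      rec[n %/% config$decimation, ] <- state$p[mic_idx]
    }
    if (n %% check_every == 0L) .check_state_finite(state, "during run")
    if (n %in% report_at) {
      message(sprintf("  step %d / %d (%.0f%%)", n, config$n_steps,
                      100 * n / config$n_steps))
    }
  }
  .check_state_finite(state, "end of run")

  rate <- 1 / (config$dt * config$decimation)
  traces <- lapply(seq_along(microphones), function(i) {
    pressure_trace(rec[seq_len(n_out), i], rate, microphones[[i]]$label)
  })
  list(traces = traces, state = state, fields = fields, config = config)
}
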