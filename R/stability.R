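#' Maximum stable time step (Courant bound)
#'
#' For the 3D staggered-grid scheme the classic Courant bound is
#' \eqn{\Delta t \le \delta / (c_{max} \sqrt{3})}. The fourth-order spatial
#' stencil actually used by the solver has a slightly smaller stability
#' region, 6/7 of the classic bound (`scheme = "yee24"`); the classic
#' second-order bound (`scheme = "yee22"`) is the default and is the number
#' usually quoted for these simulations.
#'
#' @param x a [tissue_registry()], a `material_fields` object, or a numeric
#'   vector of sound speeds (m/s); the largest speed present is used.
#' @param delta spatial step in metres (default 1 mm).
#' @param scheme `"yee22"` (classic bound) or `"yee24"` (6/7 of it, matching
#'   the fourth-order stencil).
#' @return maximum stable dt in seconds.
#' @export
max_stable_timestep <- function(x, delta = 1e-3, scheme = c("yee22", "yee24")) {
  scheme <- match.arg(scheme)
  c_max <- if (inherits(x, "tissue_registry")) {
    max(x$entries$speed_m_s)
  } else if (inherits(x, "material_fields")) {
    max(x$c)
  } else if (is.numeric(x) && length(x) > 0) {
    max(x)
  } else {
    stop("empty material set: cannot determine maximum sound speed")
  }
  stopifnot(delta > 0, c_max > 0)
  dt <- delta / (c_max * sqrt(3))
  if (scheme == "yee24") dt <- dt * 6 / 7
  dt
}

#' Check spatial sampling against the shortest wavelength
#'
#' The spatial step should be 5--10 times smaller than the smallest signal
#' wavelength `c_min / f_max`; a warning is raised below 5 points per
#' wavelength.
#'
#' @param c_min smallest sound speed present (m/s).
#' @param f_max highest source frequency (Hz).
#' @param delta spatial step (m).
#' @return list with `wavelength` (m) and `points_per_wavelength`.
#' @export
check_spatial_sampling <- function(c_min, f_max, delta = 1e-3) {
  stopifnot(c_min > 0, f_max > 0, delta > 0)
  wavelength <- c_min / f_max
  ppw <- wavelength / delta
  if (ppw < 5) {
    warning(sprintf(
      "spatial step under-resolves the shortest wavelength: %.3g points per wavelength (want >= 5)",
      ppw))
  }
  list(wavelength = wavelength, points_per_wavelength = ppw)
}
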