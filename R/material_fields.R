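#' Convert a tabulated attenuation coefficient to a momentum-damping loss
#'
#' Tissue attenuation is tabulated in dB/cm/MHz, i.e. linear in frequency.
#' The solver models loss as a momentum damping term \eqn{\sigma v} in the
#' equation of motion, under which a plane wave decays as
#' \eqn{e^{-\alpha x}} with \eqn{\alpha = \sigma / (2 \rho c)} (in Np/m).
#' Inverting: \eqn{\sigma = 2 \rho c \alpha_{Np/m}} with
#' \eqn{\alpha_{Np/m} = \alpha_{dB/cm/MHz} \cdot (f / 10^6) \cdot 100 \cdot
#' \ln(10)/20}, evaluated at a reference frequency `f` (normally the
#' ultrasonic carrier). The result is linear in both `alpha` and `f`.
#'
#' @param alpha attenuation in dB/cm/MHz (>= 0).
#' @param f reference frequency in Hz (>= 0).
#' @param rho density in kg/m^3.
#' @param c_sound speed of sound in m/s.
#' @return loss coefficient sigma in kg m^-3 s^-1.
#' @export
attenuation_to_sigma <- function(alpha, f, rho, c_sound) {
  if (any(alpha < 0) || any(f < 0) || any(rho < 0) || any(c_sound < 0)) {
    stop("attenuation_to_sigma: all inputs must be >= 0")
  }
  alpha_np_m <- alpha * (f / 1e6) * 100 * log(10) / 20
  2 * rho * c_sound * alpha_np_m
}

#' Derive per-node material fields from a labeled grid
#'
#' Expands the tissue registry over the voxel lattice into the per-node
#' fields the solver consumes: density `rho` (kg/m^3), speed `c` (m/s), bulk
#' modulus `kappa = rho c^2` (Pa), and the loss coefficient `sigma`
#' (kg m^-3 s^-1) from [attenuation_to_sigma()] at the reference frequency
#' `f_ref`.
#'
#' @param grid a [voxel_grid()].
#' @param registry a [tissue_registry()] covering every label in `grid`.
#' @param f_ref reference frequency in Hz at which sigma is evaluated
#'   (default 40 kHz, the ultrasonic carrier).
#' @return an object of class `material_fields` with 3D arrays `rho`, `c`,
#'   `kappa`, `sigma` plus `spacing`, `dims`, `f_ref`.
#' @export
derive_material_fields <- function(grid, registry, f_ref = 40e3) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(registry, "tissue_registry"),
            f_ref > 0)
  validate_labels(grid, registry)
  idx <- as.vector(grid$labels) + 1L
  rho_lut <- .registry_lut(registry, "density_kg_m3")
  c_lut <- .registry_lut(registry, "speed_m_s")
  a_lut <- .registry_lut(registry, "atten_db_cm_mhz")
  rho <- array(rho_lut[idx], dim = grid$dims)
  cc <- array(c_lut[idx], dim = grid$dims)
  alpha <- array(a_lut[idx], dim = grid$dims)
  structure(list(rho = rho, c = cc, kappa = rho * cc^2,
                 sigma = attenuation_to_sigma(alpha, f_ref, rho, cc),
                 spacing = grid$spacing, dims = grid$dims, f_ref = f_ref),
            class = "material_fields")
}

#' @export
print.material_fields <- function(x, ...) {
  cat(sprintf(
    "<material_fields> %d x %d x %d @ %g mm; c in [%g, %g] m/s; f_ref %g Hz\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing * 1e3,
    min(x$c), max(x$c), x$f_ref))
  invisible(x)
}

#' Override material properties inside a voxel mask
#'
#' Used to paint non-registry materials (e.g. a transducer's foam baffle)
#' into already-derived fields.
#'
#' @param fields a `material_fields` object.
#' @param mask logical array (or linear index vector) selecting voxels.
#' @param density,speed,attenuation material properties of the override.
#' @return modified `material_fields`.
#' @export
override_material <- function(fields, mask, density, speed, attenuation = 0) {
  stopifnot(inherits(fields, "material_fields"),
            density > 0, speed > 0, attenuation >= 0)
  fields$rho[mask] <- density
  fields$c[mask] <- speed
  fields$kappa[mask] <- density * speed^2
  fields$sigma[mask] <- attenuation_to_sigma(attenuation, fields$f_ref,
                                             density, speed)
  fields
}
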