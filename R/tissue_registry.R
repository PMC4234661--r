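#' Tissue acoustic property registry
#'
#' A `tissue_registry` maps integer tissue ids (as found in a labeled voxel
#' volume) to the acoustic properties the solver needs: mass density
#' \eqn{\rho} (kg/m^3), speed of sound \eqn{c} (m/s) and the attenuation
#' coefficient \eqn{\alpha} in dB/cm/MHz. The package ships a registry of the
#' 26 tissue types of the AustinMan-style upper-body voxel model (plus the two
#' air entries and a generic "Soft tissue" fallback registered under id 255);
#' see [default_tissue_registry()].
#'
#' @param entries a data frame with columns `id`, `name`, `density_kg_m3`,
#'   `speed_m_s`, `atten_db_cm_mhz`.
#' @return an object of class `tissue_registry`.
#' @seealso [load_tissue_table()], [tissue_properties()]
#' @export
tissue_registry <- function(entries) {
  stopifnot(is.data.frame(entries))
  required <- c("id", "name", "density_kg_m3", "speed_m_s", "atten_db_cm_mhz")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0L) {
    stop("tissue table is missing column(s): ", paste(missing, collapse = ", "))
  }
  entries <- entries[required]
  entries$id <- as.integer(entries$id)
  for (col in c("density_kg_m3", "speed_m_s", "atten_db_cm_mhz")) {
    entries[[col]] <- as.numeric(entries[[col]])
  }
  if (anyNA(entries$id) || anyNA(entries$density_kg_m3) ||
      anyNA(entries$speed_m_s) || anyNA(entries$atten_db_cm_mhz)) {
    stop("malformed tissue table row: non-numeric id or property")
  }
  if (anyDuplicated(entries$id)) {
    dup <- unique(entries$id[duplicated(entries$id)])
    stop("duplicate tissue id(s): ", paste(dup, collapse = ", "))
  }
  if (any(entries$density_kg_m3 <= 0)) stop("tissue density must be > 0")
  if (any(entries$speed_m_s <= 0)) stop("tissue speed of sound must be > 0")
  if (any(entries$atten_db_cm_mhz < 0)) stop("tissue attenuation must be >= 0")
  structure(list(entries = entries), class = "tissue_registry")
}

#' Read a tissue property table from CSV
#'
#' Expects columns `id`, `name`, `density_kg_m3`, `speed_m_s`,
#' `atten_db_cm_mhz`. Duplicate ids, non-positive densities or speeds, and
#' negative attenuations are rejected.
#'
#' @param path path to a CSV file.
#' @return a [tissue_registry()].
#' @export
load_tissue_table <- function(path) {
  if (!file.exists(path)) stop("tissue table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tissue_registry(df)
}

#' The bundled tissue registry
#'
#' Returns the registry shipped with the package: density, speed of sound and
#' attenuation for the labeled tissue types of a 1 mm upper-body voxel model
#' (air, soft tissues, cartilage, bone, teeth, ...), with a generic
#' "Soft tissue" entry (1000 kg/m^3, 1540 m/s, 0.5 dB/cm/MHz) under the
#' reserved id 255 used by the homogeneous phantoms.
#'
#' @return a [tissue_registry()].
#' @export
default_tissue_registry <- function() {
  path <- system.file("extdata", "tissue_table.csv", package = "beatfdtd",
                      mustWork = TRUE)
  load_tissue_table(path)
}

#' Look up the properties of one tissue id
#'
#' @param registry a [tissue_registry()].
#' @param id integer tissue id.
#' @return a one-row data frame (id, name, density_kg_m3, speed_m_s,
#'   atten_db_cm_mhz). Unknown ids are an error, never a silent default.
#' @export
tissue_properties <- function(registry, id) {
  stopifnot(inherits(registry, "tissue_registry"), length(id) == 1L)
  row <- registry$entries[registry$entries$id == as.integer(id), , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown tissue id: ", id)
  row
}

#' @export
print.tissue_registry <- function(x, ...) {
  e <- x$entries
  cat(sprintf("<tissue_registry> %d tissues, c in [%g, %g] m/s\n",
              nrow(e), min(e$speed_m_s), max(e$speed_m_s)))
  invisible(x)
}

#' Registered tissue ids
#' @param registry a [tissue_registry()].
#' @return integer vector of ids.
#' @export
tissue_ids <- function(registry) {
  stopifnot(inherits(registry, "tissue_registry"))
  registry$entries$id
}

# Fast property lookup tables indexed by id + 1 (ids are uint8-ranged).
.registry_lut <- function(registry, what) {
  e <- registry$entries
  lut <- rep(NA_real_, max(e$id) + 1L)
  lut[e$id + 1L] <- e[[what]]
  lut
}

#' Convert a sound pressure level to pressure
#'
#' SPL is referenced to 20 micropascal: `p = 20e-6 * 10^(level/20)`.
#'
#' @param level sound pressure level in dB SPL (re 20 uPa).
#' @return pressure in Pa.
#' @seealso [pressure_to_spl()]
#' @export
spl_to_pressure <- function(level) {
  20e-6 * 10^(level / 20)
}

#' Convert a pressure to sound pressure level
#'
#' @param p pressure in Pa (must be >= 0; 0 maps to -Inf).
#' @return level in dB SPL re 20 uPa.
#' @export
pressure_to_spl <- function(p) {
  if (any(p < 0)) stop("pressure must be >= 0")
  20 * log10(p / 20e-6)
}
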