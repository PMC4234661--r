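#' Labeled voxel volume
#'
#' A `voxel_grid` is a 3D lattice of integer tissue ids on a uniform grid.
#' Voxel `[1,1,1]` sits at position (0 mm, 0 mm, 0 mm) and position in metres
#' is `(index - 1) * spacing` along each axis (right-handed x, y, z).
#'
#' @param labels 3D integer array of tissue ids.
#' @param spacing voxel edge length in metres (default `1e-3`, i.e. 1 mm^3
#'   voxels).
#' @return an object of class `voxel_grid` with fields `labels`, `dims`,
#'   `spacing`.
#' @export
voxel_grid <- function(labels, spacing = 1e-3) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("labels must be a 3D array")
  }
  if (anyNA(labels)) stop("labels must not contain NA")
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, dims = dim(labels), spacing = spacing),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %g mm, %d distinct labels\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing * 1e3,
              length(unique(as.vector(x$labels)))))
  invisible(x)
}

#' Check that every label of a grid is registered
#' @param grid a [voxel_grid()].
#' @param registry a [tissue_registry()].
#' @return invisibly `TRUE`; unknown labels are an error.
#' @export
validate_labels <- function(grid, registry) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(registry, "tissue_registry"))
  present <- sort(unique(as.vector(grid$labels)))
  unknown <- setdiff(present, tissue_ids(registry))
  if (length(unknown) > 0L) {
    stop("unknown tissue id(s) in volume: ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a labeled voxel volume from a raw binary file
#'
#' The default dialect is a flat binary of unsigned 8-bit tissue ids stored as
#' z-major slices (x fastest, then y, then z), with a YAML sidecar
#' (`<path>.yaml`) declaring `dims`, `order`, `dtype` and `endianness`.
#' Arguments given explicitly override the sidecar.
#'
#' @param path path to the raw file.
#' @param dims integer triple (nx, ny, nz); taken from the sidecar if `NULL`.
#' @param dtype `"uint8"` or `"uint16"`.
#' @param endianness `"little"` or `"big"` (relevant for uint16 only).
#' @param spacing voxel edge length in metres.
#' @param registry optional [tissue_registry()]; when supplied, labels absent
#'   from the registry are an error listing the offending ids.
#' @return a [voxel_grid()].
#' @export
read_voxel_volume <- function(path, dims = NULL, dtype = NULL,
                              endianness = NULL, spacing = NULL,
                              registry = NULL) {
  if (!file.exists(path)) stop("voxel volume not found: ", path)
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  dims <- as.integer(dims %||% meta$dims %||%
                       stop("dims not given and no sidecar found"))
  dtype <- dtype %||% meta$dtype %||% "uint8"
  endianness <- endianness %||% meta$endianness %||% "little"
  spacing <- spacing %||% meta$spacing_m %||% 1e-3
  order <- meta$order %||% "xyz"
  if (!identical(order, "xyz")) {
    stop("unsupported voxel storage order: ", order)
  }
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  n <- prod(dims)
  bytes_per <- switch(dtype, uint8 = 1L, uint16 = 2L,
                      stop("unsupported dtype: ", dtype))
  expect_size <- n * bytes_per
  actual <- file.size(path)
  if (actual != expect_size) {
    stop(sprintf("file size mismatch: %d bytes on disk, %d expected for %s %dx%dx%d",
                 actual, expect_size, dtype, dims[1], dims[2], dims[3]))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "integer", n = n, size = bytes_per,
                  signed = FALSE, endian = endianness)
  labels <- array(vals, dim = dims)
  grid <- voxel_grid(labels, spacing = spacing)
  if (!is.null(registry)) validate_labels(grid, registry)
  grid
}

#' Write a voxel grid as raw binary plus YAML sidecar
#'
#' Inverse of [read_voxel_volume()]; the round trip is bit-exact.
#'
#' @param grid a [voxel_grid()].
#' @param path output path for the raw file; the sidecar goes to
#'   `<path>.yaml`.
#' @param dtype `"uint8"` (labels must fit) or `"uint16"`.
#' @return invisibly `path`.
#' @export
write_voxel_volume <- function(grid, path, dtype = "uint8") {
  stopifnot(inherits(grid, "voxel_grid"))
  bytes_per <- switch(dtype, uint8 = 1L, uint16 = 2L,
                      stop("unsupported dtype: ", dtype))
  maxval <- if (bytes_per == 1L) 255L else 65535L
  if (any(grid$labels > maxval)) stop("labels exceed ", dtype, " range")
  con <- file(path, "wb")
  on.exit(close(con))
  if (bytes_per == 1L) {
    writeBin(as.raw(as.vector(grid$labels)), con)
  } else {
    writeBin(as.integer(as.vector(grid$labels)), con, size = 2L,
             endian = "little")
  }
  yaml::write_yaml(list(dims = as.integer(grid$dims), order = "xyz",
                        dtype = dtype, endianness = "little",
                        spacing_m = grid$spacing),
                   paste0(path, ".yaml"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical tissue ids used by the phantoms
.ID_INT_AIR <- 1L
.ID_CARTILAGE <- 112L
.ID_FAT <- 136L
.ID_MUSCLE <- 180L
.ID_SKIN <- 204L
.ID_SOFT_TISSUE <- 255L

#' Homogeneous soft-tissue phantom
#'
#' A block filled with the generic soft-tissue material (id 255;
#' 1000 kg/m^3, 1540 m/s, 0.5 dB/cm/MHz).
#'
#' @param dims integer triple of voxel counts (default 64^3).
#' @param spacing voxel edge in metres.
#' @return a [voxel_grid()].
#' @export
make_soft_tissue_phantom <- function(dims = c(64L, 64L, 64L), spacing = 1e-3) {
  voxel_grid(array(.ID_SOFT_TISSUE, dim = dims), spacing = spacing)
}

#' Synthetic layered neck phantom
#'
#' A desk-scale stand-in for the anatomical neck geometry that matters to the
#' difference-frequency experiment: a layered slab of skin / fat / muscle /
#' cartilage stacked along +y starting at the y = 0 face (where the transducer
#' sits), an air-filled cylindrical airway lumen running along z beyond the
#' layers, and muscle everywhere else. Deterministic for fixed parameters.
#'
#' @param dims voxel counts (nx, ny, nz).
#' @param skin_mm,fat_mm,muscle_mm,cartilage_mm layer thicknesses in mm
#'   (0 allowed; all-zero with `airway_radius_mm = 0` gives a homogeneous
#'   muscle block).
#' @param airway_radius_mm lumen radius in mm; 0 suppresses the airway.
#' @param airway_center_mm (x, y) centre of the lumen axis in mm; default
#'   centred in x, just beyond the layers in y.
#' @param spacing voxel edge in metres.
#' @return a [voxel_grid()].
#' @export
make_neck_phantom <- function(dims = c(64L, 64L, 64L),
                              skin_mm = 2, fat_mm = 4, muscle_mm = 12,
                              cartilage_mm = 4, airway_radius_mm = 5,
                              airway_center_mm = NULL, spacing = 1e-3) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 8L))
  mm <- spacing * 1e3  # voxels per mm is 1/mm
  thick <- c(skin_mm, fat_mm, muscle_mm, cartilage_mm)
  if (any(thick < 0)) stop("layer thicknesses must be >= 0")
  nlay <- as.integer(round(thick / mm))
  total <- sum(nlay)
  if (total >= dims[2]) stop("layers exceed domain depth")
  labels <- array(.ID_MUSCLE, dim = dims)
  ids <- c(.ID_SKIN, .ID_FAT, .ID_MUSCLE, .ID_CARTILAGE)
  y0 <- 0L
  for (k in seq_along(ids)) {
    if (nlay[k] > 0L) {
      labels[, (y0 + 1L):(y0 + nlay[k]), ] <- ids[k]
      y0 <- y0 + nlay[k]
    }
  }
  if (airway_radius_mm > 0) {
    if (is.null(airway_center_mm)) {
      airway_center_mm <- c((dims[1] - 1) / 2 * mm,
                            total * mm + airway_radius_mm + 2)
    }
    cx <- airway_center_mm[1]; cy <- airway_center_mm[2]
    if (cy - airway_radius_mm < total * mm) {
      stop("airway intersects the layered slab: move it beyond the layers")
    }
    if (cy - airway_radius_mm <= 0) stop("airway intersects source face")
    if (cy + airway_radius_mm >= (dims[2] - 1) * mm) {
      stop("airway exceeds domain depth")
    }
    xs <- ((seq_len(dims[1]) - 1) * mm - cx)^2
    ys <- ((seq_len(dims[2]) - 1) * mm - cy)^2
    inside <- outer(xs, ys, "+") <= airway_radius_mm^2
    idx <- which(inside, arr.ind = TRUE)
    for (z in seq_len(dims[3])) {
      labels[cbind(idx, z)] <- .ID_INT_AIR
    }
  }
  voxel_grid(labels, spacing = spacing)
}
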