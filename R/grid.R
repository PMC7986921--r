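#' Tissue property grid
#'
#' A regular voxel grid carrying the tissue properties needed to turn electric
#' fields into local SAR: electrical conductivity `sigma` (S/m), mass density
#' `rho` (kg/m^3), and a logical body mask separating tissue from air. Voxel
#' positions are implied by the grid shape and the physical voxel size; axes
#' are ordered (x, y, z) with x fastest.
#'
#' @param shape Integer vector `c(nx, ny, nz)`.
#' @param voxel_size Numeric length-1 or length-3, voxel edge length in meters.
#' @param sigma Conductivity array (S/m), dim `shape`, or a scalar.
#' @param rho Mass density array (kg/m^3), dim `shape`, or a scalar.
#' @param body_mask Logical array, dim `shape`, or `NULL` for all-tissue.
#'
#' @return An object of class `tissue_grid`.
#' @export
tissue_grid <- function(shape, voxel_size, sigma, rho, body_mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_trigsar("`shape` must be three positive voxel counts", "trigsar_domain_error")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop_trigsar("voxel_size must be positive", "trigsar_domain_error")
  expand <- function(x, what) {
    if (length(x) == 1L) x <- array(x, dim = shape)
    if (!identical(dim(x), shape)) # dim of array vs integer vector
      if (!identical(as.integer(dim(x)), shape))
        stop_trigsar(paste0("`", what, "` does not match grid shape"), "trigsar_shape_error")
    x
  }
  sigma <- expand(sigma, "sigma")
  rho <- expand(rho, "rho")
  if (is.null(body_mask)) body_mask <- array(TRUE, dim = shape)
  body_mask <- expand(body_mask, "body_mask")
  if (any(sigma < 0, na.rm = TRUE))
    stop_trigsar("conductivity must be non-negative", "trigsar_domain_error")
  if (any(rho[body_mask] <= 0))
    stop_trigsar("mass density must be positive on the body mask", "trigsar_invalid_tissue")
  structure(
    list(shape = shape, voxel_size = as.numeric(voxel_size),
         sigma = sigma, rho = rho, body_mask = body_mask),
    class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("<tissue_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %d body voxels\n",
              x$shape[1], x$shape[2], x$shape[3],
              1e3 * x$voxel_size[1], 1e3 * x$voxel_size[2], 1e3 * x$voxel_size[3],
              sum(x$body_mask)))
  invisible(x)
}

#' Voxel mass of a tissue grid
#'
#' Tissue mass per voxel in kilograms (`rho * voxel volume`), zero outside the
#' body mask so that air never contributes to cube averaging.
#'
#' @param grid A [tissue_grid].
#' @return Numeric array of voxel masses (kg), dim = grid shape.
#' @export
voxel_mass <- function(grid) {
  stopifnot(inherits(grid, "tissue_grid"))
  m <- grid$rho * prod(grid$voxel_size)
  m[!grid$body_mask] <- 0
  m
}

#' Per-channel electric-field maps on a tissue grid
#'
#' Holds the three Cartesian components of the complex electric field
#' transmitted by each channel under unit (1 W) excitation, in V/m per
#' sqrt(W). Arrays are indexed `[channel, x, y, z]`.
#'
#' @param grid A [tissue_grid].
#' @param ex,ey,ez Complex arrays `[n_channels, nx, ny, nz]`.
#'
#' @return An object of class `channel_field_set`.
#' @export
channel_field_set <- function(grid, ex, ey, ez) {
  stopifnot(inherits(grid, "tissue_grid"))
  d <- dim(ex)
  if (is.null(d) || length(d) != 4L)
    stop_trigsar("field arrays must be [n_channels, nx, ny, nz]", "trigsar_shape_error")
  if (!identical(as.integer(d[-1]), grid$shape))
    stop_trigsar("field arrays do not match the grid shape", "trigsar_shape_error")
  if (!identical(dim(ey), d) || !identical(dim(ez), d))
    stop_trigsar("ex, ey, ez must share dimensions", "trigsar_shape_error")
  nc <- as.integer(d[1])
  if (nc < 3L)
    stop_trigsar("at least 3 channels are required", "trigsar_domain_error")
  as_cx <- function(a) { storage.mode(a) <- "complex"; a }
  structure(
    list(grid = grid, ex = as_cx(ex), ey = as_cx(ey), ez = as_cx(ez),
         n_channels = nc),
    class = "channel_field_set")
}

#' @export
print.channel_field_set <- function(x, ...) {
  cat(sprintf("<channel_field_set> %d channels on ", x$n_channels))
  print(x$grid)
  invisible(x)
}

#' Per-channel drive vector
#'
#' A drive setting for an `Nc`-channel transmit array: non-negative amplitudes
#' in sqrt(W) (so squared amplitudes are per-channel powers) and, optionally,
#' phases in radians. A drive without phases denotes an amplitude-only setting,
#' e.g. when the phase monitoring chain is absent or untrusted.
#'
#' @param amplitudes Non-negative numeric vector, sqrt(W).
#' @param phases Optional numeric vector of phases (rad), same length.
#' @return An object of class `drive_vector` with derived `total_power` (W).
#' @export
drive_vector <- function(amplitudes, phases = NULL) {
  amplitudes <- as.numeric(amplitudes)
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop_trigsar("amplitudes must be finite and non-negative", "trigsar_domain_error")
  if (!is.null(phases)) {
    phases <- as.numeric(phases)
    if (length(phases) != length(amplitudes))
      stop_trigsar("phases and amplitudes differ in length", "trigsar_shape_error")
  }
  structure(
    list(amplitudes = amplitudes, phases = phases,
         total_power = sum(amplitudes^2)),
    class = "drive_vector")
}

#' @export
print.drive_vector <- function(x, ...) {
  cat(sprintf("<drive_vector> %d channels, P_tot = %.4g W, phases %s\n",
              length(x$amplitudes), x$total_power,
              if (is.null(x$phases)) "unknown" else "known"))
  invisible(x)
}

#' Complex channel weights of a drive
#'
#' @param drive A [drive_vector] with phases.
#' @return Complex vector `amplitudes * exp(1i * phases)`.
#' @export
drive_weights <- function(drive) {
  stopifnot(inherits(drive, "drive_vector"))
  if (is.null(drive$phases))
    stop_trigsar("drive has no phases", "trigsar_domain_error")
  drive$amplitudes * exp(1i * drive$phases)
}
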