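#' Projection stack
#'
#' A stack of 2-D detector readings in the line-integral (post-log) domain,
#' bound to the geometry that produced them.  Data are stored as a 3-D array
#' of dim `(det_nu, det_nv, n_views)` (u fastest, matching R column-major
#' layout).
#'
#' @param data 3-D numeric array, dim `(det_nu, det_nv, n_views)`.
#' @param geometry a [scan_geometry()] whose detector/view counts match.
#' @param stage processing stage tag, one of `"raw"`, `"preweighted"`,
#'   `"filtered"`, `"simulated"`.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(data, geometry,
                           stage = c("raw", "preweighted", "filtered",
                                     "simulated")) {
  stage <- match.arg(stage)
  stopifnot(inherits(geometry, "scan_geometry"))
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  if (length(d) != 3L)
    stop("projection data must be a 3-D array (nu, nv, n_views)")
  expect <- c(geometry$det_nu, geometry$det_nv, length(geometry$angles))
  if (!all(d == expect))
    stop(sprintf(paste0("projection data dim (%d, %d, %d) does not match ",
                        "geometry (nu=%d, nv=%d, views=%d)"),
                 d[1], d[2], d[3], expect[1], expect[2], expect[3]))
  if (!all(is.finite(data))) {
    bad <- which(apply(!is.finite(data), 3L, any))
    stop("non-finite projection values in view(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(data = data, geometry = geometry, stage = stage),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Projection set [%s]: %d views of %d x %d, range [%.4g, %.4g]\n",
              x$stage, d[3], d[1], d[2], min(x$data), max(x$data)))
  invisible(x)
}

set_stage <- function(proj, stage) {
  proj$stage <- stage
  proj
}

#' Reconstructed volume
#'
#' A 3-D voxel grid of linear attenuation coefficients (mm^-1) or Hounsfield
#' units.  Data are stored as an array of dim `(nx, ny, nz)`.
#'
#' @param data 3-D numeric array (nx, ny, nz), all finite.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param origin physical position (mm) of the centre of voxel (1,1,1).
#' @param unit `"mu_mm^-1"` (attenuation per mm) or `"HU"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = NULL,
                      unit = c("mu_mm^-1", "HU")) {
  unit <- match.arg(unit)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stop("volume data must be a 3-D array")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), unit = unit),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("CT volume %d x %d x %d [%s], spacing (%g, %g, %g) mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$unit,
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Grid specification of a volume
#' @param vol a [ct_volume()].
#' @return The matching [grid_spec()].
#' @export
volume_grid <- function(vol) {
  grid_spec(dim(vol$data), vol$spacing, vol$origin)
}

#' Convert attenuation coefficients to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`.
#'
#' @param vol a [ct_volume()] in unit `"mu_mm^-1"`.
#' @param mu_water attenuation of water in mm^-1 (> 0), default 0.02.
#' @return The volume in unit `"HU"`.
#' @export
mu_to_hu <- function(vol, mu_water = 0.02) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$unit != "mu_mm^-1") stop("mu_to_hu expects a volume in mu_mm^-1")
  if (!(is.numeric(mu_water) && length(mu_water) == 1L && mu_water > 0))
    stop("mu_water must be a positive scalar")
  vol$data <- 1000 * (vol$data - mu_water) / mu_water
  vol$unit <- "HU"
  vol
}

#' Convert Hounsfield units back to attenuation coefficients
#' @inheritParams mu_to_hu
#' @param vol a [ct_volume()] in unit `"HU"`.
#' @return The volume in unit `"mu_mm^-1"`.
#' @export
hu_to_mu <- function(vol, mu_water = 0.02) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$unit != "HU") stop("hu_to_mu expects a volume in HU")
  if (!(is.numeric(mu_water) && length(mu_water) == 1L && mu_water > 0))
    stop("mu_water must be a positive scalar")
  vol$data <- mu_water * (1 + vol$data / 1000)
  vol$unit <- "mu_mm^-1"
  vol
}
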