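#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam acquisition: source-axis distance (SAD),
#' source-detector distance (SDD), a flat detector grid, and the gantry
#' angles of the views.
#'
#' Coordinate convention (right-handed, patient-style): the rotation axis is
#' +z, and at gantry angle 0 degrees the source sits on the -y axis at
#' distance `sad` from the isocenter while the detector centre sits on +y at
#' distance `sdd - sad`.  Detector coordinate u increases with +x at angle 0
#' and rotates with the gantry; v is parallel to +z.  Angles increase
#' counter-clockwise when viewed from +z.
#'
#' @param sad source-axis distance in mm (> 0).
#' @param sdd source-detector distance in mm (> `sad`).
#' @param det_nu,det_nv detector pixel counts along u (columns) and v (rows).
#' @param det_du,det_dv detector pixel pitch in mm.
#' @param angles gantry angles in degrees, one per view, in acquisition order.
#' @param arc_deg total scan arc in degrees, in (0, 360]. Defaults to the
#'   span implied by `angles` (range plus one angular step), rounded to 360
#'   when within half a step of a full turn.
#' @param det_offset_u,det_offset_v detector centre offset in mm.
#'
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(sad, sdd, det_nu, det_nv, det_du, det_dv,
                          angles, arc_deg = NULL,
                          det_offset_u = 0, det_offset_v = 0) {
  stopifnot(is.numeric(sad), length(sad) == 1L, is.finite(sad),
            is.numeric(sdd), length(sdd) == 1L, is.finite(sdd))
  if (!(sdd > sad && sad > 0))
    stop("scan_geometry requires sdd > sad > 0 (got sad=", sad,
         ", sdd=", sdd, ")")
  det_nu <- as.integer(det_nu); det_nv <- as.integer(det_nv)
  if (det_nu < 1L || det_nv < 1L)
    stop("detector pixel counts must be >= 1")
  if (!(det_du > 0 && det_dv > 0))
    stop("detector pixel pitch must be > 0")
  angles <- as.numeric(angles)
  if (length(angles) < 1L || any(!is.finite(angles)))
    stop("angles must be a non-empty vector of finite gantry angles (deg)")
  if (is.null(arc_deg)) {
    if (length(angles) > 1L) {
      step <- diff(range(angles)) / (length(angles) - 1L)
      arc_deg <- diff(range(angles)) + step
      if (abs(arc_deg - 360) < step / 2) arc_deg <- 360
    } else arc_deg <- 360
  }
  if (!(arc_deg > 0 && arc_deg <= 360))
    stop("arc_deg must lie in (0, 360], got ", arc_deg)
  structure(list(sad = sad, sdd = sdd,
                 det_nu = det_nu, det_nv = det_nv,
                 det_du = det_du, det_dv = det_dv,
                 angles = angles, arc_deg = arc_deg,
                 det_offset_u = det_offset_u, det_offset_v = det_offset_v),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("Cone-beam scan geometry\n")
  cat(sprintf("  SAD %.1f mm, SDD %.1f mm (magnification %.3f)\n",
              x$sad, x$sdd, x$sdd / x$sad))
  cat(sprintf("  detector %d x %d px, pitch %.3f x %.3f mm, offset (%g, %g) mm\n",
              x$det_nu, x$det_nv, x$det_du, x$det_dv,
              x$det_offset_u, x$det_offset_v))
  cat(sprintf("  %d views over %.1f deg arc [%.2f .. %.2f]\n",
              length(x$angles), x$arc_deg, min(x$angles), max(x$angles)))
  invisible(x)
}

is_full_scan <- function(geom) geom$arc_deg >= 360 - 1e-9

#' Source focal-spot position at a gantry angle
#'
#' @param geom a [scan_geometry()].
#' @param angle_deg gantry angle in degrees (vectorised).
#' @return A matrix with columns x, y, z (mm), one row per angle.
#' @export
source_position <- function(geom, angle_deg) {
  b <- angle_deg * pi / 180
  cbind(x = geom$sad * sin(b), y = -geom$sad * cos(b), z = 0 * b)
}

#' Physical centre position of a detector pixel
#'
#' @param geom a [scan_geometry()].
#' @param angle_deg gantry angle in degrees (scalar).
#' @param iu,iv 1-based detector pixel indices along u and v (vectorised).
#' @return A matrix with columns x, y, z (mm).
#' @export
detector_pixel_position <- function(geom, angle_deg, iu, iv) {
  b <- angle_deg * pi / 180
  uvec <- c(cos(b), sin(b), 0)
  vvec <- c(0, 0, 1)
  ctr <- c(-(geom$sdd - geom$sad) * sin(b), (geom$sdd - geom$sad) * cos(b), 0) +
    geom$det_offset_u * uvec + geom$det_offset_v * vvec
  u <- (iu - 1 - (geom$det_nu - 1) / 2) * geom$det_du
  v <- (iv - 1 - (geom$det_nv - 1) / 2) * geom$det_dv
  cbind(x = ctr[1] + u * uvec[1] + v * vvec[1],
        y = ctr[2] + u * uvec[2] + v * vvec[2],
        z = ctr[3] + u * uvec[3] + v * vvec[3])
}

#' Physical detector u coordinates of pixel columns
#'
#' Distance (mm) of each detector column centre from the central ray axis,
#' including the detector offset.
#' @param geom a [scan_geometry()].
#' @return Numeric vector of length `det_nu`.
#' @export
detector_u_coords <- function(geom) {
  (seq_len(geom$det_nu) - 1 - (geom$det_nu - 1) / 2) * geom$det_du +
    geom$det_offset_u
}

detector_v_coords <- function(geom) {
  (seq_len(geom$det_nv) - 1 - (geom$det_nv - 1) / 2) * geom$det_dv +
    geom$det_offset_v
}

#' Reconstruction grid specification
#'
#' A 3-D voxel grid: dimensions, isotropic-or-not spacing, and the physical
#' position of the centre of voxel (1,1,1).
#'
#' @param dims integer vector (nx, ny, nz).
#' @param spacing numeric vector (dx, dy, dz) in mm, all > 0.
#' @param origin position (mm) of the centre of the first voxel. Default
#'   centres the grid on the isocenter.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dims, spacing, origin = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(origin)) origin <- -(dims - 1) / 2 * spacing
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Voxel grid %d x %d x %d, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel centre coordinates along each axis
#' @param grid a [grid_spec()].
#' @return List with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3])
}
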