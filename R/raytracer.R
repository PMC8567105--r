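#' Exact ray/voxel intersection lengths (Siddon tracing)
#'
#' Computes the ordered list of voxels traversed by the segment `p0 -> p1`
#' and the exact chord length through each, by parametric plane crossing.
#' Degenerate crossings shorter than 1e-12 mm are dropped; a ray that misses
#' the grid yields an empty result.  The sum of the lengths equals the chord
#' of the segment inside the grid bounding box.
#'
#' @param p0,p1 length-3 numeric endpoints in mm (e.g. detector pixel centre
#'   and source focal spot).
#' @param grid a [grid_spec()].
#' @return A data.frame with columns `index` (1-based linear voxel index,
#'   x fastest) and `length` (mm), ordered along the ray.
#' @export
trace_ray <- function(p0, p1, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L)
    stop("ray endpoints must be length-3 points (mm)")
  if (!all(is.finite(c(p0, p1)))) stop("non-finite ray endpoint")
  if (all(p0 == p1)) stop("degenerate ray: p0 == p1")
  r <- cpp_trace_ray(p0, p1, grid$dims, grid$spacing, grid$origin)
  data.frame(index = r$index, length = r$length)
}

#' Forward projection of a volume
#'
#' Line integrals `p_k = sum_j l_jk * mu_j` along the source-to-pixel ray of
#' every detector pixel and view, using exact Siddon intersection lengths.
#'
#' @param vol a [ct_volume()] in unit `"mu_mm^-1"`.
#' @param geometry a [scan_geometry()].
#' @return A [projection_set()] with stage `"simulated"`.
#' @export
forward_project <- function(vol, geometry) {
  stopifnot(inherits(vol, "ct_volume"), inherits(geometry, "scan_geometry"))
  if (vol$unit != "mu_mm^-1")
    stop("forward_project expects a volume in mu_mm^-1")
  g <- volume_grid(vol)
  p <- cpp_forward_project(as.numeric(vol$data), g$dims, g$spacing, g$origin,
                           geometry$sad, geometry$sdd,
                           geometry$det_nu, geometry$det_nv,
                           geometry$det_du, geometry$det_dv,
                           geometry$det_offset_u, geometry$det_offset_v,
                           geometry$angles)
  dim(p) <- c(geometry$det_nu, geometry$det_nv, length(geometry$angles))
  if (all(p == 0) && any(vol$data != 0))
    warning("forward projection is identically zero: geometry and volume do not intersect")
  projection_set(p, geometry, stage = "simulated")
}

#' Ray-driven backprojection (intersection-length weighted average)
#'
#' For every voxel j accumulates the numerator `sum_k l_jk * P_k` and
#' denominator `sum_k l_jk` over the backprojection rays of all detector
#' pixels and views, then divides.  This is a pure length-weighted average
#' of the projection values seen by each voxel: constant projections map to
#' a constant volume.  Quantitative FDK scaling is applied by
#' [reconstruct_fbp()], not here.
#'
#' Voxels whose accumulated length stays below `den_floor` are set to zero
#' and flagged in the coverage mask.
#'
#' @param proj a [projection_set()] (normally stage `"filtered"`).
#' @param grid a [grid_spec()].
#' @param den_floor minimum accumulated intersection length (mm) for a voxel
#'   to count as covered; default 1e-9.
#' @return A [ct_volume()] (unit `"mu_mm^-1"`) with attribute `"coverage"`,
#'   a logical array marking voxels traversed by at least one ray.
#' @export
backproject_ray_driven <- function(proj, grid, den_floor = 1e-9) {
  stopifnot(inherits(proj, "projection_set"), inherits(grid, "grid_spec"))
  geom <- proj$geometry
  r <- cpp_backproject_rdb(as.numeric(proj$data), grid$dims, grid$spacing,
                           grid$origin, geom$sad, geom$sdd,
                           geom$det_nu, geom$det_nv, geom$det_du, geom$det_dv,
                           geom$det_offset_u, geom$det_offset_v, geom$angles)
  covered <- r$den > den_floor
  mu <- ifelse(covered, r$num / pmax(r$den, den_floor), 0)
  dim(mu) <- grid$dims
  dim(covered) <- grid$dims
  out <- ct_volume(mu, grid$spacing, grid$origin, unit = "mu_mm^-1")
  attr(out, "coverage") <- covered
  out
}
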