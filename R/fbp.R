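#' Cone-angle (cosine) pre-weighting
#'
#' Multiplies every detector pixel by `sdd / sqrt(sdd^2 + u^2 + v^2)`, where
#' (u, v) are the physical pixel coordinates relative to the central-ray
#' axis.  This is the standard FDK cosine factor that compensates the
#' intensity drop of oblique (large cone/fan angle) rays.
#'
#' @param proj a [projection_set()] with stage `"raw"` or `"simulated"`.
#' @return The pre-weighted projections, stage `"preweighted"`.
#' @export
cone_preweight <- function(proj) {
  stopifnot(inherits(proj, "projection_set"))
  geom <- proj$geometry
  u <- detector_u_coords(geom)
  v <- detector_v_coords(geom)
  w <- geom$sdd / sqrt(geom$sdd^2 + outer(u^2, v^2, `+`))
  proj$data <- proj$data * as.vector(w)  # recycles over views
  set_stage(proj, "preweighted")
}

ramp_response <- function(m, du) {
  f <- c(0:(m / 2), -(m / 2 - 1):-1) / (m * du)
  fn <- 1 / (2 * du)
  ramp_sl <- fn * (2 / pi) * abs(sin(pi * f / (2 * fn)))
  w_rc <- 0.5 * (1 + cos(pi * f / fn))
  ramp_sl * w_rc
}

#' Ramp filtering of projection rows
#'
#' Applies the 1-D reconstruction filter to every detector row (lines along
#' u): zero-pad to at least twice the row length (next power of two),
#' forward DFT, multiply by `H(f) = Ramp_SL(f) * W_rc(f)` with the
#' Shepp-Logan apodised ramp `Ramp_SL(f) = f_N (2/pi) |sin(pi f / (2 f_N))|`
#' and the raised-cosine (Hann) window `W_rc(f) = (1 + cos(pi f / f_N)) / 2`
#' (`f_N` = detector Nyquist frequency), inverse DFT and crop.  The filter
#' is scaled in physical frequency units (cycles/mm), so the detector pixel
#' pitch's convolution step is built in.
#'
#' @param proj a [projection_set()], normally stage `"preweighted"`.
#' @param pad_mode `"edge"` (default) continues each row with its endpoint
#'   values before the circular convolution, avoiding the truncation rim a
#'   hard zero pad would add (and giving exactly zero response to constant
#'   rows); `"zero"` pads with zeros.  Rows of real projections taper to
#'   zero at the detector edge, where the two coincide.
#' @return The filtered projections, stage `"filtered"`.
#' @export
ramp_filter <- function(proj, pad_mode = c("edge", "zero")) {
  pad_mode <- match.arg(pad_mode)
  stopifnot(inherits(proj, "projection_set"))
  geom <- proj$geometry
  nu <- geom$det_nu
  if (nu < 2L) stop("ramp_filter needs detector rows of length >= 2")
  m <- 2^ceiling(log2(2 * nu))
  h <- ramp_response(m, geom$det_du)
  nview <- length(geom$angles)
  ntail <- m - nu
  nhead <- ntail %/% 2          # padding split so wrap-around stays remote
  out <- proj$data
  for (k in seq_len(nview)) {
    pad <- matrix(0, m, geom$det_nv)
    if (pad_mode == "edge") {
      pad[seq_len(nhead), ] <- rep(proj$data[1, , k], each = nhead)
      pad[nhead + nu + seq_len(ntail - nhead), ] <-
        rep(proj$data[nu, , k], each = ntail - nhead)
    }
    pad[nhead + seq_len(nu), ] <- proj$data[, , k]
    q <- Re(mvfft(mvfft(pad) * h, inverse = TRUE)) / m
    out[, , k] <- q[nhead + seq_len(nu), ]
  }
  proj$data <- out
  set_stage(proj, "filtered")
}

#' Parker short-scan weight for a single ray
#'
#' Classic Parker weighting generalised to arcs longer than the minimal
#' `180 + 2 * fan` short scan: with half over-scan
#' `delta = (arc - 180 deg) / 2` (radians) and fan angle `gamma`, the weight
#' ramps up as `sin^2(pi/4 * beta / (delta - gamma))`, is 1 on the
#' non-redundant interior, and ramps down as
#' `sin^2(pi/4 * (pi + 2 delta - beta) / (delta + gamma))`.  Redundant ray
#' pairs `(beta, gamma)` and `(beta + pi + 2 gamma, -gamma)` sum to 1.
#'
#' @param beta angle (radians) of the view relative to the first view of the
#'   arc, in `[0, arc)`.
#' @param gamma fan angle (radians) of the ray, `atan(u / sdd)`.
#' @param arc total scan arc in radians (`> pi + 2 |gamma|`).
#' @return Weight in `[0, 1]` (vectorised over `beta`/`gamma`).
#' @export
parker_weight_value <- function(beta, gamma, arc) {
  delta <- (arc - pi) / 2
  w <- rep(1, length(beta + gamma))
  beta <- rep(beta, length.out = length(w))
  gamma <- rep(gamma, length.out = length(w))
  up <- beta < 2 * (delta - gamma)
  w[up] <- sin(pi / 4 * beta[up] / (delta - gamma[up]))^2
  down <- beta > pi - 2 * gamma
  w[down] <- sin(pi / 4 * (pi + 2 * delta - beta[down]) /
                   (delta + gamma[down]))^2
  w[down & beta > pi + 2 * delta] <- 0
  w
}

#' Parker short-scan weighting of a projection set
#'
#' Applies the fan-angle dependent Parker weight of [parker_weight_value()]
#' to every detector column; rows (the cone direction) share the fan weight.
#' Full-scan (360 degree) inputs pass through unchanged.
#'
#' @param proj a [projection_set()].
#' @return The weighted projections (stage unchanged).
#' @export
parker_weight <- function(proj) {
  stopifnot(inherits(proj, "projection_set"))
  geom <- proj$geometry
  if (is_full_scan(geom)) return(proj)
  arc <- geom$arc_deg * pi / 180
  gamma <- atan(detector_u_coords(geom) / geom$sdd)
  fan <- max(abs(gamma))
  if (arc < pi + 2 * fan)
    stop(sprintf(paste0("scan arc %.1f deg is below the minimal short scan ",
                        "180 + 2*fan = %.1f deg"),
                 geom$arc_deg, (pi + 2 * fan) * 180 / pi))
  beta <- (geom$angles - geom$angles[1]) * pi / 180
  beta <- beta %% (2 * pi)
  for (k in seq_along(beta)) {
    wk <- parker_weight_value(beta[k], gamma, arc)
    proj$data[, , k] <- proj$data[, , k] * wk
  }
  proj
}

#' Pixel-driven (FDK) backprojection
#'
#' Perspective-projects every voxel centre onto the detector at every view,
#' bilinearly interpolates the filtered projection, and accumulates with the
#' FDK distance weight `(sad/U)^2` (`U` = voxel distance from the source
#' along the central-ray direction) times the per-view scale
#' `dbeta * (sdd/sad) * c`, where `dbeta = arc / n_views` (radians) and
#' `c = 1/2` for a full scan (redundancy) or 1 for a Parker-weighted short
#' scan.  The `sdd/sad` factor rescales the detector-pitch ramp filter to
#' the isocenter (virtual detector) sampling, making the output quantitative
#' in mm^-1.  Voxels that project outside the detector receive no
#' contribution.
#'
#' @param proj a [projection_set()] with stage `"filtered"`.
#' @param grid a [grid_spec()].
#' @return A [ct_volume()] in unit `"mu_mm^-1"`.
#' @export
backproject_pixel_driven <- function(proj, grid) {
  stopifnot(inherits(proj, "projection_set"), inherits(grid, "grid_spec"))
  geom <- proj$geometry
  arc <- geom$arc_deg * pi / 180
  dbeta <- arc / length(geom$angles)
  vs <- rep(dbeta * (geom$sdd / geom$sad) *
              (if (is_full_scan(geom)) 0.5 else 1), length(geom$angles))
  mu <- cpp_backproject_pdb(as.numeric(proj$data), grid$dims, grid$spacing,
                            grid$origin, geom$sad, geom$sdd,
                            geom$det_nu, geom$det_nv, geom$det_du,
                            geom$det_dv, geom$det_offset_u,
                            geom$det_offset_v, geom$angles, vs)
  dim(mu) <- grid$dims
  ct_volume(mu, grid$spacing, grid$origin, unit = "mu_mm^-1")
}

#' Filtered backprojection reconstruction
#'
#' Composes the full analytical chain: cosine pre-weighting, Parker
#' short-scan weighting (when the arc is below 360 degrees), Shepp-Logan /
#' Hann ramp filtering, and the chosen backprojector.  The ray-driven
#' backprojector output (a length-weighted projection average, see
#' [backproject_ray_driven()]) is scaled by `arc * (sdd/sad) * c`
#' (`c = 1/2` full scan, 1 short scan), the angular-integration factor that
#' makes it quantitative in mm^-1 near the axis; the pixel-driven
#' backprojector carries its per-view FDK scale internally.
#'
#' @param proj a [projection_set()] with stage `"raw"` or `"simulated"`.
#' @param grid a [grid_spec()].
#' @param backprojector `"rdb"` (ray-driven) or `"pdb"` (pixel-driven).
#' @param apply_parker apply short-scan weighting when the arc is partial;
#'   default `TRUE` (ignored for full scans).
#' @param verbose log per-stage value ranges.
#' @return A [ct_volume()] in unit `"mu_mm^-1"`; negative values are
#'   reported (message) but not clamped.  For `"rdb"` the coverage mask is
#'   attached as attribute `"coverage"`.
#' @export
reconstruct_fbp <- function(proj, grid, backprojector = c("rdb", "pdb"),
                            apply_parker = TRUE, verbose = FALSE) {
  backprojector <- match.arg(backprojector)
  stopifnot(inherits(proj, "projection_set"), inherits(grid, "grid_spec"))
  geom <- proj$geometry
  t0 <- proc.time()[3]
  say <- function(stage, x) {
    if (verbose)
      message(sprintf("  [%6.2fs] %-12s range [%.4g, %.4g]",
                      proc.time()[3] - t0, stage, min(x), max(x)))
  }
  p <- cone_preweight(proj); say("preweight", p$data)
  if (!is_full_scan(geom) && apply_parker) {
    p <- parker_weight(p); say("parker", p$data)
  }
  p <- ramp_filter(p); say("filter", p$data)
  arc <- geom$arc_deg * pi / 180
  if (backprojector == "rdb") {
    vol <- backproject_ray_driven(p, grid)
    vol$data <- vol$data * arc * (geom$sdd / geom$sad) *
      (if (is_full_scan(geom)) 0.5 else 1)
  } else {
    vol <- backproject_pixel_driven(p, grid)
  }
  say(backprojector, vol$data)
  nneg <- sum(vol$data < 0)
  if (verbose && nneg > 0)
    message(sprintf("  %d voxels (%.1f%%) reconstructed negative (not clamped)",
                    nneg, 100 * nneg / length(vol$data)))
  vol
}
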