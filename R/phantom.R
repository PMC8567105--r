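#' Catphan-like digital phantom description
#'
#' A cylindrical water-equivalent body carrying three axial modules: a
#' sensitometry ring of seven density inserts (Delrin, Teflon, air, PMP,
#' LDPE, polystyrene, air), a uniform module, and a resolution module of
#' line-pair bar groups.  Insert attenuations are package constants
#' approximating the named materials relative to water (`mu_water`); they
#' are nominal design values, not measured data.
#'
#' All lengths in mm, attenuations in mm^-1.  The phantom axis is the z
#' axis through the isocenter.
#'
#' @param mu_water water attenuation (mm^-1).
#' @param body_radius radius of the cylindrical body.
#' @param body_z axial extent `c(zmin, zmax)` of the body.
#' @param insert_radius,ring_radius radius of each sensitometry insert and
#'   of the ring they sit on.
#' @param z_sensitometry,z_uniformity,z_resolution axial extents of the
#'   three modules.
#' @param linepair_lp line-pair frequencies (lp/cm) of the bar groups.
#' @param linepair_mu bar attenuation (default twice water, bone-like).
#' @param linepair_nbars bars per group.
#' @param linepair_height bar length along y.
#' @param linepair_y y centre of each group (recycled to `linepair_lp`).
#' @return An object of class `phantom_spec`.
#' @export
catphan_spec <- function(mu_water = 0.02, body_radius = 20,
                         body_z = c(-8, 8),
                         insert_radius = 2.5, ring_radius = 13,
                         z_sensitometry = c(-8, -3),
                         z_uniformity = c(-3, 3),
                         z_resolution = c(3, 8),
                         linepair_lp = c(2, 3, 4, 6),
                         linepair_mu = 2 * mu_water,
                         linepair_nbars = 4L,
                         linepair_height = 5,
                         linepair_y = c(-9, -3, 3, 9)) {
  stopifnot(mu_water >= 0, body_radius > 0)
  rel <- c(delrin = 1.36, teflon = 1.87, air = 0, pmp = 0.83,
           ldpe = 0.92, polystyrene = 0.96, air2 = 0)
  ang <- (seq_along(rel) - 1) * 2 * pi / length(rel)
  inserts <- data.frame(name = names(rel),
                        cx = ring_radius * cos(ang),
                        cy = ring_radius * sin(ang),
                        radius = insert_radius,
                        mu = unname(rel) * mu_water)
  if (any(sqrt(inserts$cx^2 + inserts$cy^2) + inserts$radius > body_radius))
    stop("inserts extend outside the phantom body")
  d <- as.matrix(dist(inserts[, c("cx", "cy")]))
  diag(d) <- Inf
  if (any(d < 2 * insert_radius)) stop("overlapping inserts")
  linepair_y <- rep(linepair_y, length.out = length(linepair_lp))
  structure(list(mu_water = mu_water, body_radius = body_radius,
                 body_z = body_z, inserts = inserts,
                 z_sensitometry = z_sensitometry,
                 z_uniformity = z_uniformity,
                 z_resolution = z_resolution,
                 linepair_lp = linepair_lp, linepair_mu = linepair_mu,
                 linepair_nbars = as.integer(linepair_nbars),
                 linepair_height = linepair_height,
                 linepair_y = linepair_y),
            class = "phantom_spec")
}

linepair_bar_edges <- function(spec, lp) {
  b <- 5 / lp                       # bar width, mm (period 10/lp)
  n <- spec$linepair_nbars
  width <- (2 * n - 1) * b
  starts <- -width / 2 + (seq_len(n) - 1) * 2 * b
  cbind(lo = starts, hi = starts + b)
}

#' Voxelise a phantom description onto a grid
#'
#' Centre-sampled voxelisation: each voxel takes the attenuation of the
#' shape containing its centre (body, then insert/bar overrides within the
#' respective module's z range).
#'
#' @param grid a [grid_spec()].
#' @param spec a [catphan_spec()], or `NULL` for an empty (all-zero) volume.
#' @return A [ct_volume()] in unit `"mu_mm^-1"`.
#' @export
make_catphan_like <- function(grid, spec = catphan_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  vol <- array(0, grid$dims)
  if (is.null(spec))
    return(ct_volume(vol, grid$spacing, grid$origin, unit = "mu_mm^-1"))
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- grid_axes(grid)
  r2 <- outer(ax$x^2, ax$y^2, `+`)            # nx x ny squared radius
  in_body <- r2 <= spec$body_radius^2
  for (iz in seq_len(grid$dims[3])) {
    z <- ax$z[iz]
    if (z < spec$body_z[1] || z > spec$body_z[2]) next
    sl <- matrix(0, grid$dims[1], grid$dims[2])
    sl[in_body] <- spec$mu_water
    if (z >= spec$z_sensitometry[1] && z < spec$z_sensitometry[2]) {
      for (i in seq_len(nrow(spec$inserts))) {
        ins <- spec$inserts[i, ]
        m <- outer((ax$x - ins$cx)^2, (ax$y - ins$cy)^2, `+`) <= ins$radius^2
        sl[m & in_body] <- ins$mu
      }
    }
    if (z >= spec$z_resolution[1] && z < spec$z_resolution[2]) {
      for (g in seq_along(spec$linepair_lp)) {
        edges <- linepair_bar_edges(spec, spec$linepair_lp[g])
        iny <- abs(ax$y - spec$linepair_y[g]) <= spec$linepair_height / 2
        for (bb in seq_len(nrow(edges))) {
          inx <- ax$x >= edges[bb, "lo"] & ax$x < edges[bb, "hi"]
          m <- outer(inx, iny, `&`)
          sl[m & in_body] <- spec$linepair_mu
        }
      }
    }
    vol[, , iz] <- sl
  }
  ct_volume(vol, grid$spacing, grid$origin, unit = "mu_mm^-1")
}

#' Simulate noisy cone-beam projections of a volume
#'
#' Forward-projects the volume (exact Siddon line integrals), converts the
#' line integrals to expected photon counts `I0 * exp(-p)`, draws Poisson
#' transmission noise (plus optional Gaussian electronic noise), and
#' post-logs back: `p_hat = -ln(max(counts, 1) / I0)`.  The counts floor of
#' 1 avoids `-ln 0` under photon starvation.  `I0 = Inf` (or
#' `noise = FALSE`) returns the noise-free line integrals.
#'
#' @param vol a [ct_volume()] in `"mu_mm^-1"`.
#' @param geometry a [scan_geometry()].
#' @param I0 unattenuated photon count per detector pixel (> 0); the
#'   low-dose regime of a 0.1 mAs acquisition vs a 1.6 mAs benchmark is
#'   emulated by scaling `I0` proportionally.
#' @param seed integer seed for the noise draw (`NULL` = use the current
#'   RNG state).
#' @param electronic_sigma standard deviation of additive Gaussian
#'   electronic noise, in counts (default 0).
#' @param noise set `FALSE` for the noise-free passthrough.
#' @return A [projection_set()] with stage `"simulated"`.
#' @export
simulate_projections <- function(vol, geometry, I0 = 2e4, seed = NULL,
                                 electronic_sigma = 0, noise = TRUE) {
  stopifnot(I0 > 0)
  proj <- forward_project(vol, geometry)
  if (!noise || is.infinite(I0)) return(proj)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  lambda <- I0 * exp(-proj$data)
  counts <- rpois(length(lambda), lambda)
  if (electronic_sigma > 0)
    counts <- counts + rnorm(length(counts), 0, electronic_sigma)
  phat <- -log(pmax(counts, 1) / I0)
  dim(phat) <- dim(proj$data)
  proj$data <- phat
  proj
}

#' Standard measurement ROIs of the digital phantom
#'
#' Derives the regions used by the image-quality metrics from the phantom
#' geometry: one circular foreground ROI per density insert and a central
#' background ROI on the sensitometry module; a central uniformity ROI,
#' five SNU ROIs (centre + 4 peripheral) and a ring of eight square NPS
#' ROIs on the uniformity module.  ROIs are shrunk by `margin` from the
#' nominal edges to stay clear of partial-volume voxels.
#'
#' @param spec a [catphan_spec()].
#' @param margin shrink margin in mm.
#' @return List with elements `inserts` (named list of [roi_spec()]),
#'   `background`, `uniformity`, `snu` (list of 5), `nps` (list of 8).
#' @export
catphan_rois <- function(spec = catphan_spec(), margin = 1.5) {
  zs <- spec$z_sensitometry + c(margin, -margin)
  zu <- spec$z_uniformity + c(margin, -margin)
  R <- spec$body_radius
  ins <- lapply(seq_len(nrow(spec$inserts)), function(i) {
    roi_spec("circle", center = c(spec$inserts$cx[i], spec$inserts$cy[i]),
             size = max(spec$inserts$radius[i] - margin,
                        spec$inserts$radius[i] / 2), zrange = zs)
  })
  names(ins) <- spec$inserts$name
  rp <- R / 2
  snu_centers <- rbind(c(0, 0), c(rp, 0), c(-rp, 0), c(0, rp), c(0, -rp))
  nps_ang <- (0:7) * pi / 4
  list(inserts = ins,
       background = roi_spec("circle", c(0, 0), size = 0.3 * R, zrange = zs),
       uniformity = roi_spec("circle", c(0, 0), size = R / 2, zrange = zu),
       snu = lapply(seq_len(nrow(snu_centers)), function(i)
         roi_spec("circle", snu_centers[i, ], size = R / 4, zrange = zu)),
       nps = lapply(nps_ang, function(a)
         roi_spec("square", rp * c(cos(a), sin(a)), size = 0.6 * R,
                  zrange = zu)))
}

#' Line-pair bar modulation of a reconstructed volume
#'
#' Measures the contrast of one bar group of the resolution module: the
#' mean intensity over the central halves of the bars minus the mean over
#' the central halves of the gaps between them, averaged over the module's
#' interior slices.  The masks come from the phantom geometry, so the same
#' measure can be compared before and after denoising.
#'
#' @param vol a [ct_volume()] on any grid covering the resolution module.
#' @param spec the [catphan_spec()] used to build the phantom.
#' @param lp which bar group, in lp/cm (must be one of `spec$linepair_lp`).
#' @param margin axial shrink (mm) of the module range.
#' @return Modulation amplitude (bar mean - gap mean) in the volume's unit.
#' @export
linepair_modulation <- function(vol, spec, lp, margin = 1) {
  stopifnot(inherits(vol, "ct_volume"), inherits(spec, "phantom_spec"))
  g <- which(abs(spec$linepair_lp - lp) < 1e-9)
  if (length(g) != 1L) stop("no bar group at ", lp, " lp/cm in this phantom")
  ax <- grid_axes(volume_grid(vol))
  zr <- spec$z_resolution + c(margin, -margin)
  izs <- which(ax$z >= zr[1] & ax$z <= zr[2])
  if (length(izs) == 0L) stop("volume does not cover the resolution module")
  edges <- linepair_bar_edges(spec, lp)
  b <- 5 / lp
  iny <- abs(ax$y - spec$linepair_y[g]) <= spec$linepair_height / 2 - margin
  bar_x <- rep(FALSE, length(ax$x))
  gap_x <- rep(FALSE, length(ax$x))
  for (bb in seq_len(nrow(edges))) {
    ctr <- mean(edges[bb, ])
    bar_x <- bar_x | abs(ax$x - ctr) <= b / 4
    if (bb < nrow(edges)) {
      gctr <- edges[bb, "hi"] + b / 2
      gap_x <- gap_x | abs(ax$x - gctr) <= b / 4
    }
  }
  if (!any(bar_x) || !any(gap_x))
    stop("grid too coarse to resolve ", lp, " lp/cm bars")
  bar_m <- outer(bar_x, iny, `&`)
  gap_m <- outer(gap_x, iny, `&`)
  vals_b <- vals_g <- numeric(0)
  for (iz in izs) {
    vals_b <- c(vals_b, vol$data[, , iz][bar_m])
    vals_g <- c(vals_g, vol$data[, , iz][gap_m])
  }
  mean(vals_b) - mean(vals_g)
}
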