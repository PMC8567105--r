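#' Region of interest specification
#'
#' A circular or square region in the axial plane, extruded over a z range.
#' All coordinates in mm, in the volume's physical frame.
#'
#' @param shape `"circle"` or `"square"`.
#' @param center (x, y) centre in mm.
#' @param size radius (circle) or side length (square) in mm.
#' @param zrange `c(zmin, zmax)` in mm.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(shape = c("circle", "square"), center, size, zrange) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2L, size > 0, length(zrange) == 2L,
            zrange[1] <= zrange[2])
  structure(list(shape = shape, center = as.numeric(center),
                 size = size, zrange = as.numeric(zrange)),
            class = "roi_spec")
}

roi_slice_mask <- function(roi, ax) {
  if (roi$shape == "circle") {
    outer((ax$x - roi$center[1])^2, (ax$y - roi$center[2])^2, `+`) <=
      roi$size^2
  } else {
    outer(abs(ax$x - roi$center[1]) <= roi$size / 2,
          abs(ax$y - roi$center[2]) <= roi$size / 2, `&`)
  }
}

#' Voxel values inside a region of interest
#'
#' @param vol a [ct_volume()].
#' @param roi a [roi_spec()].
#' @return Numeric vector of the voxel values (error if the ROI is empty or
#'   outside the volume).
#' @export
roi_values <- function(vol, roi) {
  stopifnot(inherits(vol, "ct_volume"), inherits(roi, "roi_spec"))
  ax <- grid_axes(volume_grid(vol))
  izs <- which(ax$z >= roi$zrange[1] & ax$z <= roi$zrange[2])
  m <- roi_slice_mask(roi, ax)
  if (length(izs) == 0L || !any(m))
    stop("ROI selects no voxels (outside the volume?)")
  unlist(lapply(izs, function(iz) vol$data[, , iz][m]), use.names = FALSE)
}

#' Contrast-to-noise ratio
#'
#' `CNR = |mean(fg) - mean(bg)| / sd(bg)`, the conventional definition with
#' background-only noise (set `pooled_sd = TRUE` for the pooled-noise
#' variant).
#'
#' @param vol a [ct_volume()].
#' @param roi_fg,roi_bg foreground and background [roi_spec()]s.
#' @param pooled_sd use `sqrt((sd_fg^2 + sd_bg^2)/2)` instead of `sd(bg)`.
#' @return The CNR (dimensionless).
#' @export
cnr <- function(vol, roi_fg, roi_bg, pooled_sd = FALSE) {
  fg <- roi_values(vol, roi_fg)
  bg <- roi_values(vol, roi_bg)
  s <- if (pooled_sd) sqrt((sd(fg)^2 + sd(bg)^2) / 2) else sd(bg)
  if (!is.finite(s) || s == 0)
    stop("background standard deviation is zero; CNR undefined")
  abs(mean(fg) - mean(bg)) / s
}

#' Root-mean-square error against a benchmark volume
#'
#' @param vol,ref [ct_volume()]s of identical dimensions (and unit).
#' @param mask optional logical array (or [roi_spec()]) restricting the
#'   comparison, e.g. a region inside the phantom excluding surrounding
#'   air.
#' @return RMS difference in the volumes' unit.
#' @export
rmse <- function(vol, ref, mask = NULL) {
  v <- masked_pair(vol, ref, mask)
  sqrt(mean((v$a - v$b)^2))
}

#' Pearson correlation against a benchmark volume
#'
#' @inheritParams rmse
#' @return Pearson r over the masked voxels.
#' @export
pearson_correlation <- function(vol, ref, mask = NULL) {
  v <- masked_pair(vol, ref, mask)
  if (sd(v$a) == 0 || sd(v$b) == 0)
    stop("zero-variance input; correlation undefined")
  cor(v$a, v$b)
}

masked_pair <- function(vol, ref, mask) {
  stopifnot(inherits(vol, "ct_volume"), inherits(ref, "ct_volume"))
  if (!all(dim(vol$data) == dim(ref$data)))
    stop("volume dimensions differ")
  if (is.null(mask)) return(list(a = as.numeric(vol$data),
                                 b = as.numeric(ref$data)))
  if (inherits(mask, "roi_spec"))
    return(list(a = roi_values(vol, mask), b = roi_values(ref, mask)))
  stopifnot(all(dim(mask) == dim(vol$data)))
  if (!any(mask)) stop("empty mask")
  list(a = vol$data[mask], b = ref$data[mask])
}

#' Spatial non-uniformity
#'
#' `SNU = (max_k mean_k - min_k mean_k) / 1000 * 100`, the spread of the
#' mean HU over five uniform ROIs (one central, four peripheral), in
#' percent.
#'
#' @param vol a [ct_volume()] in HU.
#' @param rois list of five [roi_spec()]s.
#' @return SNU in percent.
#' @export
snu <- function(vol, rois) {
  stopifnot(is.list(rois), length(rois) >= 2L)
  means <- vapply(rois, function(r) mean(roi_values(vol, r)), 0)
  (max(means) - min(means)) / 1000 * 100
}

#' 2-D noise power spectrum of uniform-region ROIs
#'
#' Estimates the NPS from an ensemble of square ROIs on uniform slices:
#' each ROI is detrended by a first-order polynomial (plane) fit, then
#' `NPS = dx * dy / (Nx * Ny) * |DFT2|^2`, ensemble-averaged over the ROIs.
#' A radial average over annuli, the peak value, and the intensity-weighted
#' mean spatial frequency (DC excluded) are reported.
#'
#' @param vol a [ct_volume()] (typically in HU).
#' @param rois list of square [roi_spec()]s (>= 2); every ROI is evaluated
#'   on each slice of its z range, so 8 ROIs x 13 slices gives a
#'   104-member ensemble.
#' @param nbins number of annuli of the radial profile.
#' @return List with `nps` (2-D map, HU^2 mm^2), `fx`, `fy` (cycles/mm),
#'   `radial` (data.frame freq/nps), `peak` and `mean_frequency`.
#' @export
nps_2d <- function(vol, rois, nbins = 30) {
  stopifnot(inherits(vol, "ct_volume"), is.list(rois))
  if (length(rois) < 2L) stop("need at least 2 ROIs for an NPS ensemble")
  ax <- grid_axes(volume_grid(vol))
  dx <- vol$spacing[1]; dy <- vol$spacing[2]
  patches <- list()
  for (roi in rois) {
    stopifnot(inherits(roi, "roi_spec"))
    if (roi$shape != "square") stop("NPS ROIs must be square")
    ixs <- which(abs(ax$x - roi$center[1]) <= roi$size / 2)
    iys <- which(abs(ax$y - roi$center[2]) <= roi$size / 2)
    izs <- which(ax$z >= roi$zrange[1] & ax$z <= roi$zrange[2])
    if (!length(ixs) || !length(iys) || !length(izs))
      stop("NPS ROI selects no voxels")
    for (iz in izs) patches[[length(patches) + 1L]] <-
      vol$data[ixs, iys, iz]
  }
  d <- dim(patches[[1]])
  if (any(vapply(patches, function(p) any(dim(p) != d), TRUE)))
    stop("NPS ROIs must share a common size")
  gx <- row(patches[[1]]); gy <- col(patches[[1]])
  X <- cbind(1, as.numeric(gx), as.numeric(gy))
  XtXi <- solve(crossprod(X))
  acc <- matrix(0, d[1], d[2])
  for (p in patches) {
    beta <- XtXi %*% crossprod(X, as.numeric(p))
    res <- as.numeric(p) - X %*% beta
    dim(res) <- d
    acc <- acc + Mod(fft(res))^2
  }
  nps <- dx * dy / (d[1] * d[2]) * acc / length(patches)
  fx <- fft_freq(d[1], dx)
  fy <- fft_freq(d[2], dy)
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  fmax <- max(fr)
  bin <- pmin(nbins, 1L + as.integer(fr / fmax * nbins))
  radial <- data.frame(
    freq = as.numeric(tapply(as.numeric(fr), as.numeric(bin), mean)),
    nps = as.numeric(tapply(as.numeric(nps), as.numeric(bin), mean)))
  nz <- fr > 0
  list(nps = nps, fx = fx, fy = fy, radial = radial,
       peak = max(nps),
       mean_frequency = sum(nps[nz] * fr[nz]) / sum(nps[nz]))
}

fft_freq <- function(n, d) {
  k <- c(0:floor((n - 1) / 2), -ceiling((n - 1) / 2):-1)
  k[seq_len(n)] / (n * d)
}

#' Maximum / minimum intensity projection
#'
#' Per-ray maximum (MIP) or minimum (MinIP) along one volume axis.
#'
#' @param vol a [ct_volume()].
#' @param axis 1 (x), 2 (y) or 3 (z, the longitudinal direction).
#' @return A matrix over the two remaining axes.
#' @export
mip <- function(vol, axis = 3L) {
  stopifnot(inherits(vol, "ct_volume"), axis %in% 1:3)
  apply(vol$data, setdiff(1:3, axis), max)
}

#' @rdname mip
#' @export
minip <- function(vol, axis = 3L) {
  stopifnot(inherits(vol, "ct_volume"), axis %in% 1:3)
  apply(vol$data, setdiff(1:3, axis), min)
}

#' Tabulated image-quality report for a set of volumes
#'
#' Computes, for each named volume, the insert CNRs (mean over inserts),
#' uniformity noise, SNU, and - when a benchmark is given - RMSE and
#' Pearson correlation, mirroring the usual phantom-study comparison
#' tables.
#'
#' @param vols named list of [ct_volume()]s (HU).
#' @param ref optional benchmark [ct_volume()] (HU).
#' @param rois ROI set from [catphan_rois()].
#' @param mask optional mask or [roi_spec()] for RMSE/correlation.
#' @return A data.frame, one row per volume.
#' @export
evaluate_report <- function(vols, ref = NULL, rois, mask = NULL) {
  stopifnot(is.list(vols), !is.null(names(vols)))
  rows <- lapply(names(vols), function(nm) {
    v <- vols[[nm]]
    cnrs <- vapply(rois$inserts, function(r)
      cnr(v, r, rois$background), 0)
    u <- roi_values(v, rois$uniformity)
    row <- data.frame(volume = nm,
                      cnr_mean = mean(cnrs),
                      cnr_min = min(cnrs),
                      noise_sd = sd(u),
                      snu = snu(v, rois$snu))
    for (i in seq_along(cnrs))
      row[[paste0("cnr_", names(cnrs)[i])]] <- cnrs[i]
    if (!is.null(ref)) {
      row$rmse <- rmse(v, ref, mask)
      row$correlation <- pearson_correlation(v, ref, mask)
    }
    row
  })
  do.call(rbind, rows)
}
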