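# Independent reference implementations used as oracles.  These share no
# code with the package internals: plain R loops and direct-summation
# formulas only.

# reflective (symmetric, edge-including) indexing, 1-based
reflect1 <- function(i, n) {
  i <- as.integer(i) - 1L
  while (i < 0L || i >= n) {
    if (i < 0L) i <- -i - 1L
    if (i >= n) i <- 2L * n - 1L - i
  }
  i + 1L
}

pad_reflect <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- vapply(seq_len(nr + 2 * pad) - pad, reflect1, 1L, n = nr)
  ci <- vapply(seq_len(nc + 2 * pad) - pad, reflect1, 1L, n = nc)
  m[ri, ci, drop = FALSE]
}

bin_index <- function(v, mn, mx, B) {
  if (mx <= mn) return(rep(1L, length(v)))
  pmin(B - 1L, pmax(0L, as.integer(floor((v - mn) / (mx - mn) * B)))) + 1L
}

# double-loop joint histogram oracle (aggregated over all non-null
# displacements of the search window)
oracle_joint_hist <- function(slice, center, a, s, B) {
  pad <- a + s
  mn <- min(slice); mx <- max(slice)
  p <- pad_reflect(slice, pad)
  bins <- matrix(bin_index(as.numeric(p), mn, mx, B), nrow(p), ncol(p))
  counts <- matrix(0, B, B)
  r <- center[1] + pad; c <- center[2] + pad
  for (di in -s:s) for (dj in -s:s) {
    if (di == 0 && dj == 0) next
    for (pi in -a:a) for (pj in -a:a) {
      ia <- bins[r + pi, c + pj]
      ib <- bins[r + pi + di, c + pj + dj]
      counts[ia, ib] <- counts[ia, ib] + 1
    }
  }
  counts
}

oracle_entropy <- function(p) {
  p <- p / sum(p); p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi_measure <- function(slice, center, a, s, B) {
  counts <- oracle_joint_hist(slice, center, a, s, B)
  ha <- oracle_entropy(rowSums(counts))
  if (ha < 1e-12) return(0)
  mi <- ha + oracle_entropy(colSums(counts)) -
    oracle_entropy(as.numeric(counts))
  min(1, max(0, max(0, mi) / ha))
}

oracle_nlm_measure <- function(slice, center, a, s, h) {
  pad <- a + s
  p <- pad_reflect(slice, pad)
  r <- center[1] + pad; c <- center[2] + pad
  stat <- p[(r - a):(r + a), (c - a):(c + a)]
  acc <- 0; nd <- 0
  for (di in -s:s) for (dj in -s:s) {
    if (di == 0 && dj == 0) next
    mov <- p[(r - a + di):(r + a + di), (c - a + dj):(c + a + dj)]
    acc <- acc + exp(-sum((stat - mov)^2) / ((2 * a + 1)^2 * h^2))
    nd <- nd + 1
  }
  acc / nd
}

# clean-room weight map (MI mode)
oracle_weight_map <- function(slice, a, s, B, rho, tau) {
  M <- matrix(0, nrow(slice), ncol(slice))
  for (i in seq_len(nrow(slice))) for (j in seq_len(ncol(slice)))
    M[i, j] <- oracle_mi_measure(slice, c(i, j), a, s, B)
  exp(-(pmax(slice, 0) / tau)^rho * M)
}

oracle_tv_objective <- function(V, W, eps) {
  acc <- 0
  for (i in seq_len(nrow(V))) for (j in seq_len(ncol(V))) {
    dx <- if (i > 1) V[i, j] - V[i - 1, j] else 0
    dy <- if (j > 1) V[i, j] - V[i, j - 1] else 0
    acc <- acc + W[i, j] * sqrt(dx^2 + dy^2 + eps^2)
  }
  acc
}

numeric_tv_gradient <- function(V, W, eps, h) {
  g <- matrix(0, nrow(V), ncol(V))
  for (i in seq_len(nrow(V))) for (j in seq_len(ncol(V))) {
    vp <- V; vp[i, j] <- V[i, j] + h
    vm <- V; vm[i, j] <- V[i, j] - h
    g[i, j] <- (tv_objective(vp, W, eps) - tv_objective(vm, W, eps)) / (2 * h)
  }
  g
}

# direct-summation DFT (O(n^2)); sign convention of stats::fft
oracle_dft <- function(x, inverse = FALSE) {
  n <- length(x)
  k <- 0:(n - 1)
  sgn <- if (inverse) 2i else -2i
  vapply(k, function(kk) sum(x * exp(sgn * pi * kk * k / n)), complex(1))
}

# dense-sampling ray oracle: per-voxel lengths by midpoint sampling
oracle_dense_trace <- function(p0, p1, grid, step = 1e-4) {
  D <- p1 - p0
  L <- sqrt(sum(D^2))
  bmin <- grid$origin - grid$spacing / 2
  bmax <- bmin + grid$dims * grid$spacing
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (D[a] != 0) {
      ta <- (bmin[a] - p0[a]) / D[a]; tb <- (bmax[a] - p0[a]) / D[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
    } else if (p0[a] < bmin[a] || p0[a] > bmax[a]) return(numeric(0))
  }
  if (t0 >= t1) return(numeric(0))
  dt <- step / L
  ts <- seq(t0 + dt / 2, t1, by = dt)
  ix <- floor((p0[1] + ts * D[1] - bmin[1]) / grid$spacing[1])
  iy <- floor((p0[2] + ts * D[2] - bmin[2]) / grid$spacing[2])
  iz <- floor((p0[3] + ts * D[3] - bmin[3]) / grid$spacing[3])
  ok <- ix >= 0 & ix < grid$dims[1] & iy >= 0 & iy < grid$dims[2] &
    iz >= 0 & iz < grid$dims[3]
  idx <- 1 + ix[ok] + grid$dims[1] * (iy[ok] + grid$dims[2] * iz[ok])
  tab <- table(idx)
  lens <- as.numeric(tab) * step
  names(lens) <- names(tab)
  lens
}

# box chord length of segment p0 -> p1 through the grid bounding box
box_chord <- function(p0, p1, grid) {
  D <- p1 - p0
  bmin <- grid$origin - grid$spacing / 2
  bmax <- bmin + grid$dims * grid$spacing
  t0 <- 0; t1 <- 1
  for (a in 1:3) {
    if (D[a] != 0) {
      ta <- (bmin[a] - p0[a]) / D[a]; tb <- (bmax[a] - p0[a]) / D[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
    } else if (p0[a] < bmin[a] || p0[a] > bmax[a]) return(0)
  }
  if (t0 >= t1) return(0)
  (t1 - t0) * sqrt(sum(D^2))
}

# loop reimplementation of the pixel-driven FDK backprojector
oracle_pdb <- function(proj, geom, grid) {
  arc <- geom$arc_deg * pi / 180
  dbeta <- arc / length(geom$angles)
  full <- geom$arc_deg >= 360 - 1e-9
  scale <- dbeta * (geom$sdd / geom$sad) * (if (full) 0.5 else 1)
  dims <- grid$dims
  out <- array(0, dims)
  nu <- geom$det_nu; nv <- geom$det_nv
  for (k in seq_along(geom$angles)) {
    b <- geom$angles[k] * pi / 180
    s <- c(geom$sad * sin(b), -geom$sad * cos(b))
    e <- c(-sin(b), cos(b))
    uv <- c(cos(b), sin(b))
    for (iz in seq_len(dims[3])) for (iy in seq_len(dims[2]))
      for (ix in seq_len(dims[1])) {
        r <- grid$origin + (c(ix, iy, iz) - 1) * grid$spacing
        rx <- r[1] - s[1]; ry <- r[2] - s[2]
        U <- rx * e[1] + ry * e[2]
        if (U <= 1e-9) next
        mag <- geom$sdd / U
        uc <- mag * (rx * uv[1] + ry * uv[2]) - geom$det_offset_u
        vc <- mag * r[3] - geom$det_offset_v
        fu <- uc / geom$det_du + (nu - 1) / 2
        fv <- vc / geom$det_dv + (nv - 1) / 2
        if (fu < 0 || fu > nu - 1 || fv < 0 || fv > nv - 1) next
        i0 <- min(max(floor(fu), 0), nu - 2)
        v0 <- min(max(floor(fv), 0), nv - 2)
        au <- fu - i0; av <- fv - v0
        P <- proj$data[, , k]
        interp <- (1 - au) * (1 - av) * P[i0 + 1, v0 + 1] +
          au * (1 - av) * P[i0 + 2, v0 + 1] +
          (1 - au) * av * P[i0 + 1, v0 + 2] +
          au * av * P[i0 + 2, v0 + 2]
        out[ix, iy, iz] <- out[ix, iy, iz] +
          scale * (geom$sad / U)^2 * interp
      }
  }
  out
}

# fixtures ------------------------------------------------------------

make_cylinder_volume <- function(grid, radius, mu = 0.02) {
  ax <- grid_axes(grid)
  m <- outer(ax$x^2, ax$y^2, `+`) <= radius^2
  d <- array(0, grid$dims)
  for (iz in seq_len(grid$dims[3])) d[, , iz][m] <- mu
  ct_volume(d, grid$spacing, grid$origin)
}

make_noisy_disk_slice <- function(n = 96, radius = 35, mu = 0.02,
                                  sigma = 0.002, seed = 1) {
  set.seed(seed)
  ax <- (1:n) - (n + 1) / 2
  disk <- outer(ax^2, ax^2, `+`) <= radius^2
  sl <- matrix(0, n, n)
  sl[disk] <- mu
  sl + matrix(rnorm(n * n, 0, sigma), n, n) * disk
}

disk_interior_mask <- function(n = 96, radius = 28) {
  ax <- (1:n) - (n + 1) / 2
  outer(ax^2, ax^2, `+`) <= radius^2
}

# small full-scan geometry matched to a centred grid
small_geometry <- function(n_views = 24, nu = 64, nv = 32, du = 1.6,
                           arc = 360, sad = 1000, sdd = 1536) {
  scan_geometry(sad, sdd, nu, nv, du, du,
                angles = (0:(n_views - 1)) * arc / n_views, arc_deg = arc)
}

# the desk-scale study conditions (matches the package default config)
study_conditions <- function() {
  list(geometry = scan_geometry(1000, 1536, 128, 128, 0.8, 0.8,
                                angles = (0:59) * 6, arc_deg = 360),
       grid = grid_spec(c(96, 96, 16), c(0.5, 0.5, 1)),
       spec = catphan_spec(),
       I0 = 2e4)
}
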