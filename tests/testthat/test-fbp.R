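test_that("cosine pre-weight is sdd/sqrt(sdd^2 + u^2 + v^2)", {
  g <- scan_geometry(1000, 1536, 9, 7, 51.2, 51.2, angles = 0)
  proj <- projection_set(array(1, c(9, 7, 1)), g)
  w <- cone_preweight(proj)
  expect_s3_class(w, "projection_set")
  expect_equal(w$stage, "preweighted")
  expect_equal(w$data[5, 4, 1], 1)  # central pixel, u = v = 0
  u <- detector_u_coords(g)
  v <- (seq_len(7) - 4) * 51.2
  for (iu in c(1, 3, 9)) for (iv in c(1, 7))
    expect_equal(w$data[iu, iv, 1],
                 1536 / sqrt(1536^2 + u[iu]^2 + v[iv]^2), tolerance = 1e-12)
  # a pixel at distance sdd from the axis is weighted 1/sqrt(2)
  g2 <- scan_geometry(1000, 1536, 3, 1, 1536, 1, angles = 0)
  w2 <- cone_preweight(projection_set(array(1, c(3, 1, 1)), g2))
  expect_equal(w2$data[3, 1, 1], 1 / sqrt(2), tolerance = 1e-12)
})

test_that("ramp filtering suppresses DC and matches a direct DFT oracle", {
  g <- scan_geometry(1000, 1536, 64, 4, 0.8, 0.8, angles = 0)
  const <- projection_set(array(5, c(64, 4, 1)), g, "preweighted")
  out <- ramp_filter(const)
  expect_lt(max(abs(out$data)), 1e-6 * 5)
  expect_equal(out$stage, "filtered")

  # unit impulse response vs independent direct-summation DFT; the row is
  # zero at its ends, so edge padding reduces to zeros and the impulse sits
  # at offset nhead = 32 of the length-128 padded grid
  imp <- array(0, c(64, 4, 1))
  imp[20, , 1] <- 1
  got <- ramp_filter(projection_set(imp, g, "preweighted"))$data[, 1, 1]
  m <- 128                      # 2x next power of two
  du <- 0.8
  f <- c(0:(m / 2), -(m / 2 - 1):-1) / (m * du)
  fn <- 1 / (2 * du)
  H <- fn * (2 / pi) * abs(sin(pi * f / (2 * fn))) *
    0.5 * (1 + cos(pi * f / fn))
  x <- rep(0, m); x[32 + 20] <- 1
  want <- Re(oracle_dft(oracle_dft(x) * H, inverse = TRUE)) / m
  expect_lt(max(abs(got - want[32 + (1:64)])), 1e-10)
})

test_that("ramp filtering is linear", {
  g <- scan_geometry(1000, 1536, 32, 8, 1, 1, angles = c(0, 120))
  set.seed(5)
  X <- array(rnorm(32 * 8 * 2), c(32, 8, 2))
  Y <- array(rnorm(32 * 8 * 2), c(32, 8, 2))
  fx <- ramp_filter(projection_set(X, g, "preweighted"))$data
  fy <- ramp_filter(projection_set(Y, g, "preweighted"))$data
  fxy <- ramp_filter(projection_set(2 * X - 3 * Y, g, "preweighted"))$data
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-10)
})

test_that("Parker weights: redundant ray pairs sum to one", {
  arc <- 200 * pi / 180
  fan <- atan(51.2 / 1536)      # generous fan
  set.seed(9)
  for (i in 1:200) {
    gam <- runif(1, -fan, fan)
    beta <- runif(1, 0, arc - pi - 2 * gam)
    w1 <- parker_weight_value(beta, gam, arc)
    w2 <- parker_weight_value(beta + pi + 2 * gam, -gam, arc)
    expect_lt(abs(w1 + w2 - 1), 1e-9)
  }
})

test_that("Parker weight matches the sin^2 ramp formula and is continuous", {
  arc <- 200 * pi / 180
  delta <- (arc - pi) / 2
  gam <- delta / 2              # gamma = half the over-scan
  # ramp-up region: beta < 2 (delta - gamma)
  beta <- 0.8 * 2 * (delta - gam)
  expect_equal(parker_weight_value(beta, gam, arc),
               sin(pi / 4 * beta / (delta - gam))^2, tolerance = 1e-12)
  expect_equal(parker_weight_value(0, gam, arc), 0)
  # interior is 1; ramp-down matches the mirrored formula
  expect_equal(parker_weight_value(pi / 2, gam, arc), 1)
  bd <- pi - 2 * gam + 0.1
  expect_equal(parker_weight_value(bd, gam, arc),
               sin(pi / 4 * (pi + 2 * delta - bd) / (delta + gam))^2,
               tolerance = 1e-12)
  # bounded in [0, 1] and continuous: adjacent samples differ by at most
  # the analytic slope bound pi/(4 (delta - fan)) * dbeta
  fan <- 0.9 * delta
  bs <- seq(0, arc, length.out = 4001)
  db <- bs[2] - bs[1]
  for (g in c(-fan, 0, fan)) {
    w <- parker_weight_value(bs, g, arc)
    expect_true(all(w >= 0 & w <= 1))
    expect_lt(max(abs(diff(w))), 1.01 * db * pi / (4 * (delta - fan)))
  }
})

test_that("parker_weight passes full scans through and rejects short arcs", {
  g360 <- small_geometry(n_views = 8)
  p <- projection_set(array(runif(64 * 32 * 8), c(64, 32, 8)), g360)
  expect_identical(parker_weight(p)$data, p$data)
  g_small <- scan_geometry(1000, 1536, 64, 8, 10, 10,
                           angles = (0:9) * 19, arc_deg = 190)
  pp <- projection_set(array(1, c(64, 8, 10)), g_small)
  expect_error(parker_weight(pp), "short scan")
})

test_that("pixel-driven backprojection matches an independent loop oracle", {
  geom <- scan_geometry(80, 120, 12, 10, 4, 4,
                        angles = c(0, 85, 170, 255), arc_deg = 360)
  grid <- grid_spec(c(8, 8, 8), c(2, 2, 2))
  set.seed(21)
  proj <- projection_set(array(rnorm(12 * 10 * 4), c(12, 10, 4)), geom,
                         "filtered")
  got <- backproject_pixel_driven(proj, grid)
  want <- oracle_pdb(proj, geom, grid)
  expect_lt(max(abs(got$data - want)), 1e-10)
})

test_that("voxels projecting outside the detector receive nothing", {
  geom <- scan_geometry(1000, 1536, 4, 4, 0.5, 0.5, angles = c(0, 90))
  grid <- grid_spec(c(21, 21, 1), c(2, 2, 2))  # odd: one voxel on the axis
  proj <- projection_set(array(1, c(4, 4, 2)), geom, "filtered")
  vol <- backproject_pixel_driven(proj, grid)
  expect_true(any(vol$data == 0))          # periphery unseen
  expect_gt(max(abs(vol$data)), 0)         # centre seen
})

test_that("FBP recovers a uniform cylinder quantitatively (RDB and PDB)", {
  grid <- grid_spec(c(64, 64, 8), c(1, 1, 1))
  vol <- make_cylinder_volume(grid, radius = 25, mu = 0.02)
  geom <- small_geometry(n_views = 60, nu = 96, nv = 48)
  proj <- simulate_projections(vol, geom, I0 = Inf, noise = FALSE)
  ax <- grid_axes(grid)
  interior <- outer(ax$x^2, ax$y^2, `+`) <= 18^2
  for (bp in c("rdb", "pdb")) {
    rec <- reconstruct_fbp(proj, grid, bp)
    vals <- unlist(lapply(3:6, function(iz) rec$data[, , iz][interior]))
    expect_lt(abs(mean(vals) - 0.02) / 0.02, 0.05)
    expect_lt(sqrt(mean((vals - 0.02)^2)) / 0.02, 0.05)
  }
})

test_that("FBP of zero projections is a zero volume", {
  geom <- small_geometry(n_views = 8)
  grid <- grid_spec(c(16, 16, 4), c(1, 1, 1))
  proj <- projection_set(array(0, c(64, 32, 8)), geom)
  expect_true(all(reconstruct_fbp(proj, grid, "rdb")$data == 0))
  expect_true(all(reconstruct_fbp(proj, grid, "pdb")$data == 0))
})

test_that("an off-centre sphere reconstructs at its true position", {
  grid <- grid_spec(c(48, 48, 12), c(1, 1, 1))
  ax <- grid_axes(grid)
  truth <- array(0, grid$dims)
  ctr <- c(10, -8, 1)
  for (iz in seq_len(12)) {
    d2 <- outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, `+`) +
      (ax$z[iz] - ctr[3])^2
    truth[, , iz][d2 <= 36] <- 0.03
  }
  vol <- ct_volume(truth, grid$spacing, grid$origin)
  geom <- small_geometry(n_views = 48, nu = 96, nv = 48)
  rec <- reconstruct_fbp(simulate_projections(vol, geom, I0 = Inf,
                                              noise = FALSE),
                         grid, "rdb")
  th <- rec$data > 0.5 * max(rec$data)
  idx <- which(th, arr.ind = TRUE)
  centroid <- c(mean(ax$x[idx[, 1]]), mean(ax$y[idx[, 2]]),
                mean(ax$z[idx[, 3]]))
  expect_true(all(abs(centroid - ctr) <= grid$spacing))
})
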