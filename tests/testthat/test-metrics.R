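# a block volume with controllable ROI means: 40 x 40 x 2 mm grid
block_volume <- function(fill = 0) {
  ct_volume(array(fill, c(40, 40, 2)), spacing = c(1, 1, 1), unit = "HU")
}
circ <- function(cx, cy, r = 4) roi_spec("circle", c(cx, cy), r,
                                         zrange = c(-1, 1))

test_that("CNR is |mean difference| over background sd", {
  set.seed(43)
  v <- block_volume()
  ax <- grid_axes(volume_grid(v))
  bgm <- outer((ax$x - 10)^2, (ax$y)^2, `+`) <= 16
  fgm <- outer((ax$x + 10)^2, (ax$y)^2, `+`) <= 16
  for (iz in 1:2) {
    sl <- v$data[, , iz]
    sl[bgm] <- rnorm(sum(bgm), 0, 10)
    sl[fgm] <- 100
    v$data[, , iz] <- sl
  }
  fg <- circ(-10, 0); bg <- circ(10, 0)
  got <- cnr(v, fg, bg)
  vals <- roi_values(v, bg)
  expect_equal(got, abs(100 - mean(vals)) / sd(vals), tolerance = 1e-12)
  expect_equal(cnr(v, bg, bg), 0)
  # invariance under affine rescaling a*V + b, a > 0
  v2 <- v; v2$data <- 3.5 * v$data + 40
  expect_equal(cnr(v2, fg, bg), got, tolerance = 1e-9)
  # pooled-sd variant differs when fg has noise
  expect_error(cnr(block_volume(1), fg, bg), "zero")
})

test_that("RMSE and correlation match their textbook definitions", {
  set.seed(47)
  a <- ct_volume(array(rnorm(800), c(20, 20, 2)), unit = "HU")
  b <- ct_volume(array(rnorm(800), c(20, 20, 2)), unit = "HU")
  expect_equal(rmse(a, a), 0)
  shifted <- a; shifted$data <- a$data + 5
  expect_equal(rmse(shifted, a), 5, tolerance = 1e-12)
  expect_equal(pearson_correlation(shifted, a), 1, tolerance = 1e-12)
  va <- as.numeric(a$data); vb <- as.numeric(b$data)
  expect_equal(rmse(a, b), sqrt(mean((va - vb)^2)), tolerance = 1e-12)
  expect_equal(pearson_correlation(a, b),
               sum((va - mean(va)) * (vb - mean(vb))) /
                 sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2)),
               tolerance = 1e-12)
  expect_error(pearson_correlation(block_volume(1), block_volume(1)),
               "variance")
  # triangle-type bound on random triples
  for (i in 1:10) {
    x <- ct_volume(array(rnorm(200), c(10, 10, 2)))
    y <- ct_volume(array(rnorm(200), c(10, 10, 2)))
    z <- ct_volume(array(rnorm(200), c(10, 10, 2)))
    expect_lte(rmse(x, z), rmse(x, y) + rmse(y, z) + 1e-12)
  }
})

test_that("masked comparison restricts to the ROI", {
  a <- block_volume(0)
  b <- block_volume(2)                        # differs by 2 everywhere
  b$data[1, 1, 1] <- 1000                     # gross error outside the mask
  m <- circ(5, 5, r = 4)
  expect_equal(rmse(a, b, m), 2, tolerance = 1e-12)
  expect_error(rmse(a, ct_volume(array(0, c(5, 5, 1)))), "dimensions")
})

test_that("SNU is the ROI-mean range in percent of 1000 HU", {
  v <- block_volume()
  centers <- list(c(0, 0), c(12, 0), c(-12, 0), c(0, 12), c(0, -12))
  means <- c(0, 50, 100, 20, 80)
  ax <- grid_axes(volume_grid(v))
  for (i in seq_along(centers)) {
    m <- outer((ax$x - centers[[i]][1])^2, (ax$y - centers[[i]][2])^2,
               `+`) <= 16
    for (iz in 1:2) v$data[, , iz][m] <- means[i]
  }
  rois <- lapply(centers, function(cc) circ(cc[1], cc[2]))
  expect_equal(snu(v, rois), 10)
  expect_equal(snu(block_volume(7), rois), 0)
})

test_that("NPS of noise-free uniform ROIs is zero", {
  v <- block_volume(100)
  rois <- list(roi_spec("square", c(-8, 0), 16, c(-1, 1)),
               roi_spec("square", c(8, 0), 16, c(-1, 1)))
  r <- nps_2d(v, rois)
  expect_lt(r$peak, 1e-20)
})

test_that("white-noise NPS satisfies Parseval: mean = sigma^2 dx dy", {
  set.seed(53)
  sigma <- 20
  v <- ct_volume(array(rnorm(64 * 64 * 6, 0, sigma), c(64, 64, 6)),
                 spacing = c(0.5, 0.5, 1), unit = "HU")
  rois <- lapply(list(c(-8, -8), c(8, -8), c(-8, 8), c(8, 8)), function(cc)
    roi_spec("square", cc, 12, c(-2.5, 2.5)))
  r <- nps_2d(v, rois)           # 4 ROIs x 6 slices = 24 patches
  expect_equal(mean(r$nps), sigma^2 * 0.25, tolerance = 0.1)
  expect_gt(r$mean_frequency, 0)
})

test_that("a pure sinusoid peaks in the annulus containing its frequency", {
  f0 <- 0.25                       # cycles/mm
  dx <- 0.5
  ax <- (0:63) * dx
  sl <- outer(cos(2 * pi * f0 * ax), rep(1, 64))
  v <- ct_volume(array(rep(sl, 4), c(64, 64, 4)), spacing = c(dx, dx, 1),
                 unit = "HU")
  rois <- list(roi_spec("square", c(0, 0), 30, c(-2, 2)),
               roi_spec("square", c(0, 0), 30, c(-2, 2)))
  r <- nps_2d(v, rois, nbins = 20)
  peak_bin <- which.max(r$radial$nps)
  expect_lt(abs(r$radial$freq[peak_bin] - f0), 0.08)
})

test_that("MIP and MinIP take per-ray extrema along the chosen axis", {
  v <- block_volume(0)
  v$data[5, 7, 2] <- 9
  m <- mip(v, 3)
  expect_equal(m[5, 7], 9)
  expect_equal(sum(m), 9)
  expect_true(all(minip(v, 3) == 0))
  set.seed(59)
  r <- ct_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)))
  want <- matrix(0, 3, 5)
  for (i in 1:3) for (k in 1:5) want[i, k] <- max(r$data[i, , k])
  expect_equal(mip(r, 2), want)
  want2 <- matrix(0, 4, 5)
  for (j in 1:4) for (k in 1:5) want2[j, k] <- min(r$data[, j, k])
  expect_equal(minip(r, 1), want2)
})

test_that("evaluate_report tabulates all metrics per volume", {
  sc <- study_conditions()
  truth <- mu_to_hu(make_catphan_like(sc$grid, sc$spec))
  set.seed(61)
  addnoise <- function(v, s) {
    v$data <- v$data + array(rnorm(length(v$data), 0, s), dim(v$data))
    v
  }
  low <- addnoise(truth, 10)
  high <- addnoise(truth, 40)
  rois <- catphan_rois(sc$spec)
  rep <- evaluate_report(list(low = low, high = high), ref = truth,
                         rois = rois,
                         mask = roi_spec("circle", c(0, 0), 17, c(-6, 6)))
  expect_equal(nrow(rep), 2)
  expect_true(all(c("cnr_mean", "noise_sd", "snu", "rmse",
                    "correlation") %in% names(rep)))
  expect_equal(rep$rmse[rep$volume == "low"], 10, tolerance = 0.1)
  expect_equal(rep$rmse[rep$volume == "high"], 40, tolerance = 0.1)
  expect_gt(rep$cnr_mean[rep$volume == "low"],
            rep$cnr_mean[rep$volume == "high"])
  expect_gt(rep$correlation[rep$volume == "low"],
            rep$correlation[rep$volume == "high"])
})
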