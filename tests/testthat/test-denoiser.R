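test_that("denoise parameters validate their ranges", {
  p <- denoise_params()
  expect_equal(p$a, 2L)
  expect_equal(p$search_radius, 10L)   # 21 x 21 search window
  expect_equal(p$rho, 10)
  expect_equal(p$tau_percentile, 90)
  expect_equal(p$bins, 128L)
  expect_equal(p$iterations, 20L)
  expect_equal(p$gamma0, 1)
  expect_equal(p$r_red, 0.8)
  expect_error(denoise_params(a = 0), "a must")
  expect_error(denoise_params(search_radius = 1), "search_radius")
  expect_error(denoise_params(rho = -1), "rho")
  expect_error(denoise_params(tau_percentile = 100), "tau_percentile")
  expect_error(denoise_params(bins = 1), "bins")
  expect_error(denoise_params(r_red = 1), "r_red")
})

test_that("entropy follows -sum p log2 p with 0 log 0 = 0", {
  expect_equal(entropy(c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_equal(entropy(c(1, 0, 0, 0)), 0)
  expect_equal(entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(entropy(c(2, 2, 2, 2)), 2)  # counts are normalised
  expect_error(entropy(numeric(0)), "empty")
  expect_error(entropy(c(0, 0)), "empty")
})

test_that("mutual information: identity, independence, and a hand case", {
  d <- diag(c(3, 1, 2, 4))
  expect_equal(mutual_information(d), entropy(c(3, 1, 2, 4)),
               tolerance = 1e-12)
  ind <- outer(c(1, 2, 3), c(4, 1, 5))
  expect_lt(mutual_information(ind), 1e-12)
  # independent scalar evaluation for counts [[2,1],[1,2]]
  counts <- matrix(c(2, 1, 1, 2), 2, 2)
  p <- counts / 6
  hab <- -sum(p * log2(p))
  want <- 1 + 1 - hab           # both marginals are (3,3)/6 -> 1 bit
  expect_equal(mutual_information(counts), want, tolerance = 1e-12)
  expect_equal(statistical_measure(counts), want / 1, tolerance = 1e-12)
})

test_that("MI invariants hold on random joint histograms", {
  set.seed(13)
  for (i in 1:300) {
    B <- sample(2:12, 1)
    counts <- matrix(rpois(B * B, 2), B, B)
    if (sum(counts) == 0) counts[1, 1] <- 1
    mi <- mutual_information(counts)
    ha <- entropy(rowSums(counts)); hb <- entropy(colSums(counts))
    expect_gte(mi, 0)
    expect_lte(mi, min(ha, hb) + 1e-12)
    expect_equal(mi, mutual_information(t(counts)), tolerance = 1e-12)
    m <- statistical_measure(counts)
    expect_gte(m, 0); expect_lte(m, 1)
  }
})

test_that("joint histogram: constant slice, totals, and loop oracle", {
  p <- denoise_params(a = 1, search_radius = 1, bins = 2)
  h <- build_joint_histogram(matrix(7, 8, 8), c(4, 4), p)
  expect_equal(h$n, 72)                   # 9 pixels x 8 displacements
  expect_equal(h$counts[1, 1], 72)
  expect_equal(sum(h$counts), h$n)
  expect_equal(h$marginal_a, rowSums(h$counts))

  set.seed(17)
  slice <- matrix(rnorm(16 * 16), 16, 16)
  p2 <- denoise_params(a = 1, search_radius = 2, bins = 8)
  for (ctr in list(c(1, 1), c(8, 9), c(16, 16))) {
    got <- build_joint_histogram(slice, ctr, p2)
    expect_equal(got$counts, oracle_joint_hist(slice, ctr, 1, 2, 8))
  }
  p3 <- denoise_params(a = 2, search_radius = 3, bins = 16)
  got <- build_joint_histogram(slice, c(7, 5), p3)
  expect_equal(got$counts, oracle_joint_hist(slice, c(7, 5), 2, 3, 16))
})

test_that("statistical measure: diagonal limit is 1, featureless is 0", {
  expect_equal(statistical_measure(diag(c(5, 2, 9))), 1)
  flat <- matrix(0, 4, 4); flat[1, ] <- c(5, 1, 2, 2)  # H(A) = 0
  expect_equal(statistical_measure(flat), 0)
})

test_that("MI weight map matches a clean-room reimplementation", {
  set.seed(19)
  slice <- matrix(abs(rnorm(10 * 10, 0.02, 0.005)), 10, 10)
  p <- denoise_params(a = 1, search_radius = 2, bins = 8)
  tau <- as.numeric(quantile(slice, 0.9))
  wm <- compute_weight_map(slice, p, tau = tau)
  want <- oracle_weight_map(slice, 1, 2, 8, p$rho, tau)
  expect_lt(max(abs(wm$values - want)), 1e-12)
  expect_true(all(wm$values > 0 & wm$values <= 1))
  expect_true(all(wm$measure >= 0 & wm$measure <= 1))
})

test_that("weight map of a flat slice is identically 1 (M = 0 => w = 1)", {
  wm <- compute_weight_map(matrix(0.02, 12, 12), denoise_params())
  expect_equal(as.numeric(wm$values), rep(1, 144))
  expect_equal(as.numeric(wm$measure), rep(0, 144))
})

test_that("weight map of a pure-noise flat region stays near 1", {
  set.seed(23)
  slice <- matrix(rnorm(40 * 40, 0.02, 0.002), 40, 40)
  wm <- compute_weight_map(slice, denoise_params(), tau = 0.02)
  expect_gte(mean(wm$values), 0.9)
})

test_that("NLM weights: self-similar limit, large-h limit, loop oracle", {
  p <- denoise_params(a = 1, search_radius = 2, weight_mode = "nlm",
                      nlm_h = 0.01)
  # constant slice: every displaced patch equals the stationary patch
  wm <- nlm_weight_map(matrix(4, 10, 10), p, tau = 4)
  expect_equal(as.numeric(wm$measure), rep(1, 100))
  expect_equal(as.numeric(wm$values), rep(exp(-1), 100), tolerance = 1e-12)

  set.seed(29)
  slice <- matrix(rnorm(12 * 12), 12, 12)
  ph <- denoise_params(a = 1, search_radius = 2, weight_mode = "nlm",
                       nlm_h = 1e6)
  wmh <- compute_weight_map(slice, ph, tau = 1)
  expect_equal(as.numeric(wmh$measure), rep(1, 144), tolerance = 1e-6)

  pl <- denoise_params(a = 1, search_radius = 3, weight_mode = "nlm",
                       nlm_h = 0.8)
  wml <- compute_weight_map(slice, pl, tau = 1)
  for (ctr in list(c(1, 1), c(6, 7), c(12, 12)))
    expect_equal(wml$measure[ctr[1], ctr[2]],
                 oracle_nlm_measure(slice, ctr, 1, 3, 0.8),
                 tolerance = 1e-12)
})

test_that("TV objective: constant slice, 2x2 hand case, loop oracle", {
  w1 <- matrix(1, 5, 5)
  expect_equal(tv_objective(matrix(3, 5, 5), w1, eps = 0.01), 25 * 0.01)
  V <- matrix(c(0, 0, 1, 1), 2, 2)   # columns (0,0) and (1,1)
  expect_equal(tv_objective(V, matrix(1, 2, 2), eps = 0), 2)
  set.seed(31)
  Vr <- matrix(rnorm(64), 8, 8)
  Wr <- matrix(runif(64, 0.2, 1), 8, 8)
  expect_equal(tv_objective(Vr, Wr, 0.01),
               oracle_tv_objective(Vr, Wr, 0.01), tolerance = 1e-12)
})

test_that("analytic TV gradient equals the numerical gradient", {
  set.seed(37)
  for (i in 1:5) {
    V <- matrix(rnorm(144), 12, 12)
    W <- matrix(runif(144, 0.1, 1), 12, 12)
    eps <- 1e-8 * diff(range(V))
    g <- tv_gradient(V, W, eps)
    num <- numeric_tv_gradient(V, W, eps, h = 1e-6 * diff(range(V)))
    expect_lt(max(abs(g$gradient - num)) / max(abs(num)), 1e-4)
    expect_equal(g$norm, sqrt(sum(g$gradient^2)))
  }
  expect_equal(tv_gradient(matrix(2, 6, 6), matrix(1, 6, 6), 0)$norm, 0)
})

test_that("TV gradient sign pattern: positive at a bump, negative below/right", {
  V <- matrix(0, 6, 6); V[3, 3] <- 1
  g <- tv_gradient(V, matrix(1, 6, 6), eps = 1e-12)$gradient
  expect_gt(g[3, 3], 0)
  expect_lt(g[4, 3], 0)
  expect_lt(g[3, 4], 0)
})

test_that("TV term is invariant under a constant intensity shift", {
  set.seed(41)
  V <- matrix(rnorm(100), 10, 10)
  W <- matrix(runif(100), 10, 10)
  expect_equal(tv_objective(V + 5, W, 0.01), tv_objective(V, W, 0.01),
               tolerance = 1e-9)
  expect_equal(tv_gradient(V + 5, W, 0.01)$gradient,
               tv_gradient(V, W, 0.01)$gradient, tolerance = 1e-9)
  # the measure is shift-invariant too (binning uses the shifted range)
  p <- denoise_params(a = 1, search_radius = 2, bins = 8)
  m1 <- compute_weight_map(V, p, tau = 1)$measure
  m2 <- compute_weight_map(V + 5, p, tau = 1)$measure
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("denoising a constant volume returns it unchanged", {
  vol <- ct_volume(array(0.02, c(16, 16, 2)))
  res <- denoise(vol, denoise_params(a = 1, search_radius = 2,
                                     iterations = 5))
  expect_equal(res$volume$data, vol$data)
  expect_true(all(vapply(res$states, function(s)
    all(diff(s$r_history) == 0), TRUE)))
})

test_that("descent reduces noise and the objective on a noisy disk", {
  p <- denoise_params()
  interior <- disk_interior_mask()
  for (seed in 1:2) {
    sl <- make_noisy_disk_slice(seed = seed)
    vol <- ct_volume(array(sl, c(dim(sl), 1)), c(1, 1, 1))
    res <- denoise(vol, p)
    st <- res$states[[1]]
    expect_lt(st$r_history[length(st$r_history)], st$r_history[1])
    expect_lt(sd(res$volume$data[, , 1][interior]), sd(sl[interior]))
    expect_true(all(diff(st$gamma_history) <= 0))
    # minimum objective is attained at the final accepted iterate
    expect_equal(min(st$r_history), st$r_history[length(st$r_history)])
  }
})

test_that("the NLM-weighted pathway runs end to end with the same interface", {
  sl <- make_noisy_disk_slice(n = 48, radius = 18, seed = 3)
  vol <- ct_volume(array(sl, c(48, 48, 1)))
  res <- denoise(vol, denoise_params(weight_mode = "nlm", iterations = 10))
  st <- res$states[[1]]
  expect_lt(st$r_history[length(st$r_history)], st$r_history[1])
  expect_true(all(is.finite(res$volume$data)))
  expect_named(st, c("t", "gamma", "lambda", "gamma_history", "r_history",
                     "accepted"))
})

test_that("denoise rejects HU volumes and all-zero volumes", {
  hu <- mu_to_hu(ct_volume(array(0.02, c(8, 8, 1))))
  expect_error(denoise(hu), "mu_mm")
  expect_error(denoise(ct_volume(array(0, c(8, 8, 1)))), "tau")
})
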