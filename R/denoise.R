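#' Denoiser hyper-parameters
#'
#' Parameters of the mutual-information weighted non-local total-variation
#' (MI-NLTV) denoiser and of its non-local-means (NLM) weighted baseline.
#' Defaults follow the reference configuration: 5 x 5 patches (`a = 2`),
#' 21 x 21 search window (`search_radius = 10`), spatial exponent
#' `rho = 10`, intensity normaliser `tau` at the 90th percentile of the
#' volume's cumulative intensity distribution, 128 x 128 joint-histogram
#' bins, 20 descent iterations, initial step scale `gamma0 = 1` reduced by
#' `r_red = 0.8` whenever a step fails to lower the objective.
#'
#' @param a patch radius; patch side is `2a + 1` (>= 1).
#' @param search_radius half-extent of the square non-local search window
#'   (>= `a`).
#' @param rho exponent of the spatially encoded factor `(V/tau)^rho` (> 0).
#' @param tau_percentile percentile (0-100, exclusive) of the volume
#'   intensity CDF defining `tau`.
#' @param bins joint-histogram side length (>= 2; 64/128/256 are typical).
#' @param iterations number of gradient-descent steps (>= 1).
#' @param gamma0 initial step scaling `gamma` (> 0).
#' @param r_red multiplicative reduction of `gamma` after a rejected step,
#'   in (0, 1).
#' @param eps TV smoothing constant; `NULL` (default) resolves at run time
#'   to `1e-8` times the slice intensity range.
#' @param weight_mode `"mi"` (mutual information) or `"nlm"` (non-local
#'   means baseline).
#' @param nlm_h NLM bandwidth (intensity units) for `weight_mode = "nlm"`.
#' @param step_scale multiplier of the adaptive step
#'   `lambda = gamma * sqrt(sum(V^2)) * step_scale`; default 1 (the step is
#'   controlled by the `gamma` backtracking).
#' @param accept_mode `"reject"` (default: a step that raises the objective
#'   is undone and `gamma` shrunk) or `"keep"` (the step is kept and only
#'   future steps shrink).
#' @param weight_composition `"product"` (default: exponent is
#'   `(V/tau)^rho * M`) or `"quotient"` (`(V/tau)^rho / M`), retained for
#'   experimentation.
#' @param recompute_weights_every recompute the weight map every this many
#'   iterations (0 = compute once from the input slice, the default).
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(a = 2L, search_radius = 10L, rho = 10,
                           tau_percentile = 90, bins = 128L,
                           iterations = 20L, gamma0 = 1.0, r_red = 0.8,
                           eps = NULL, weight_mode = c("mi", "nlm"),
                           nlm_h = 0.002, step_scale = 1.0,
                           accept_mode = c("reject", "keep"),
                           weight_composition = c("product", "quotient"),
                           recompute_weights_every = 0L) {
  weight_mode <- match.arg(weight_mode)
  accept_mode <- match.arg(accept_mode)
  weight_composition <- match.arg(weight_composition)
  a <- as.integer(a); search_radius <- as.integer(search_radius)
  bins <- as.integer(bins); iterations <- as.integer(iterations)
  if (a < 1L) stop("patch radius a must be >= 1")
  if (search_radius < a) stop("search_radius must be >= patch radius a")
  if (!(rho > 0)) stop("rho must be > 0, got ", rho)
  if (!(tau_percentile > 0 && tau_percentile < 100))
    stop("tau_percentile must lie in (0, 100)")
  if (bins < 2L) stop("bins must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!(gamma0 > 0)) stop("gamma0 must be > 0")
  if (!(r_red > 0 && r_red < 1)) stop("r_red must lie in (0, 1)")
  if (!is.null(eps) && !(eps > 0)) stop("eps must be > 0 (or NULL for auto)")
  if (!(nlm_h > 0)) stop("nlm_h must be > 0")
  if (!(step_scale > 0)) stop("step_scale must be > 0")
  structure(list(a = a, search_radius = search_radius, rho = rho,
                 tau_percentile = tau_percentile, bins = bins,
                 iterations = iterations, gamma0 = gamma0, r_red = r_red,
                 eps = eps, weight_mode = weight_mode, nlm_h = nlm_h,
                 step_scale = step_scale, accept_mode = accept_mode,
                 weight_composition = weight_composition,
                 recompute_weights_every = as.integer(recompute_weights_every)),
            class = "denoise_params")
}

#' Shannon entropy of a histogram or probability vector (bits)
#'
#' `H = -sum p_i log2 p_i` with the `0 log 0 := 0` convention.  Raw counts
#' are normalised internally.
#'
#' @param marginal non-negative counts or probabilities, summing to > 0.
#' @return Entropy in bits.
#' @export
entropy <- function(marginal) {
  marginal <- as.numeric(marginal)
  if (length(marginal) == 0L || sum(marginal) <= 0)
    stop("entropy of an empty histogram is undefined")
  if (any(marginal < 0)) stop("negative histogram counts")
  p <- marginal / sum(marginal)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint intensity histogram of non-local patch pairs
#'
#' Builds the aggregated joint histogram at one slice position: intensities
#' are mapped linearly to bins `1..B` from the slice-global min/max, and for
#' every non-null displacement `d` in the `(2s+1)^2` search window each
#' pixel pair (stationary patch, patch shifted by `d`) increments one joint
#' bin.  The total count is `(2a+1)^2 * ((2s+1)^2 - 1)`.  A flat slice puts
#' every pair in bin (1, 1) (still a valid histogram).  Borders use
#' reflective padding.
#'
#' @param slice numeric matrix.
#' @param center integer (row, col), 1-based position of the stationary
#'   patch centre.
#' @param params a [denoise_params()].
#' @return List with `counts` (B x B matrix, stationary bins on rows),
#'   `marginal_a`, `marginal_b` (row/column sums) and `n` (total pairs).
#' @export
build_joint_histogram <- function(slice, center, params = denoise_params()) {
  stopifnot(is.matrix(slice), length(center) == 2L)
  h <- cpp_joint_histogram(slice, as.integer(center[1]),
                           as.integer(center[2]),
                           params$a, params$search_radius, params$bins)
  list(counts = h$counts,
       marginal_a = rowSums(h$counts),
       marginal_b = colSums(h$counts),
       n = h$n)
}

#' Mutual information of a joint histogram (bits)
#'
#' `MI = H(A) + H(B) - H(A, B)` from the marginal and joint entropies of
#' the (normalised) counts; clipped at 0 from below against float
#' round-off.
#'
#' @param h a joint histogram as returned by [build_joint_histogram()], or
#'   any list with a `counts` matrix.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(h) {
  counts <- if (is.list(h)) h$counts else h
  stopifnot(is.matrix(counts))
  if (sum(counts) <= 0) stop("empty joint histogram")
  ha <- entropy(rowSums(counts))
  hb <- entropy(colSums(counts))
  hab <- entropy(as.numeric(counts))
  max(0, ha + hb - hab)
}

#' MI-based statistical similarity measure
#'
#' `M = MI(A, B) / H(A)`, the mutual information between the stationary
#' patch and the aggregated search-set patches normalised by the stationary
#' patch entropy; clamped to `[0, 1]`.  A featureless stationary patch
#' (`H(A) < 1e-12` bits) maps to 0, the pure-smoothing state.
#'
#' @inheritParams mutual_information
#' @return M in `[0, 1]`.
#' @export
statistical_measure <- function(h) {
  counts <- if (is.list(h)) h$counts else h
  ha <- entropy(rowSums(counts))
  if (ha < 1e-12) return(0)
  min(1, max(0, mutual_information(counts) / ha))
}

compose_weights <- function(slice, M, tau, params) {
  spatial <- (pmax(slice, 0) / tau)^params$rho
  expo <- if (params$weight_composition == "product") spatial * M
          else spatial / pmax(M, 1e-12)
  w <- exp(-expo)
  matrix(w, nrow(slice), ncol(slice))
}

#' Per-pixel smoothing weight map
#'
#' For every pixel j of a slice computes
#' `w_j = exp(-(max(V_j, 0)/tau)^rho * M_j)`, combining the spatially
#' encoded intensity factor with the similarity measure `M_j`
#' ([statistical_measure()] of the pixel's aggregated joint histogram for
#' `weight_mode = "mi"`, or the mean Gaussian patch-distance similarity for
#' `"nlm"`).  Small weights mark preservation pixels (high intensity and/or
#' high patch similarity); weights near 1 mark smoothing pixels.
#'
#' @param slice numeric matrix in the attenuation (mu) domain.
#' @param params a [denoise_params()].
#' @param tau intensity normaliser; default the `tau_percentile` point of
#'   the slice's own intensity CDF (pass the volume-wide value explicitly
#'   when denoising slice-by-slice).
#' @return List of class `weight_map` with matrices `values` (w, in (0,1])
#'   and `measure` (M, in \[0,1\]).
#' @export
compute_weight_map <- function(slice, params = denoise_params(), tau = NULL) {
  stopifnot(is.matrix(slice))
  if (is.null(tau))
    tau <- as.numeric(quantile(slice, params$tau_percentile / 100))
  if (!(is.finite(tau) && tau > 0))
    stop("tau must be positive; is the volume all zero?")
  M <- if (params$weight_mode == "mi") {
    cpp_mi_measure_map(slice, params$a, params$search_radius, params$bins)
  } else {
    cpp_nlm_measure_map(slice, params$a, params$search_radius, params$nlm_h)
  }
  structure(list(values = compose_weights(slice, M, tau, params),
                 measure = M, tau = tau),
            class = "weight_map")
}

#' Non-local-means weight map (baseline)
#'
#' Convenience wrapper: [compute_weight_map()] with the NLM similarity
#' (`M_j` = mean over displacements of
#' `exp(-||patch_0 - patch_d||^2 / ((2a+1)^2 nlm_h^2))`) in place of the MI
#' measure, composed with the same spatial factor.
#'
#' @inheritParams compute_weight_map
#' @return A `weight_map`, as [compute_weight_map()].
#' @export
nlm_weight_map <- function(slice, params = denoise_params(), tau = NULL) {
  params$weight_mode <- "nlm"
  compute_weight_map(slice, params, tau)
}

resolve_eps <- function(params, slice) {
  if (!is.null(params$eps)) return(params$eps)
  rng <- diff(range(slice))
  if (rng <= 0) rng <- 1
  1e-8 * rng
}

#' Weighted total-variation objective
#'
#' `R = sum_j w_j sqrt(D_j^2 + eps^2)` with the backward-difference local
#' gradient magnitude
#' `D(V_j) = sqrt((V(x,y) - V(x-1,y))^2 + (V(x,y) - V(x,y-1))^2)`; the
#' first row/column differences are 0 (reflective boundary).
#'
#' @param v_slice numeric matrix.
#' @param w weight map: a `weight_map` or a matrix of the same shape.
#' @param eps smoothing constant (>= 0).
#' @return The scalar objective value.
#' @export
tv_objective <- function(v_slice, w, eps = 0) {
  if (inherits(w, "weight_map")) w <- w$values
  stopifnot(is.matrix(v_slice), is.matrix(w))
  if (!all(dim(v_slice) == dim(w))) stop("slice/weight-map shape mismatch")
  cpp_tv_objective(v_slice, w, eps)
}

#' Analytic gradient of the weighted TV objective
#'
#' The exact derivative of [tv_objective()] with respect to every pixel:
#' three terms coupling each pixel to its own backward differences and to
#' the differences of its right and lower neighbours, with eps-smoothed
#' denominators.
#'
#' @inheritParams tv_objective
#' @return List with `gradient` (matrix) and `norm`
#'   (`sqrt(sum(gradient^2))`, the root-sum-square used to normalise the
#'   descent direction).
#' @export
tv_gradient <- function(v_slice, w, eps = 0) {
  if (inherits(w, "weight_map")) w <- w$values
  stopifnot(is.matrix(v_slice), is.matrix(w))
  if (!all(dim(v_slice) == dim(w))) stop("slice/weight-map shape mismatch")
  g <- cpp_tv_gradient(v_slice, w, eps)
  list(gradient = g, norm = sqrt(sum(g^2)))
}

denoise_slice <- function(slice, params, tau) {
  eps <- resolve_eps(params, slice)
  wm <- compute_weight_map(slice, params, tau)
  v <- slice
  r_hist <- cpp_tv_objective(v, wm$values, eps)
  gamma <- params$gamma0
  gamma_hist <- lambda_hist <- numeric(0)
  accepted <- logical(0)
  for (t in seq_len(params$iterations)) {
    if (params$recompute_weights_every > 0L &&
        t > 1L && (t - 1L) %% params$recompute_weights_every == 0L)
      wm <- compute_weight_map(v, params, tau)
    g <- cpp_tv_gradient(v, wm$values, eps)
    gn <- sqrt(sum(g^2))
    lambda <- gamma * sqrt(sum(v^2)) * params$step_scale
    if (gn <= .Machine$double.xmin) {  # flat objective: nothing to descend
      r_hist <- c(r_hist, r_hist[length(r_hist)])
      gamma_hist <- c(gamma_hist, gamma)
      lambda_hist <- c(lambda_hist, lambda)
      accepted <- c(accepted, TRUE)
      next
    }
    cand <- v - lambda * g / gn
    r_new <- cpp_tv_objective(cand, wm$values, eps)
    if (!is.finite(r_new)) stop("non-finite objective during descent")
    r_prev <- r_hist[length(r_hist)]
    if (r_new > r_prev) {
      gamma <- gamma * params$r_red
      if (params$accept_mode == "keep") {
        v <- cand
        r_hist <- c(r_hist, r_new)
      } else {
        r_hist <- c(r_hist, r_prev)
      }
      accepted <- c(accepted, params$accept_mode == "keep")
    } else {
      v <- cand
      r_hist <- c(r_hist, r_new)
      accepted <- c(accepted, TRUE)
    }
    gamma_hist <- c(gamma_hist, gamma)
    lambda_hist <- c(lambda_hist, lambda)
  }
  if (!all(is.finite(v))) stop("non-finite voxels after descent")
  list(slice = v, weight_map = wm,
       state = list(t = params$iterations, gamma = gamma,
                    lambda = lambda_hist, gamma_history = gamma_hist,
                    r_history = r_hist, accepted = accepted))
}

#' MI-NLTV / NLTV volume denoising
#'
#' Minimises the weighted TV objective slice by slice (2-D processing along
#' the axial direction) by normalised steepest descent with an adaptive
#' step.  Per slice: the weight map is computed once from the input slice
#' (see `recompute_weights_every`); each step moves
#' `V <- V - lambda * grad R / ||grad R||` with
#' `lambda = gamma * sqrt(sum(V^2)) * step_scale`; whenever a step fails to
#' lower `R`, `gamma` is multiplied by `r_red` (and the step undone under
#' the default `accept_mode = "reject"`), so the step length backtracks
#' geometrically from image scale down to noise scale.  The intensity
#' normaliser `tau` is the `tau_percentile` point of the whole volume's
#' intensity CDF, computed once.
#'
#' @param vol a [ct_volume()] in unit `"mu_mm^-1"`.
#' @param params a [denoise_params()].
#' @param keep_weight_maps return the per-slice weight maps (memory
#'   permitting).
#' @return List of class `denoise_result`: `volume` (the denoised
#'   [ct_volume()]), `states` (per-slice descent state: `r_history`,
#'   `gamma_history`, `lambda`, `accepted`), `tau`, and optionally
#'   `weight_maps`.
#' @export
denoise <- function(vol, params = denoise_params(),
                    keep_weight_maps = FALSE) {
  stopifnot(inherits(vol, "ct_volume"), inherits(params, "denoise_params"))
  if (vol$unit != "mu_mm^-1")
    stop("denoise operates on mu_mm^-1 volumes (convert HU first)")
  tau <- as.numeric(quantile(vol$data, params$tau_percentile / 100))
  if (!(is.finite(tau) && tau > 0))
    stop("tau (volume intensity percentile) must be positive; ",
         "is the volume all zero?")
  nz <- dim(vol$data)[3]
  out <- vol
  states <- vector("list", nz)
  wms <- if (keep_weight_maps) vector("list", nz) else NULL
  for (iz in seq_len(nz)) {
    r <- tryCatch(denoise_slice(vol$data[, , iz], params, tau),
                  error = function(e)
                    stop("denoise failed at slice ", iz, ": ",
                         conditionMessage(e)))
    out$data[, , iz] <- r$slice
    states[[iz]] <- r$state
    if (keep_weight_maps) wms[[iz]] <- r$weight_map
  }
  res <- list(volume = out, states = states, tau = tau, params = params)
  if (keep_weight_maps) res$weight_maps <- wms
  class(res) <- "denoise_result"
  res
}

#' @export
print.denoise_result <- function(x, ...) {
  r0 <- vapply(x$states, function(s) s$r_history[1], 0)
  r1 <- vapply(x$states, function(s) s$r_history[length(s$r_history)], 0)
  cat(sprintf("MI-NLTV denoise result: %d slices, objective %.4g -> %.4g (sum)\n",
              length(x$states), sum(r0), sum(r1)))
  invisible(x)
}
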