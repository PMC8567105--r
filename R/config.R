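default_config <- function() {
  list(
    geometry = list(sad = 1000, sdd = 1536, det_nu = 128L, det_nv = 128L,
                    det_du = 0.8, det_dv = 0.8, n_views = 60L,
                    arc_deg = 360, start_angle = 0,
                    det_offset_u = 0, det_offset_v = 0),
    grid = list(dims = c(96L, 96L, 16L), spacing = c(0.5, 0.5, 1),
                origin = NULL),
    reconstruction = list(backprojectors = c("rdb", "pdb"),
                          apply_parker = TRUE, mu_water = 0.02),
    denoise = list(modes = c("none", "nlm", "mi"),
                   a = 2L, search_radius = 10L, rho = 10,
                   tau_percentile = 90, bins = 128L, iterations = 20L,
                   gamma0 = 1.0, r_red = 0.8, eps = NULL,
                   nlm_h = 0.002, step_scale = 1.0,
                   accept_mode = "reject",
                   weight_composition = "product",
                   recompute_weights_every = 0L),
    simulation = list(I0 = 2e4, benchmark_I0 = 3.2e5, seed = 1L,
                      noise = TRUE, electronic_sigma = 0),
    metrics = list(roi_margin = 1.5),
    output = list(dir = "conebeam_out"),
    log_level = "info"
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) document, fills unset keys with the package
#' defaults (the reference denoiser configuration: 5 x 5 patches, 21 x 21
#' search, rho = 10, tau at the 90th percentile, 128 bins, 20 iterations,
#' gamma0 = 1, r_red = 0.8), and validates every value.  Unknown keys are
#' rejected by name (typo safety), out-of-range values raise errors naming
#' the offending key.
#'
#' @param path YAML/JSON file; `NULL` yields the pure defaults.
#' @return An object of class `pipeline_config` with elements `geometry`
#'   ([scan_geometry()]), `grid` ([grid_spec()]), `denoise_params`
#'   ([denoise_params()]) plus the raw validated sections.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  build_config(cfg)
}

#' Build a validated pipeline configuration from a list
#'
#' @param cfg a full configuration list in the layout of the package
#'   defaults (see [load_config()]); partial lists should go through
#'   [load_config()] instead.
#' @return A `pipeline_config`.
#' @export
build_config <- function(cfg) {
  g <- cfg$geometry
  angles <- g$start_angle + (seq_len(g$n_views) - 1) * g$arc_deg / g$n_views
  geometry <- scan_geometry(g$sad, g$sdd, g$det_nu, g$det_nv, g$det_du,
                            g$det_dv, angles, arc_deg = g$arc_deg,
                            det_offset_u = g$det_offset_u,
                            det_offset_v = g$det_offset_v)
  grid <- grid_spec(cfg$grid$dims, cfg$grid$spacing, cfg$grid$origin)
  dn <- cfg$denoise
  modes <- match.arg(dn$modes, c("none", "nlm", "mi"), several.ok = TRUE)
  dp <- denoise_params(a = dn$a, search_radius = dn$search_radius,
                       rho = dn$rho, tau_percentile = dn$tau_percentile,
                       bins = dn$bins, iterations = dn$iterations,
                       gamma0 = dn$gamma0, r_red = dn$r_red, eps = dn$eps,
                       nlm_h = dn$nlm_h, step_scale = dn$step_scale,
                       accept_mode = dn$accept_mode,
                       weight_composition = dn$weight_composition,
                       recompute_weights_every = dn$recompute_weights_every)
  bp <- match.arg(cfg$reconstruction$backprojectors, c("rdb", "pdb"),
                  several.ok = TRUE)
  if (!(cfg$reconstruction$mu_water > 0))
    stop("reconstruction.mu_water must be > 0")
  if (!(cfg$simulation$I0 > 0)) stop("simulation.I0 must be > 0")
  structure(list(geometry = geometry, grid = grid, denoise_params = dp,
                 denoise_modes = modes, backprojectors = bp,
                 raw = cfg), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  print(x$geometry)
  print(x$grid)
  cat(sprintf("  backprojectors: %s; denoisers: %s\n",
              paste(x$backprojectors, collapse = "/"),
              paste(x$denoise_modes, collapse = "/")))
  cat(sprintf("  simulation: I0 = %g, seed = %s\n", x$raw$simulation$I0,
              x$raw$simulation$seed))
  invisible(x)
}
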