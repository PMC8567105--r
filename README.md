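# conebeam

Cone-beam CT (CBCT) image formation and restoration for the low-dose
regime, in R.

CBCT scans taken at every radiotherapy fraction add up to a real imaging
dose; acquiring each projection at a low tube current-time product (mAs)
cuts that dose but leaves the filtered-backprojection reconstruction
dominated by photon noise.  `conebeam` implements an image-domain answer
to this problem for physicists and algorithm developers who want a fully
inspectable, test-covered reference implementation:

* **Siddon ray tracing** — exact ray/voxel intersection lengths, driving a
  forward projector and a *ray-driven backprojector* (RDB) that
  reconstructs each voxel as the intersection-length weighted average
  `mu_j = sum_k l_jk P_k / sum_k l_jk` of the filtered projection values,
  plus a conventional pixel-driven FDK backprojector (PDB) as baseline.
* **The analytical chain** — FDK cosine pre-weighting, a Shepp-Logan x
  raised-cosine (Hann) ramp filter applied per detector row in physical
  frequency units, and Parker short-scan weighting for partial arcs.
* **The MI-NLTV denoiser** — a weighted total-variation objective
  `R(V) = sum_j w_j D(V_j)` minimised by normalised steepest descent with
  an adaptive, backtracking step.  The per-pixel weight
  `w_j = exp(-(V_j/tau)^rho * M_j)` combines a spatially encoded intensity
  factor with a *mutual-information statistical measure*
  `M = MI(A, B_Omega) / H(A)`: the MI between a stationary patch and the
  aggregated non-local patches of its search window, normalised by the
  stationary-patch entropy and estimated from a joint intensity histogram.
  Unlike non-local-means patch distances (also provided, as the NLTV
  baseline), the MI measure does not require a linear intensity match, so
  it stays informative when both patches carry heavy noise.
* **A synthetic study** — a Catphan-like digital phantom (sensitometry
  inserts, uniformity module, line-pair bars) with a Poisson transmission
  noise model, and the standard metrics: CNR, RMSE, correlation, SNU,
  2-D noise power spectrum, MIP/MinIP.

The models, parameter meanings and all numerical choices are documented in
the methods vignette (`vignettes/conebeam-methods.Rmd`).

## Worked example

A low-dose scan of the digital phantom, reconstructed with the RDB and
denoised with MI-NLTV:

```r
library(conebeam)

geometry <- scan_geometry(sad = 1000, sdd = 1536, det_nu = 128,
                          det_nv = 128, det_du = 0.8, det_dv = 0.8,
                          angles = (0:59) * 6)
grid    <- grid_spec(dims = c(96, 96, 16), spacing = c(0.5, 0.5, 1))
phantom <- catphan_spec()
truth   <- make_catphan_like(grid, phantom)

proj  <- simulate_projections(truth, geometry, I0 = 2e4, seed = 1)
recon <- reconstruct_fbp(proj, grid, backprojector = "rdb")
result <- denoise(recon, denoise_params(weight_mode = "mi"))
result
#> MI-NLTV denoise result: 16 slices, objective 270.4 -> 172.9 (sum)

rois <- catphan_rois(phantom)
hu0 <- mu_to_hu(recon); hu1 <- mu_to_hu(result$volume)
round(sapply(rois$inserts, function(r)
  c(fbp = cnr(hu0, r, rois$background),
    minltv = cnr(hu1, r, rois$background))), 1)
#>        delrin teflon  air pmp ldpe polystyrene air2
#> fbp       7.9   19.2 21.7 4.2  1.6         0.7 21.9
#> minltv   15.4   39.2 43.4 7.4  3.4         1.8 43.7
```

The denoiser roughly doubles the contrast-to-noise ratio of every density
insert while the uniformity-region noise drops from 27.8 HU to 13.2 HU;
`result$states` holds the per-slice objective history, step sizes and
acceptance flags of the descent.  `run_pipeline(load_config())` performs
the whole six-way comparison (RDB/PDB x none/NLTV/MI-NLTV) from a single
config and writes volumes, weight maps, objective logs, a metrics report
and a reproducibility manifest; a thin command-line wrapper lives at
`inst/scripts/conebeam_cli.R`.

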