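---
title: "Low-dose CBCT reconstruction and MI-NLTV denoising: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-dose CBCT reconstruction and MI-NLTV denoising: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cone-beam CT (CBCT) guides patient positioning in image-guided
radiotherapy.  Because a CBCT is acquired at every fraction, the imaging
dose matters: lowering the tube current-time product (mAs) per projection
lowers the dose proportionally, but the photon-starved projections produce
reconstructions dominated by noise.  `conebeam` implements an image-domain
restoration chain for this regime: an analytical filtered-backprojection
(FBP) reconstructor with a ray-driven backprojector, followed by a
mutual-information weighted non-local total-variation (MI-NLTV) denoiser
that removes noise while preserving high-contrast structure.  A digital
phantom simulator and the standard CT image-quality metrics make the whole
chain testable without any scanner data.

## Image formation

### Geometry

A circular cone-beam orbit: the source rotates at distance `sad` (mm) from
the rotation axis (+z), a flat detector at `sdd` from the source.  At
gantry angle 0 the source is on -y; detector coordinate u rotates with the
gantry (+x at angle 0), v is axial.  Projections are stored post-log, i.e.
as line integrals $p = \int \mu \, dl$ of the attenuation map
$\mu$ (mm$^{-1}$).

### Siddon ray tracing

Forward projection and the ray-driven backprojector need the exact
intersection lengths $l_{jk}$ between ray $k$ and voxel $j$.  These are
computed by parametric plane crossing (the Siddon construction): the ray's
entry/exit parameters for each slab of voxel planes are merged in order,
and each inter-crossing interval contributes its length to the voxel it
traverses.  Two numerical choices close degenerate cases the construction
leaves open: crossings shorter than $10^{-12}$ mm (corner grazes) are
dropped, and exact plane/corner ties are resolved by advancing every axis
whose crossing parameter equals the merged minimum.  The implementation
guarantees $\sum_j l_{jk}$ equals the ray's bounding-box chord to float
precision, which the tests verify against an independent
dense-sampling oracle.

### Filtering

The reconstruction filter chain applies, per projection:

1. **Cosine pre-weighting** $w(u,v) = \mathrm{sdd}/\sqrt{\mathrm{sdd}^2 +
   u^2 + v^2}$, the FDK factor compensating the intensity drop of oblique
   rays at larger cone/fan angles.
2. **Parker weighting** (short scans only, arc $< 360^\circ$): rays
   measured twice on an arc of $\pi + 2\delta$ (with
   $\delta = (\mathrm{arc} - \pi)/2$) are blended by the classic
   $\sin^2$ ramps in $(\beta, \gamma)$, $\gamma = \arctan(u/\mathrm{sdd})$
   the fan angle, so that every redundant pair sums to weight 1.  Using
   the half over-scan $\delta$ instead of the physical fan half-angle
   generalises the classic weights to arcs longer than the minimal short
   scan; arcs below $180^\circ + 2\,\mathrm{fan}$ are rejected.  Whether
   this weighting runs before or after ramp filtering is analytically
   irrelevant for row-constant weights; it runs before (the conventional
   order), and `reconstruct_fbp()` keeps that fixed.
3. **Ramp filtering** of each detector row: DFT, multiplication by
   $H(f) = \underbrace{f_N \tfrac{2}{\pi}\left|\sin\tfrac{\pi f}{2 f_N}\right|}_{\text{Shepp-Logan ramp}}
   \cdot \underbrace{\tfrac12\left(1 + \cos\tfrac{\pi f}{f_N}\right)}_{\text{raised cosine (Hann)}}$,
   inverse DFT.  $f_N = 1/(2\,\Delta u)$ is the detector Nyquist
   frequency; expressing $H$ in physical frequency units builds the
   convolution step $\Delta u$ into the result.  Rows are padded to twice
   the next power of two.  The pad continues each row with its endpoint
   value (`pad_mode = "edge"`) rather than zeros: a hard zero pad turns a
   constant row into a boxcar whose edge response leaks several percent
   into the cropped output, while edge continuation leaves constants with
   exactly zero response ($H(0) = 0$).  For physical projections, which
   taper to zero at the detector edge, the two modes coincide;
   `pad_mode = "zero"` is available.

### Backprojection

**Ray-driven (RDB).**  Each detector pixel casts a ray back to the focal
spot; every traversed voxel accumulates
$\mu_j = \sum_k l_{jk} P_k \,\big/\, \sum_k l_{jk}$,
a pure intersection-length weighted average of the filtered projection
values.  This form is exactly invariant on constant projections (a
flat-field maps to a flat volume), which the tests exploit as an identity.
Voxels whose accumulated length stays below $10^{-9}$ mm are reported as
uncovered in a coverage mask rather than divided by a near-zero.  Because
the average strips the angular integration measure, `reconstruct_fbp()`
multiplies the RDB output by $\mathrm{arc} \cdot (\mathrm{sdd}/\mathrm{sad})
\cdot c$ ($c = \tfrac12$ for full scans, 1 for Parker-weighted short
scans), the factor that restores quantitative mm$^{-1}$ near the axis; the
separation keeps the backprojector itself a clean averaging operator.

**Pixel-driven (PDB).**  The FDK baseline: each voxel centre is
perspective-projected onto the detector, the filtered projection is
bilinearly interpolated, and the contribution is weighted by
$(\mathrm{sad}/U)^2$ ($U$ = voxel distance from the source along the
central ray) and the per-view scale $\Delta\beta \cdot
(\mathrm{sdd}/\mathrm{sad}) \cdot c$.  The $\mathrm{sdd}/\mathrm{sad}$
factor rescales the detector-pitch ramp filter to isocenter sampling;
with it, both backprojectors reconstruct a known cylinder's $\mu$ within a
few percent, and agreement between the two is a standing cross-check in
the test suite.

HU conversion is $\mathrm{HU} = 1000\,(\mu - \mu_w)/\mu_w$ with
$\mu_w = 0.02$ mm$^{-1}$ by default (configurable); reconstruction leaves
negative $\mu$ unclamped and reports it.

## The MI-NLTV denoiser

Processing is 2-D, slice by slice along the axis.  Three ingredients:

### The statistical measure

For every pixel, a stationary patch of side $2a+1$ ($a = 2$, i.e.
$5\times5$) is compared against all patches displaced by
$d \ne 0$ within a $21 \times 21$ search window.  All
$(2a+1)^2 \cdot \left((2s+1)^2 - 1\right)$ intensity pairs increment one
aggregated joint histogram ($B \times B$, $B = 128$ by default; intensity
bins span the slice's global min-max so the histogram axes always cover
exactly $B$ levels).  From its marginal and joint Shannon entropies (bits),

$$M = \frac{\mathrm{MI}(A, B^\Omega)}{H(A)}
    = \frac{H(A) + H(B^\Omega) - H(A, B^\Omega)}{H(A)} \in [0, 1].$$

$M$ is high where the neighbourhood predicts the stationary patch
(repeating structure, edges) and near zero for featureless noise, and —
unlike patch-difference (NLM) similarity — it does not require the
corresponding intensities to match linearly, which is what makes it robust
when both patches are noise-corrupted.  Design choices behind this
realisation, where the formulation is open:

* one histogram aggregated over all displacements (per-voxel $M$, matching
  a per-voxel weight map), rather than per-displacement MIs averaged;
* the null displacement is excluded — including it adds a diagonal
  component that inflates MI toward $H(A)$ everywhere;
* slice-global intensity scaling, so $M$ is continuous across neighbouring
  centres (per-window scaling would make the binning jump);
* a featureless stationary patch ($H(A) < 10^{-12}$ bits) maps to
  $M = 0$, the pure-smoothing state.

### The weight map

$$w_j = \exp\!\left(-\left(\max(V_j, 0)/\tau\right)^{\rho} M_j\right)
  \in (0, 1],$$

with $\rho = 10$ and $\tau$ the 90th percentile of the whole volume's
intensity CDF, computed once per volume.  The exponent is the *product* of
the spatially encoded factor and $M$: weights shrink (preservation) where
intensity is high and/or the neighbourhood is structured, and stay near 1
(smoothing) in flat noisy regions.  The alternative quotient reading would
invert that behaviour; a `weight_composition` switch retains it for
experimentation.  The spatial factor uses $\max(V_j, 0)$ because FBP
leaves small negative values whose odd powers would misbehave — the
denoiser therefore operates in the $\mu$ domain before HU conversion.
The NLM baseline (`weight_mode = "nlm"`) replaces $M_j$ with the mean
Gaussian patch-distance similarity
$\mathrm{mean}_d \exp(-\lVert p_0 - p_d \rVert^2 / ((2a+1)^2 h^2))$,
composed with the same spatial factor; the bandwidth default
$h = 0.002$ mm$^{-1}$ is a few times the reconstructed noise SD at the
package's study conditions (no reference formulation is available for this
baseline, so it is stated as a package choice).

### The descent

The weighted TV objective, with backward differences and reflective
boundaries (first row/column differences are zero), smoothed by a small
$\varepsilon$:

$$R(V) = \sum_j w_j \sqrt{D^2(V_j) + \varepsilon^2}, \qquad
  D^2(V_j) = (V_{x,y} - V_{x-1,y})^2 + (V_{x,y} - V_{x,y-1})^2.$$

Its analytic gradient couples each pixel to its own differences and to
those of its right and lower neighbours (three terms, each with the
$\varepsilon$-smoothed denominator of the objective term it
differentiates), so the gradient is the exact derivative of the smoothed
objective — the single most important correctness gate, enforced against
central differences in the tests.  $\varepsilon$ defaults to $10^{-8}$
times the slice range: it only regularises the kink at zero gradient and
is orders of magnitude below image contrast.

Descent iterates
$V^{t+1} = V^t - \lambda \, \nabla R(V^t) / \lVert \nabla R(V^t) \rVert$
with the adaptive step $\lambda = \gamma \sqrt{\sum_j (V_j^t)^2}$,
$\gamma_0 = 1$, for 20 iterations; whenever a step fails to lower $R$,
$\gamma$ is multiplied by $r_{red} = 0.8$.  Because the gradient is
normalised to unit L2 norm, $\lambda$ *is* the L2 displacement of the
step, and $\lambda_0$ equals the image norm — far too large to be
accepted.  Two readings of the failure handling are possible, and the
package chooses **rejection**: a step that raised the objective is undone
before $\gamma$ shrinks.  With rejection, the scheme is a normalised
gradient descent with geometric backtracking: the step length collapses
from image scale to noise scale within roughly
$\log_{0.8}(\sigma \sqrt{N} / \lVert V \rVert)$ rejected trials
(about half the 20-iteration budget at the study conditions), after which
accepted steps decrease $R$ monotonically.  This makes the step
self-scaling without any hand-chosen step constant.  The alternative —
keeping the failed step — would apply an image-norm-sized perturbation in
the first iteration and destroy the image before $\gamma$ decays; a
step-scale multiplier small enough to make kept steps safe (e.g.
$1/N_{\text{pixels}}$) caps the total 20-iteration displacement at
$20/N_{\text{pixels}}$ of the image norm, orders of magnitude below the
noise it must remove.  Both alternatives remain reachable through the
`accept_mode` and `step_scale` parameters.  The weight map is computed
once per slice from the input slice (an optional
`recompute_weights_every` refreshes it); the per-slice objective history,
$\gamma$ path and acceptance flags are returned for inspection.

### Parameters at a glance

| parameter | meaning | default | unit |
|---|---|---|---|
| `a` | patch radius (side $2a+1$) | 2 | px |
| `search_radius` | search half-extent ($21\times21$) | 10 | px |
| `rho` | spatial exponent | 10 | — |
| `tau_percentile` | intensity CDF point for $\tau$ | 90 | % |
| `bins` | joint-histogram side | 128 | — |
| `iterations` | descent steps | 20 | — |
| `gamma0`, `r_red` | step scale and its reduction | 1.0, 0.8 | — |
| `eps` | TV smoothing | $10^{-8}\times$ range | intensity |
| `nlm_h` | NLM bandwidth | 0.002 | mm$^{-1}$ |

Larger `bins` resolves finer intensity structure in $M$ at quadratic cost
(the joint-histogram pass dominates runtime); 64 begins to merge close
tissue classes, 256 doubles the cost for little change — 128 is the
balanced default.

## The synthetic study

`make_catphan_like()` builds a cylindrical water phantom (radius 20 mm,
$\mu_w = 0.02$ mm$^{-1}$) with three axial modules modelled on a CT
quality phantom: a sensitometry ring of seven inserts (Delrin, Teflon,
air, PMP, LDPE, polystyrene, air — nominal attenuations relative to water:
1.36, 1.87, 0, 0.83, 0.92, 0.96, 0), a uniformity module, and a
resolution module with bar groups at 2/3/4/6 lp/cm ($\mu = 2\mu_w$).
Voxelisation is centre-sampled.  `simulate_projections()` applies a
monoenergetic Poisson transmission model: counts
$\sim \mathrm{Poisson}(I_0 e^{-p})$ (optional additive Gaussian
electronic noise), floored at 1 count before the post-log
$\hat p = -\ln(\mathrm{counts}/I_0)$.  Dose enters through $I_0$ alone,
mirroring how mAs scales photon fluence; the default low-dose setting is
$I_0 = 2\times10^4$ with a $16\times$ benchmark (the 0.1 vs 1.6 mAs
ratio).

The desk-scale study conditions used throughout the tests and the
acceptance script are 60 views over $360^\circ$, a $128^2$ detector of
0.8 mm pitch at sad/sdd = 1000/1536 mm, and a $96 \times 96 \times 16$
volume of $0.5 \times 0.5 \times 1.0$ mm$^3$ voxels — the reference
voxel size at a reduced matrix, chosen so the whole chain runs in seconds
per scan on one core.

What the simulator deliberately omits — and hence what passing tests do
*not* demonstrate about scanner data: X-ray scatter (no anti-scatter
device is modelled), beam hardening (monoenergetic model), detector blur,
lag and glare, bowtie filtration, gantry flex, and lateral detector
offsets.  In particular, shading from scatter would add low-frequency
bias that neither the denoiser nor the metrics here are designed to
remove.

## Metrics

`cnr()` is $|\bar{x}_{fg} - \bar{x}_{bg}| / \sigma_{bg}$
(background-only noise; a pooled-SD variant is a flag — the convention is
stated because reference formulations for these phantom metrics differ).
`snu()` is the range of five uniform-ROI means (centre + 4 peripheral) in
percent of 1000 HU.  `nps_2d()` detrends each square ROI by a first-order
polynomial, averages $\Delta x \Delta y / (N_x N_y)\,|\mathrm{DFT}_2|^2$
over the ensemble (e.g. 8 ROIs per slice over consecutive slices), and
reports the map, a radial profile, the peak, and the intensity-weighted
mean frequency.  `mip()`/`minip()` are per-ray extrema.
`linepair_modulation()` reads the bar-minus-gap contrast of a resolution
group off the phantom geometry so the same measure applies before and
after denoising.

## Known limitations

* 2-D patches only; an axial 3-D block extension would cube the search
  volume and is out of scope.
* The denoiser assumes non-negative intensities for its spatial factor;
  strongly negative reconstructions (severe photon starvation) degrade to
  plain weighted TV behaviour there.
* The RDB's quantitative scale factor is exact on the axis and first-order
  accurate off-axis; at the package's geometries the residual is within a
  few percent, which is also the tested tolerance.
* Runtime of the MI weight map grows with
  $(2a+1)^2 (2s+1)^2$ per pixel; the defaults cost a few seconds per
  $96^2$ slice ensemble on one core.
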