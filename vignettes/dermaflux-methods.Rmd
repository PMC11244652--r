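---
title: "Models and methods behind dermaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dermaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermaflux)
```

dermaflux analyses perfusable vascularized skin-on-a-chip experiments: a
printed plexus of ~0.5 mm channels in a GelMA "dermis", perfused with
culture medium, dextran tracers and labelled T cells, imaged by confocal
time-lapse. This vignette explains each model, its assumptions, the
defaults and why they were chosen, and what the synthetic-data tests do and
do not demonstrate about real data.

## Network hemodynamics

`solve_flow()` treats each channel as a Hagen–Poiseuille resistor with
hydraulic conductance $g = \pi d^4 / (128 \mu L)$ and solves the nodal
conservation system with the inlet flow prescribed and the outlet pressure
pinned to zero (only pressure differences are physical). Per-segment wall
shear stress is the Poiseuille value

$$\tau = \frac{32\,\mu\,|Q|}{\pi d^3},$$

reported in dyn/cm² (1 dyn/cm² = 0.1 Pa). The assumptions are laminar,
fully developed flow in channels that are long relative to their diameter —
comfortably satisfied at a few mL/min in 0.5 mm channels (Re ≈ 100,
entrance lengths a few diameters). What the 1D reduction deliberately
ignores: junction losses, local recirculation at T-junctions, and any 3D
velocity-profile detail. Segment-average shear and the relative ordering of
network regions are captured; pointwise shear maps are not.

Defaults: inlet flow 2.4 mL/min (the perfusion rate the devices are run
at) and viscosity 1.0 mPa·s (culture medium is close to water at 37 °C);
both are arguments, and the zone ordering is insensitive to viscosity
because shear scales linearly in $\mu$ everywhere.

### The bundled geometry

The exact CAD of the printed device is not published, so
`default_chip_layout()` is an explicit approximation, not a tracing: a 6 mm
footprint with two innermost horizontal channels (high-shear zone), two
outermost channels (mid-shear), vertical interconnects at four x positions
(low-shear), and inlet/outlet manifold stubs that feed both the inner and
outer channel ends. Feeding the outer channels directly matters: it leaves
the vertical interconnects carrying only the inner↔outer exchange flow,
which is what makes them the low-shear region in the real device. At the
default operating point this layout gives zone mean shears of roughly
1.2 / 7.5 / 8.8 dyn/cm² (low/mid/high) — ordered, spanning about 7×, and
inside the physiological 1–10 dyn/cm² window the device was designed for.
Every dimension can be overridden by passing a layout list or JSON/YAML
file to `build_network()`; `classify_zones()` then either verifies the
ordering implied by the layout's zone hints or splits segments by explicit
shear cutoffs.

## Barrier transport and its closed forms

The permeability assay perfuses fluorescent dextran through the
endothelialized lumen and watches it leak into the gel. The forward model
(`simulate_transport()`) is 2D diffusion in the gel,

$$\frac{\partial C}{\partial t} = D \nabla^2 C,$$

with the lumen held at $C_{\mathrm{lumen}}$ (continuous perfusion
replenishes the dye), a Robin membrane condition
$J = P\,(C_{\mathrm{lumen}} - C_{\mathrm{wall}})$ across the
endothelial barrier, and zero-flux outer boundaries. The plan-view 2D
domain matches the measurement, a confocal-planar mean intensity in a
drawn polygon; fluorescence is assumed proportional to concentration, with
no photobleaching correction.

Discretization choices, in order of how much they matter:

* **Membrane coupling.** The barrier flux into the first gel cell uses the
  series conductance $g_m = (1/P + \Delta x / 2D)^{-1}$ — the membrane in
  series with the half-cell of gel between the wall and the first cell
  center. This places the Robin surface exactly at the lumen/gel face, is
  second-order accurate in practice, and makes the $P \to \infty$
  (acellular, clamped-surface) limit well behaved. A naive $P/\Delta x$
  source is first-order and visibly grid-dependent.
* **Time stepping.** Backward Euler on the 5-point Laplacian, with the
  sparse Cholesky factor built once per step size and reused across steps.
  Implicit stepping is unconditionally stable, so the step (default 5 s
  against 5-minute imaging intervals) is chosen for accuracy alone. An
  explicit FTCS scheme with step bound $0.25\,\Delta x^2/(4D)$ (safety
  factor 0.25 on the stability limit) is kept as `method = "explicit"` and
  agrees with the default to ~10⁻⁴; it exists purely as an internal
  cross-check.
* **Grid.** Default 25 µm spacing on a 3.2 mm window centred on the plexus
  interior (128 × 128 cells). Halving the spacing changes the
  central-polygon trace by well under 1 % RMS, and the zero-flux boundary
  is far enough away that hour-scale transport never feels it at dermal
  dextran diffusivities.

Two closed forms serve as independent oracles. For acellular channels
(no barrier) the semi-infinite constant-surface solution of Fick's second
law applies:
$$C(x,t) = C_0\,\operatorname{erfc}\!\Big(\frac{x}{2\sqrt{Dt}}\Big),$$
and with a barrier the surface-conductance solution with $h = P/D$:
$$C = C_0\Big[\operatorname{erfc}(u) - e^{hx + h^2 D t}
\operatorname{erfc}\big(u + h\sqrt{Dt}\big)\Big], \qquad
u = \tfrac{x}{2\sqrt{Dt}}.$$
The exponential–erfc product overflows catastrophically in the
diffusion-limited regime, so it is evaluated as
$e^{-u^2}\,\mathrm{erfcx}(u + h\sqrt{Dt})$; the scaled complementary error
function itself switches to its asymptotic expansion above $z = 20$, where
the library implementation degenerates. The finite-difference solver
matches both closed forms to < 0.5 % RMS on a 1D strip, and mass balance
(gel mass gained vs. time-integrated membrane flux) holds to machine
precision by construction of the implicit step.

## Inverse estimation of P and D

The estimation mirrors the two-stage experimental analysis. First, gel
diffusivity is fitted from **acellular** devices: `fit_diffusivity()`
minimises the pooled squared residual of the erfc solution against
concentration time-courses at three distances from the vessel boundary.
Second, endothelial permeability is fitted from endothelialized devices
with D held fixed: `fit_permeability()` minimises the sum of squared
residuals between the observed central-polygon trace and the forward
model's trace.

Both fits are bounded scalar minimisations (Brent's golden-section /
parabolic method, `stats::optimize`) on $\log_{10}$ of the parameter, with
default bounds $[10^{-3}, 10^{3}]$ µm/s for P and $[0.1, 10^{4}]$ µm²/s
for D, a relative parameter tolerance of 10⁻³ and a cap of 100 objective
evaluations (typically ~20 are used). Residuals are unweighted, matching a
plain least-squares criterion; a weights hook exists but is off by
default. Each observed trace is fitted separately; replicate devices are
summarised afterwards.

Diagnostics matter more than the point estimate in two regimes. If the
observations are flat (all zeros), the estimate pins at the lower bound
with `converged = FALSE`. If the trace is membrane-insensitive — P so far
above the diffusion-limited regime that halving or doubling it barely
moves the objective — a post-fit probe at $\hat\theta/2$ and $2\hat\theta$
flags a flat objective instead of reporting a spuriously precise number.
Physically this happens when $1/P \ll x/D$: transport is rate-limited by
the gel, and the polygon trace carries little information about the
barrier. At the reported operating point (P ≈ 0.4–0.6 µm/s, D = 16–53
µm²/s, ROI 100–900 µm from the wall) the early frames are still
barrier-sensitive, which is why the 60-minute, 5-minute-cadence design
identifies P.

## Trafficking quantification

`binarize()` rescales each frame to the 8-bit range and thresholds —
Otsu's method by default, since the original workflow's "established
threshold" is not published; a fixed 0–255 cutoff can be supplied and is
recorded in the mask's attributes. `detect_cells()` labels 8-connected
components (implemented in the package; the available library labeller is
4-connected) and filters by a minimum area, default the equivalent of
4 px². Touching cells count as one component — no watershed — matching
plain mask counting.

Retention is a count ratio, not a tracking statistic:
$\mathrm{retention}(t) = 100\,N_{\mathrm{ROI}}(t)/N_{\mathrm{ROI}}(t_0)$
with the baseline frame configurable. A detaching cell and a newly
arriving one trade off invisibly; that is a property of the original
counting workflow, preserved deliberately. Whether the denominator should
be the attached count at baseline or the total number of perfused cells is
ambiguous in interval-counting protocols; the default is the baseline
attached count, and `config$total_cells` switches to a fixed perfused-cell
denominator. `zone_retention()` applies the same statistic per shear-zone
polygon after rejecting any overlapping pair of zones (zero-pixel
tolerance).

Infiltration distance uses the Euclidean distance transform of the vessel
mask, read at each detected centroid. Distances are measured from the
vessel *boundary*: the transform value minus one pixel, so a centroid in
the first gel ring outside the lumen scores 0, and centroids inside the
lumen are excluded from the infiltrated count (they have not
extravasated). The transform agrees with brute-force nearest-vessel-pixel
search to within a pixel diagonal.

## The synthetic-data generators

The generators exist to close the loop: every pipeline output can be
scored against recorded ground truth. Their defaults are the study
conditions, fixed once:

* **Dextran time-lapses** (`gen_dextran_timelapse()`): forward simulation
  per dye with the reported fitted parameters as defaults — 20 kDa:
  D = 16 µm²/s, P = 0.62 µm/s; 40 kDa: D = 53 µm²/s, P = 0.41 µm/s — a
  frame every 5 simulated minutes for 60 minutes, intensity linear in
  concentration, multiplicative Gaussian pixel noise (default sd 5 %;
  a simple but sufficient stand-in for imaging noise).
* **T-cell perfusion** (`gen_tcell_perfusion()`): cells placed uniformly
  on vessel pixels per zone at baseline, independent Bernoulli survival
  per interval with zone-specific probabilities, rendered as 3 px disks
  with σ = 1 px Gaussian blur. Frames at 0, 5 and 10 minutes, the analysis
  points of the perfusion assay. `tcell_survival_scenario()` encodes the
  whole-device scenarios (naïve: 55 % at 5 min, 20 % at 10 min; Th1: 60 %,
  45 %), and the reference per-zone 5-minute survivals are LS 0.8 /
  MS 0.55 / HS 0.45 with a zone-independent second interval — expressing
  the observed early zone dependence that disappears by 10 minutes.
* **Endpoint infiltration** (`gen_infiltration_endpoint()`): per-cell
  migration distances drawn from a half-normal with mean 233 µm
  (epidermis present, 22 cells) or 68 µm (absent, 15 cells). Only the mean
  and maximum of the real distance distribution are reported, so the
  half-normal shape is a declared assumption, pluggable via the
  `distance_model` argument and recorded in the truth. Cells are placed at
  gel pixels whose distance-transform value matches the sampled distance
  to within half a pixel, resampling up to a cap when a distance is not
  representable in the image.

All generators are pure functions of (parameters, seed). What passing
recovery tests on them shows: the inversion, counting and distance
machinery is correct, unbiased under the stated noise models, and
internally consistent end to end. What it does not show: robustness to
uneven illumination, photobleaching, out-of-focus light, touching or
deforming cells, cell motion during exposure, or barrier heterogeneity —
none of which the generators emulate. Noiseless transport recovery in
particular is an inverse-crime design (the generator and the fitted model
share discretization) and validates the optimiser, not model adequacy.

## Numerical and design notes

* Problem sizes: the validation suite runs transport recovery on
  128 × 128 grids (25 µm), noise studies on 64 × 64 grids (50 µm), and
  trafficking statistics on 50-seed ensembles of 300 × 300 px scenes —
  sizes at which every statistic is stable to well inside its test
  tolerance.
* Coordinates: origin top-left, x right, y down, µm everywhere; polygon
  membership is center-in-polygon. Unit conversions live in one utility
  file.
* Normalised-units caveat: the model predicts that with the *reported*
  parameter pairs the 40 kDa central-polygon trace lies *above* the
  20 kDa trace, because the reported 40 kDa gel diffusivity is the larger
  of the two. The observed lower 40 kDa leakage in the source assay
  reflects unequal lumen concentrations and fluorophores, which normalised
  concentration units do not represent. The size-dependence property test
  therefore uses a dye pair in which both D and P decrease with size.
* Degenerate inputs fail loudly and specifically: zero-diameter segments,
  disconnected graphs, self-intersecting polygons, overlapping zones,
  empty vessel masks, constant frames under Otsu, unsorted traces, and
  zero baseline counts all raise classed validation errors that the CLI
  maps to exit code 2.

## Limitations

Junction losses and pulsatility are outside the flow model; advection in
the gel, solute binding and 3D transport are outside the transport model;
cell identity is not tracked, so retention cannot distinguish detachment
from exchange; and the bundled geometry is an approximation whose absolute
shear values should not be quoted against the original device's FEM
simulation — only the zone structure and magnitudes are comparable.
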