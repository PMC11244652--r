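# dermaflux

Quantitative analysis for perfusable, vascularized skin-on-a-chip devices:
a biopsy-sized GelMA chip with a printed plexus of ~0.5 mm vascular
channels surrounding engineered hair follicles, perfused with medium,
dextran tracers and labelled T cells. dermaflux provides the four
computational stages such experiments need, plus a seeded synthetic-data
generator that makes every stage testable against recorded ground truth:

1. **Network hemodynamics** — steady Hagen–Poiseuille flow on the channel
   graph: per-segment flow, pressure, wall shear stress
   τ = 32 µ|Q| / (π d³), and classification into low/mid/high shear zones.
2. **Barrier transport** — 2D finite-difference diffusion of dextran from
   the perfused lumen across the endothelial barrier into the gel:
   ∂C/∂t = D ∇²C with a Robin membrane flux J = P (C_lumen − C_wall),
   alongside the closed-form oracles C₀ erfc(x / 2√(Dt)) (no barrier) and
   the surface-conductance solution (finite P).
3. **Inverse estimation** — least-squares recovery of gel diffusivity D
   (µm²/s, from acellular devices via the erfc solution at several
   distances) and endothelial permeability P (µm/s, from endothelialized
   devices via the forward model with D fixed), with convergence and
   identifiability diagnostics.
4. **Trafficking quantification** — threshold/binarize T-cell frames,
   count 8-connected components, retention % over time (whole-device and
   per shear zone, 100 · N(t)/N(t₀)), and infiltration distance of each
   extravasated cell from the nearest vessel via the Euclidean distance
   transform.

Intended users: organ-on-chip and immunology labs quantifying endothelial
barrier function and leukocyte trafficking from time-lapse fluorescence
microscopy, without COMSOL or ImageJ in the loop.

## Worked example

Solve the bundled chip geometry at the operating perfusion rate, then
recover permeability from a synthetic noisy dextran time-lapse:

```r
library(dermaflux)

net <- build_network(default_chip_layout())
fs  <- solve_flow(net, inlet_flow_ml_min = 2.4, viscosity_mpas = 1.0)
fs
#> <flow_solution> Q_in = 2.4 mL/min, mu = 1 mPa.s
#>   pressure drop inlet->outlet: 50.5 Pa
#>   low   mid  high
#> 1.174 7.544 8.754
```

The zone means are wall shear stresses in dyn/cm²: the vertical
interconnects sit near 1, the outermost channels near 7.5 and the
innermost channels near 9 — ordered low < mid < high and spanning the
physiological 1–10 dyn/cm² range of cutaneous vessels.

```r
dom <- make_transport_domain(net)        # 128 x 128 plan-view grid, 25 um
gen <- gen_dextran_timelapse(dom, dyes = default_dye_panel()["20kDa"],
                             noise_sd = 0.05, seed = 42)
obs <- stack_roi_trace(gen$stacks[["20kDa"]], dom$rois$central_polygon)
fit <- fit_permeability(obs, dom, D_fixed_um2_s = 16)
fit
#> <fit_result> P_um_s = 0.6198 (sse = 1.418e-07, 20 evaluations, converged)

joint_recovery_report(gen$truth, list(P_20kDa = fit))
#>   parameter truth estimate     rel_error converged
#> 1   P_20kDa  0.62 0.619767 -0.0003758412      TRUE
```

The generator hid a 60-minute leakage stack with true P = 0.62 µm/s and
5 % multiplicative imaging noise; the inversion recovers it to 0.04 %.
Retention works the same way — generate a perfusion time-lapse with
zone-dependent detachment, then count:

```r
sc <- default_tcell_scene(seed = 1)      # LS/MS/HS bands, 30 cells each
zr <- zone_retention(sc$gen$stack, sc$zones)
subset(zr$table, time_min == 5)
#>   time_s time_min count retention_pct zone
#>      300        5    25      83.33333   LS
#>      300        5    19      63.33333   MS
#>      300        5    11      36.66667   HS

relative_decrease(60, 45)
#> [1] 25
```

Retention at 5 minutes is highest in the low-shear zone, as for real
circulating T cells; `relative_decrease()` is the summary statistic used
for retention pairs (60 % → 45 % is a 25 % decrease).

## Command line

A thin wrapper over the same functions lives at `inst/cli/dermaflux.R`
(after installation: `system.file("cli", "dermaflux.R", package = "dermaflux")`):

```sh
Rscript dermaflux.R hemodynamics --geometry default --flow-ml-min 2.4 --out shear.csv
Rscript dermaflux.R synth --scenario tcell --seed 5 --noise-sd 0 --out scene/
Rscript dermaflux.R quantify-retention --stack scene/tcell_stack.tif \
        --rois scene/zones.json --out retention.csv
Rscript dermaflux.R fit-permeability --trace trace.csv --diffusivity 16 --out fit.json
```

Stages: `hemodynamics`, `simulate-transport`, `fit-permeability`,
`fit-diffusivity`, `quantify-retention`, `quantify-infiltration`, `synth`.
Every run writes a provenance JSON (parameters, seed, version); validation
errors exit 2, runtime errors exit 1. Image stacks are float32 multi-frame
TIFFs with a JSON sidecar (`timestamps_s`, `pixel_size_um`, `origin_um`,
`channel`); ROIs are JSON polygons in µm.

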