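# pcmrca

Time-resolved phase-contrast MR cardioangiography from 4D Flow CMR data.

4D Flow CMR measures, at every timeframe of the cardiac cycle, a signal
magnitude volume *M(t)* and three-directional blood velocity volumes
*V(t)* (cm/s, bounded by the velocity encoding limit, VENC). Angiograms
are classically derived by averaging over the cycle,

    PCMRA1 = 1/N Σt M²(t) · √(Vx² + Vy² + Vz²)
    PCMRA2 = √( 1/N Σt M²(t) · (Vx² + Vy² + Vz²) )

which smears every moving structure across its range of motion and
leaves the heart chambers — where flow is fast only transiently — faint.
`pcmrca` instead builds a **4D PC-MRCA**: a gamma-corrected angiogram per
timeframe,

    PCMRA(t) = M(t) · (Vx²(t) + Vy²(t) + Vz²(t))^γ,   γ = 0.2,

non-rigid registration of every timeframe onto a quiescent (diastasis)
reference, fusion by a voxelwise **maximum over time**, and warping of the
fused angiogram back to every timeframe. Each output frame shows the full
blood pool — chambers included — in that frame's geometry.

The package is aimed at researchers working with 4D Flow CMR who need
angiographic overviews, motion-faithful blood-pool outlines, or inputs to
downstream segmentation. It provides:

* the three angiogram formulas (`pcmra_eq1`, `pcmra_eq2`, `pcmra_frame`);
* noise suppression by magnitude (10% of global max) and velocity
  (1.5 × VENC) thresholds (`suppress_noise`);
* phase-based (Morphon-style) multi-scale non-rigid registration with
  diffeomorphic accumulation and fluid/elastic regularization
  (`register`, `warp_volume`, `compose_fields`,
  `inverse_consistency_error`);
* the five-step pipeline (`build_mrca`, `select_reference_frame`);
* a digital beating-heart phantom with exact analytic ground-truth motion
  (`generate_phantom`, `truth_endpoint_error`);
* rendering: rotating maximum intensity projections and marching-
  tetrahedra isosurfaces with STL/OBJ/PNG export (`mip_project`,
  `mip_series`, `isosurface`);
* NIfTI + YAML-sidecar I/O and a command-line interface
  (`inst/cli/pcmrca.R`, subcommands `phantom | pcmra | mrca | render`).

## Worked example

Generate a small phantom, preprocess, and build the 4D PC-MRCA:

```r
library(pcmrca)

cfg <- phantom_config(grid = 32, n_frames = 6, diastasis_frame = 5,
                      chamber_axes = c(5, 4.5, 4), shell_thickness = 1.5,
                      vessel_offset = c(26.5, 26.5), vessel_radius = 2,
                      vessel_wall_thickness = 1, vessel_bend = 2,
                      noise_seed = 1)
phantom <- generate_phantom(cfg)
phantom$dataset
#> 4D Flow CMR dataset: 32 x 32 x 32 voxels, 6 timeframes
#>   venc: 120 cm/s; spacing: 2.7 x 2.7 x 2.7 mm; temporal resolution: 52.8 ms
#>   magnitude range: [1.903e-07, 1]; max speed: 362 cm/s

prep <- suppress_noise(normalize_magnitude(phantom$dataset))
prep$velocity_mask
#> Suppression mask: 195845 voxels kept of 196608 (0 by magnitude rule, 763 by velocity rule)

ref <- select_reference_frame(prep$dataset, "auto")
ref
#> [1] 5

mrca <- build_mrca(prep$dataset, ref, keep_fields = TRUE)
mrca
#> 4D PC-MRCA: 32 x 32 x 32 voxels, 6 timeframes
#>   reference frame: 5; gamma: 0.2; fusion: max
```

The max speed of 362 cm/s comes from injected air-noise outliers (the
phantom plants super-VENC velocities in 1% of air voxels); the velocity
rule suppresses them — 763 voxels here — while true lumen flow (≤ 100
cm/s < 1.5 × VENC = 180) survives untouched. Automatic reference
selection recovers the configured diastasis frame (5). Diagnostics
against the phantom's analytic truth:

```r
inverse_consistency_error(prep$dataset$magnitude[, , , 2],
                          mrca$backward[["2"]], mrca$forward[["2"]])
#> [1] 0.000244   # mean squared intensity error of the B/F round trip; max possible is 1

truth_endpoint_error(mrca$backward[["2"]], phantom$truth$fields[[2]],
                     !phantom$truth$air_mask[, , , 2])
#> [1] 0.090      # mean registration error vs analytic truth, voxels
```

Render a rotating MIP stack or an isosurface mesh:

```r
stack <- mip_series(mrca, projection_spec(n_angles = 36))   # 36 angles/frame
mesh  <- isosurface(mrca$fused, default_iso_level(mrca$fused))
write_stl(mesh, "blood_pool.stl")
```

The same pipeline runs from the shell via YAML configs:

```sh
Rscript inst/cli/pcmrca.R phantom --config phantom.yaml
Rscript inst/cli/pcmrca.R mrca    --config mrca.yaml
Rscript inst/cli/pcmrca.R render  --config render.yaml
```

`mrca` writes the 4D PC-MRCA, the fused 3D volume, both classical
PC-MRAs, and a JSON-lines run log with per-stage timings, suppression
counts and per-frame inverse-consistency errors.

## Documentation

The methods vignette (`vignettes/pcmrca-methods.Rmd`) describes the
model and its assumptions, the registration algorithm and its
parameters, what the phantom does and does not emulate, numerical edge
cases, and known limitations.
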