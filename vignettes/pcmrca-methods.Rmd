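---
title: "Time-resolved phase-contrast cardioangiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved phase-contrast cardioangiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

4D Flow CMR acquires, for every timeframe of the cardiac cycle, a signal
magnitude volume $M(t)$ and three velocity component volumes
$V_x(t), V_y(t), V_z(t)$ (cm/s, bounded by the velocity encoding limit,
VENC). Angiographic images are routinely derived from such data by
combining magnitude and velocity, but the classical constructions average
over the cycle:

$$\mathrm{PCMRA}_1 = \frac{1}{N}\sum_{t=1}^{N} M^2(t)\,
  \sqrt{V_x^2(t)+V_y^2(t)+V_z^2(t)},$$
$$\mathrm{PCMRA}_2 = \sqrt{\frac{1}{N}\sum_{t=1}^{N} M^2(t)\,
  \big(V_x^2(t)+V_y^2(t)+V_z^2(t)\big)}.$$

Averaging has two costs. Moving structures (chamber walls, the aortic
root) are smeared across their range of motion, and the heart chambers —
where flow is fast only transiently — end up faint next to arteries with
sustained high flow.

`pcmrca` implements the alternative: build one angiogram **per timeframe**,

$$\mathrm{PCMRA}(t) = M(t)\,\big(V_x^2(t)+V_y^2(t)+V_z^2(t)\big)^{\gamma},
\qquad \gamma = 0.2,$$

non-rigidly align all timeframes to a quiescent (diastasis) reference,
fuse them by a voxelwise maximum over time, and warp the fused volume back
to every timeframe. The result is a time-resolved cardioangiography (4D
PC-MRCA): every frame shows the full cardiovascular blood pool, in that
frame's geometry.

The $\gamma$ power compresses the dynamic range of the squared speed so
that slow intra-chamber flow still registers next to arterial jets; at
$\gamma = 0.5$ the formula degenerates to $M\,\lVert V\rVert$. Two caveats
are deliberate and documented rather than hidden: velocities enter in cm/s
exactly as stored, and a power law is not scale-free, so changing velocity
units rescales the relative weight of slow and fast flow; and the fused
maximum is taken over *registered* angiograms, so its quality is bounded
by registration quality.

## Pipeline

`build_mrca()` runs five steps on a validated, magnitude-normalized,
noise-suppressed `flow_dataset`:

1. per-frame angiograms `pcmra_frame(ds, t, gamma = 0.2)`;
2. backward registration `B_t`: every magnitude frame (moving) onto the
   reference magnitude frame (fixed);
3. warping of each angiogram into reference geometry by its `B_t`;
4. temporal fusion, voxelwise `max` (default) or `mean` — the maximum
   preserves chamber visibility, the mean is gentler on noisy input;
5. forward registration `F_t` (reference onto every frame) and warping of
   the fused volume to each timeframe. The reference frame of the output
   is the fused volume itself, bit-identical.

The forward pass is a genuine second registration, not an inversion of
`B_t`; deriving `F_t` from `B_t` would halve the cost but is kept out of
the reference behavior (the forward/backward pair also powers the
inverse-consistency diagnostic below).

### Preprocessing

Air dominates a thoracic field of view, and phase noise in air produces
spurious angiographic signal. Two rules zero the *velocity* (never the
magnitude) of suspect voxels:

* magnitude below 10% of the global (all-frame) magnitude maximum;
* any velocity component with $|V_i| > 1.5\times$ VENC (strict
  inequality; the boundary survives). A `speed` mode comparing
  $\lVert V\rVert$ is available; per-component is the default because
  each component is encoded, and wraps manifest, per component.

Zeroing velocity rather than deleting voxels keeps array shapes stable
for registration. Both rules are monotone in their thresholds and
idempotent. The magnitude rule removes most of the volume (nearly all air
— about 94% of the default phantom); the velocity rule removes a small
scattered fraction (well under 1%), which is the number worth watching:
those are voxels bright enough to pass the magnitude gate yet carrying
nonsense velocities.

Magnitude normalization divides by a single global maximum (not
per-frame), preserving relative frame brightness. Phase unwrapping and
polynomial background-phase correction are assumed done upstream by the
scanner/recon pipeline and are out of scope.

## Registration

`register(fixed, moving)` is a phase-based (Morphon-style) multi-scale
non-rigid registration returning a dense displacement field `B` such that
`moving` sampled at $x + B(x)$ approximates `fixed`.

* **Filter bank.** Six complex log-normal quadrature filters (center
  frequency $\pi/3$ rad/voxel, bandwidth 2 octaves, spatial support
  $9^3$) along icosahedral-symmetric orientations. The local phase of a
  filter response shifts linearly with displacement along the filter
  orientation; the phase difference between fixed and moving responses,
  divided by the local spatial frequency (estimated from the phase
  gradient of the fixed response, clamped to $[0.25, 2.5]\times$ the
  center frequency), gives a displacement observation per orientation.
* **Certainty-weighted solve.** Each voxel solves a weighted least-squares
  $3\times 3$ system over the six orientation observations with certainty
  $c_k = |q_f \bar q_m| \cos^2(\Delta\phi_k/2)$ — the product of response
  magnitudes, damped where phases disagree outright. A ridge of
  $10^{-3}\times$ the local trace keeps ill-conditioned voxels stable, and
  update norms are capped at half the filter wavelength (3 voxels), the
  unambiguous range of a phase difference.
* **Fluid and elastic regularization.** The incremental update is smoothed
  by a Gaussian of $\sigma_\text{fluid} = 1.5$ voxels; after diffeomorphic
  accumulation (composition of the increment with the running field,
  `compose(field, inc)(x) = inc(x) + field(x + inc(x))`) the accumulated
  field is smoothed by $\sigma_\text{elastic} = 1.5$ voxels. Both
  smoothings are *normalized convolutions* weighted by certainty, so
  structureless regions (air, lumen interior) inherit displacement from
  informative neighbors instead of dragging estimates toward zero.
* **Scales.** Two octaves, three iterations each, coarse-to-fine;
  downsampling by 2 with Gaussian anti-aliasing, field upsampling by
  linear interpolation with doubled vectors. Defaults (2 scales, 3
  iterations, $\sigma = 1.5$) are the tuned settings for cardiac
  magnitude series; all are exposed via `registration_params()`.
* **Determinism and degeneracy.** The algorithm is free of randomness;
  identical inputs give bit-identical fields. Constant images
  short-circuit to a zero field with a warning. Self-registration returns
  an exactly zero field (all phase differences vanish identically).

Border policy for warping is replicate-nearest, so temporal MIPs do not
acquire dark halos at the volume edge — the caval veins sitting at the
image border are the classic failure mode of this pipeline, and zero
padding would make it worse.

Diffeomorphism is monitored, not assumed: `jacobian_positive_fraction()`
evaluates $\det(I + \nabla u)$ by central differences; pipeline fields are
expected positive on $\ge 99\%$ of interior voxels (in practice: 100% on
the phantom suite).

### Inverse consistency

`inverse_consistency_error(image, B_t, F_t)` warps a $[0,1]$-normalized
magnitude frame by the backward then the forward field and reports the
mean per-voxel squared difference from the original over an interior mask
(4-voxel margin; replicate-border samples carry no information). On this
scale the maximum possible error is 1. On the default phantom the
per-frame error stays below $10^{-3}$; the packaged test suite asserts
exactly that, and `scripts/acceptance.R` reports the measured values
(about $2\times 10^{-4}$ on average).

## The digital phantom

No public 4D Flow CMR datasets accompany this method, so validation rests
on `generate_phantom()`: a beating ellipsoidal chamber plus a curved
vessel, with analytic ground truth. Acquisition defaults mirror a typical
clinical protocol — 2.7 mm isotropic voxels, 20 timeframes at 52.8 ms,
VENC 120 cm/s, grid $48^3$.

* **Chamber.** An ellipsoid (semi-axes 8, 7, 6 voxels) inside a
  myocardial shell, contracting by uniform radial scaling about its
  center: displacement $u_t(x) = -A(t)\,(x - c)$ over the whole anatomy,
  with $A(t) = a \sin^4(\pi\,\tau_t)$, $a = 0.25$, and $\tau_t$ the cycle
  phase measured from the diastasis frame. Pure scaling makes the true
  deformation exact, linear, and diffeomorphic by construction; the
  $\sin^4$ envelope gives a fast systole and a long flat diastasis, so
  the stillness-based automatic reference selection has a unique optimum
  (a raised-cosine cycle has two equally still phases — full contraction
  is as motionless as diastasis). The field tapers smoothly to zero in
  the air gap strictly before the vessel begins, so the vessel is exactly
  static in both image and truth.
* **Vessel.** A tube (radius 3 voxels) running through the volume with a
  straight mid-segment and quadratically bowed ends, carrying pulsatile
  through-plane flow along the centerline tangent. The radial profile is
  blunted ($1 - (d/R)^4$ rather than parabolic) so the discrete-grid
  maximum provably reaches the configured peak speed (100 cm/s) within
  2% wherever the centerline falls relative to voxel centers; the
  straight segment passes exactly through voxel centers, pinning the peak.
  A parabolic profile remains available via the config.
* **Flow and tissue velocity.** Tissue moves with the analytic time
  derivative of the wall displacement; intra-chamber flow is a radial
  filling/ejection pattern peaking at 25 cm/s, synchronized with wall
  motion. All speeds stay below $1.5\times$ VENC so no true voxel is
  ever suppressed.
* **Noise.** Air magnitude is $|\mathcal N(0, 0.02)|$ against blood at
  1.0 and tissue at 0.3. Air velocity carries Gaussian noise (12 cm/s)
  plus, in 1% of air voxels, uniform outliers up to $1.8\times$ VENC —
  giving both suppression rules real work. Edges are smoothed over about
  one voxel so images are band-limited. All randomness derives from
  `noise_seed`; generation is bit-reproducible.

**What the phantom does not emulate** — and hence what passing tests do
not show about clinical data: MR acquisition physics (k-space sampling,
partial volume, eddy currents, aliasing), trabeculated or valve anatomy,
breathing drift, jet-flow signal voids, and contrast-agent effects.
Registration accuracy on the phantom (mean endpoint error ≈ 0.07 voxels)
is an upper bound of sorts: real myocardium has texture the phantom
lacks, but real data also break the phantom's exact intensity constancy
across frames.

## Numerical choices and edge cases

* Voxel indices are 1-based (R convention); world coordinates are
  `(index - 1) * spacing` mm. No orientation-matrix support: NIfTI
  affines are not interpreted.
* NIfTI volumes are stored as float32; round trips are exact to
  single-precision rounding. Sidecar metadata (YAML) carries VENC,
  spacing and temporal resolution; header spacing wins over the sidecar
  on conflict, with a warning.
* A single-frame dataset is accepted: fusion degenerates to that frame's
  angiogram. Empty fusion inputs, missing fields, and shape mismatches
  are structured errors naming both shapes.
* Reference selection (`auto`) minimizes the mean absolute magnitude
  difference to both temporal neighbors (cyclically — the cardiac cycle
  is periodic) over the central half of the volume; ties break to the
  lowest index.
* Isosurfaces are extracted by marching tetrahedra (six tetrahedra per
  cell around the main diagonal): every sign configuration is
  unambiguous, the mesh is watertight for surfaces closed inside the
  grid, and extraction is deterministic. On a smooth signed-distance
  sphere the mesh area matches $4\pi R^2$ within 0.5%. On *binary*
  indicator volumes any linear-interpolation extractor produces the
  midpoint surface, whose faceting overestimates a sphere's area by
  roughly 30% — area statements therefore assume smooth input. The
  default iso-level is half the 99.5th intensity percentile; figures in
  the source publication domain never state theirs, so it is an explicit
  parameter.
* Rotating MIPs resample the volume (not the rays) about the chosen axis
  with zero fill, so rotated corners never outshine anatomy; projection
  is taken along the next axis cyclically.

## Design decisions on genuinely open points

* **Eq. 3 reading.** The printed per-frame formula is typographically
  garbled; it is implemented as $M(t)\,(V_x^2+V_y^2+V_z^2)^\gamma$, the
  only reading symmetric in the components and consistent with the
  stated purpose of $\gamma$.
* **Normalized magnitude into Eq. 3.** The pipeline normalizes magnitude
  before angiogram computation (consistent with the $[0,1]$ convention
  of the inverse-consistency analysis); a flag exposes the raw-magnitude
  variant.
* **Per-component velocity thresholding** is the default (see above);
  `speed` mode is one switch away.
* **Intensity-scale comparisons across formulas.** $\mathrm{PCMRA}(t)$
  compresses speed ($\propto s^{0.4}$); $\mathrm{PCMRA}_2$ is linear in
  speed. Their absolute intensities are incommensurate — with chamber
  flow at 25 cm/s versus vascular flow at 100 cm/s the chamber rim sits
  at $(25/100)^{0.4} \approx 0.57$ of the fused volume's maximum, while
  in the time-average it sits near 0.16. Visibility comparisons in the
  tests and acceptance script therefore normalize each volume to unit
  maximum first, and threshold-overlap comparisons use a 30%-of-maximum
  cut: a half-maximum cut would select almost no chamber voxels from
  *either* volume under these flow speeds and discriminate nothing.
* **Scale count and accuracy.** Multi-scale estimation earns its keep
  when displacements exceed the phase-unambiguous range of the fine
  scale (3 voxels here). On the default phantom (max ≈ 2.6 voxels) the
  coarse scale is nearly neutral: aggregate accuracy with 2 scales is
  slightly better than with 1, but on near-still frames both sit at a
  ~0.01–0.02 voxel noise floor set by air-noise realizations, where
  per-frame orderings are not meaningful.

## Problem sizes and runtime

The test suite validates formulas on $8^3\times 3$ random datasets
against brute-force voxel loops (relative error $<10^{-12}$), unit
behavior on $16^3$–$32^3$ volumes, and the full pipeline on the default
$48^3\times 20$ phantom (two registration passes, 38 registrations,
about two minutes on one CPU). `scripts/acceptance.R` re-runs the full
default-phantom pipeline from scratch in about one minute.

## Known limitations

* No orientation/oblique-slab handling; data must share a voxel grid.
* Registration quality degrades for structures at the volume border
  (replicate border) and for displacements far beyond the coarse scale's
  unambiguous range (≈ 6 voxels).
* The fused maximum propagates any residual velocity noise that survives
  suppression; the `mean` fusion mode trades chamber brightness for
  noise robustness.
* Jet-flow signal voids, pathology geometries and contrast-agent effects
  are outside the phantom's vocabulary; conclusions about them require
  real data.
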