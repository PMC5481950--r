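#' Phantom configuration
#'
#' Parameters of the synthetic 4D Flow CMR phantom: a beating ellipsoidal
#' chamber (uniform radial contraction about its center, zero displacement at
#' the diastasis frame) plus a curved vessel with pulsatile through-plane
#' flow, embedded in air noise. Acquisition defaults mirror a typical
#' clinical protocol: 2.7 mm isotropic voxels, 20 timeframes at 52.8 ms, and
#' a velocity encoding limit of 120 cm/s.
#'
#' @param grid spatial dimensions (length 3 or scalar), voxels.
#' @param n_frames number of cardiac timeframes.
#' @param spacing_mm isotropic voxel size, mm.
#' @param venc_cms velocity encoding limit, cm/s.
#' @param temporal_resolution_ms time between frames, ms.
#' @param chamber_center chamber center, voxels (default grid center).
#' @param chamber_axes ellipsoid semi-axes, voxels.
#' @param shell_thickness myocardial shell thickness, voxels.
#' @param contraction_amplitude peak fractional radius decrease over the
#'   cycle, in `[0, 0.5)`.
#' @param diastasis_frame frame index (1-based) at which chamber motion is
#'   exactly zero.
#' @param vessel_offset centerline position `(x0, z0)` of the vessel (runs
#'   along y), voxels.
#' @param vessel_radius lumen radius, voxels.
#' @param vessel_wall_thickness vessel wall thickness, voxels.
#' @param vessel_bend lateral bow (in x) of the centerline at the volume
#'   ends, voxels; the mid-segment is straight.
#' @param vessel_profile radial flow profile: `"blunt"` (quartic, default) or
#'   `"parabolic"`.
#' @param peak_vessel_speed_cms peak through-plane speed in the vessel, cm/s.
#' @param peak_chamber_speed_cms peak intra-chamber flow speed, cm/s.
#' @param tissue_magnitude,blood_magnitude signal levels of tissue and blood.
#' @param air_noise_sigma Gaussian sigma of air magnitude noise.
#' @param air_velocity_noise_sigma_cms Gaussian sigma of regular air velocity
#'   noise, cm/s.
#' @param air_outlier_fraction fraction of air voxels given super-threshold
#'   velocity outliers (uniform up to 1.8 x venc), to exercise suppression.
#' @param noise_seed integer seed driving all phantom randomness.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(48L, 48L, 48L),
                           n_frames = 20L,
                           spacing_mm = 2.7,
                           venc_cms = 120,
                           temporal_resolution_ms = 52.8,
                           chamber_center = NULL,
                           chamber_axes = c(8, 7, 6),
                           shell_thickness = 2.5,
                           contraction_amplitude = 0.25,
                           diastasis_frame = 15L,
                           vessel_offset = c(40, 38),
                           vessel_radius = 3,
                           vessel_wall_thickness = 1.5,
                           vessel_bend = 4,
                           vessel_profile = c("blunt", "parabolic"),
                           peak_vessel_speed_cms = 100,
                           peak_chamber_speed_cms = 25,
                           tissue_magnitude = 0.3,
                           blood_magnitude = 1.0,
                           air_noise_sigma = 0.02,
                           air_velocity_noise_sigma_cms = 12,
                           air_outlier_fraction = 0.01,
                           noise_seed = 42L) {
  if (length(grid) == 1L) grid <- rep(grid, 3L)
  if (is.null(chamber_center)) chamber_center <- (grid + 1) / 2
  cfg <- list(grid = as.integer(grid), n_frames = as.integer(n_frames),
              spacing_mm = spacing_mm, venc_cms = venc_cms,
              temporal_resolution_ms = temporal_resolution_ms,
              chamber_center = chamber_center, chamber_axes = chamber_axes,
              shell_thickness = shell_thickness,
              contraction_amplitude = contraction_amplitude,
              diastasis_frame = as.integer(diastasis_frame),
              vessel_offset = vessel_offset, vessel_radius = vessel_radius,
              vessel_wall_thickness = vessel_wall_thickness,
              vessel_bend = vessel_bend,
              vessel_profile = match.arg(vessel_profile),
              peak_vessel_speed_cms = peak_vessel_speed_cms,
              peak_chamber_speed_cms = peak_chamber_speed_cms,
              tissue_magnitude = tissue_magnitude,
              blood_magnitude = blood_magnitude,
              air_noise_sigma = air_noise_sigma,
              air_velocity_noise_sigma_cms = air_velocity_noise_sigma_cms,
              air_outlier_fraction = air_outlier_fraction,
              noise_seed = as.integer(noise_seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$contraction_amplitude < 0 || cfg$contraction_amplitude >= 0.5)
    stop("contraction_amplitude must lie in [0, 0.5)", call. = FALSE)
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (cfg$diastasis_frame < 1L || cfg$diastasis_frame > cfg$n_frames)
    stop("diastasis_frame out of range", call. = FALSE)
  if (max(cfg$peak_vessel_speed_cms, cfg$peak_chamber_speed_cms) >=
      1.5 * cfg$venc_cms)
    stop("peak speeds must stay below 1.5 x venc or true flow would be ",
         "suppressed as noise", call. = FALSE)
  if (cfg$venc_cms <= 0 || cfg$spacing_mm <= 0)
    stop("venc and spacing must be positive", call. = FALSE)
  invisible(cfg)
}

# Chamber motion envelope: fraction of full contraction at each frame.
# sin^4 of cycle phase measured from the diastasis frame: exactly zero (with
# zero slope and curvature) at diastasis, single sharp peak mid-cycle --
# a fast-systole / long-quiescent-diastole cycle with an unambiguous
# stillness minimum.
contraction_envelope <- function(n_frames, diastasis_frame) {
  frac <- ((seq_len(n_frames) - diastasis_frame) %% n_frames) / n_frames
  sin(pi * frac)^4
}

# Vessel pulse: baseline + systolic surge, maximum exactly 1 mid-cycle.
vessel_pulse <- function(n_frames, diastasis_frame) {
  frac <- ((seq_len(n_frames) - diastasis_frame) %% n_frames) / n_frames
  0.1 + 0.9 * sin(pi * frac)^2
}

# smoothstep on [0, 1]
sstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Vessel centerline x-offset as a function of y (0 on the straight
# mid-segment, quadratic bow toward the volume ends), plus its derivative.
vessel_centerline <- function(y, ny, bend) {
  y1 <- 0.38 * ny; y2 <- 0.62 * ny
  off <- numeric(length(y)); doff <- numeric(length(y))
  lo <- y < y1; hi <- y > y2
  off[lo] <- bend * ((y1 - y[lo]) / y1)^2
  doff[lo] <- -2 * bend * (y1 - y[lo]) / y1^2
  off[hi] <- bend * ((y[hi] - y2) / (ny - y2))^2
  doff[hi] <- 2 * bend * (y[hi] - y2) / (ny - y2)^2
  list(offset = off, slope = doff)
}

#' Generate a synthetic 4D Flow CMR dataset with ground truth
#'
#' Builds the phantom described by a [phantom_config()]: magnitude and
#' three-directional velocity volumes for every timeframe, plus the exact
#' analytic deformation of every frame relative to the diastasis frame and
#' per-frame region masks. The chamber contracts by uniform radial scaling
#' about its center (so the true deformation is linear in the offset from the
#' center over the whole anatomy and diffeomorphic by construction); the
#' vessel is geometrically static with pulsatile through-plane flow. Edges
#' are smoothed over roughly one voxel so the images are band-limited. All
#' randomness (air noise, velocity outliers) derives from `noise_seed`; the
#' same configuration always yields bit-identical output.
#'
#' @param config a `phantom_config`.
#' @return A list with elements `dataset` (a [flow_dataset()]) and `truth`
#'   (class `phantom_truth`: per-frame `fields` (analytic
#'   [displacement_field()]s mapping reference coordinates into each frame),
#'   logical mask arrays `chamber_mask`, `vessel_mask`, `air_mask`
#'   `[X, Y, Z, N]`, an `outlier_mask` marking injected velocity outliers,
#'   and `reference_frame`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  cfg <- config
  d <- cfg$grid
  n <- cfg$n_frames
  g <- coord_grids(d)
  ctr <- cfg$chamber_center
  ax <- cfg$chamber_axes
  edge <- 0.6                      # half-width of smoothed edges, voxels

  # generalized (ellipsoidal) radii at reference size
  rho_lumen <- sqrt(((g$x - ctr[1L]) / ax[1L])^2 +
                      ((g$y - ctr[2L]) / ax[2L])^2 +
                      ((g$z - ctr[3L]) / ax[3L])^2)
  ax_out <- ax + cfg$shell_thickness
  rho_shell <- sqrt(((g$x - ctr[1L]) / ax_out[1L])^2 +
                      ((g$y - ctr[2L]) / ax_out[2L])^2 +
                      ((g$z - ctr[3L]) / ax_out[3L])^2)
  # edge half-width in generalized-radius units
  w_lum <- edge / mean(ax); w_sh <- edge / mean(ax_out)

  # vessel geometry (static): distance to centerline in the x-z cross-section
  vc <- vessel_centerline(g$y, d[2L], cfg$vessel_bend)
  dx <- g$x - (cfg$vessel_offset[1L] + vc$offset)
  dz <- g$z - cfg$vessel_offset[2L]
  dist_v <- sqrt(dx^2 + dz^2)
  slope <- vc$slope
  tang_norm <- sqrt(1 + slope^2)
  V_lum <- sstep((cfg$vessel_radius - dist_v) / edge / 2 + 0.5)
  V_wall <- sstep((cfg$vessel_radius + cfg$vessel_wall_thickness - dist_v) /
                    edge / 2 + 0.5)
  vessel_mask3 <- dist_v <= cfg$vessel_radius - edge
  prof <- if (cfg$vessel_profile == "blunt")
    pmax(0, 1 - (dist_v / cfg$vessel_radius)^4)
  else pmax(0, 1 - (dist_v / cfg$vessel_radius)^2)

  amp <- cfg$contraction_amplitude * contraction_envelope(n, cfg$diastasis_frame)
  pulse <- vessel_pulse(n, cfg$diastasis_frame)
  # intra-chamber flow envelope: proportional to the rate of wall motion,
  # normalized to peak 1 over the cycle (central difference on the cycle)
  env <- contraction_envelope(n, cfg$diastasis_frame)
  denv <- (env[c(2:n, 1L)] - env[c(n, 1:(n - 1L))]) / 2
  if (max(abs(denv)) > 0) denv <- denv / max(abs(denv))

  voxel_cm <- cfg$spacing_mm / 10

  mag <- array(0, dim = c(d, n))
  vel <- array(0, dim = c(d, 3L, n))
  chamber_mask <- vessel_mask <- air_mask <- array(FALSE, dim = c(d, n))
  outlier_mask <- array(FALSE, dim = c(d, n))
  fields <- vector("list", n)

  rx <- g$x - ctr[1L]; ry <- g$y - ctr[2L]; rz <- g$z - ctr[3L]
  r_eucl <- sqrt(rx^2 + ry^2 + rz^2)
  max_anat_r <- max(ax_out) + 2 * edge
  # taper of the true displacement field: pure scaling over the whole
  # anatomy (so the truth is exact there), smooth decay to zero strictly
  # before the static vessel begins
  R0 <- max_anat_r + 0.5
  dmin_vessel <- if (any(V_wall > 0.005)) min(r_eucl[V_wall > 0.005]) else Inf
  R1 <- max(min(dmin_vessel - 0.5, min(d) / 2 - 1), R0 + 1)
  if (cfg$contraction_amplitude > 0 && R1 > dmin_vessel)
    warning("chamber motion taper reaches the vessel; ground-truth field ",
            "is approximate near the vessel wall", call. = FALSE)
  wtaper <- array(1, dim = d)
  tz <- r_eucl > R0
  wtaper[tz] <- cos(pmin((r_eucl[tz] - R0) / (R1 - R0), 1) * pi / 2)^2

  with_seed(cfg$noise_seed, {
    for (t in seq_len(n)) {
      s <- 1 - amp[t]                     # uniform scale factor this frame
      L <- sstep((1 - rho_lumen / s) / w_lum / 2 + 0.5)
      O <- sstep((1 - rho_shell / s) / w_sh / 2 + 0.5)
      body <- pmax(O, V_wall)

      air_noise <- abs(array(rnorm(prod(d), 0, cfg$air_noise_sigma), dim = d))
      m <- cfg$tissue_magnitude * O +
        (cfg$blood_magnitude - cfg$tissue_magnitude) * L +
        cfg$tissue_magnitude * V_wall * (1 - O) +
        (cfg$blood_magnitude - cfg$tissue_magnitude) * V_lum * (1 - O) +
        air_noise * (1 - body)
      mag[, , , t] <- m

      # wall/tissue motion velocity: time derivative of the displacement
      damp_dt <- cfg$contraction_amplitude *
        (env[ifelse(t == n, 1L, t + 1L)] - env[ifelse(t == 1L, n, t - 1L)]) /
        2 / (cfg$temporal_resolution_ms / 1000)   # fraction per second
      vmx <- -damp_dt * rx * voxel_cm              # cm/s
      vmy <- -damp_dt * ry * voxel_cm
      vmz <- -damp_dt * rz * voxel_cm

      # intra-chamber filling/ejection flow, radial, peak speed at the wall
      ch_sp <- cfg$peak_chamber_speed_cms * denv[t]
      rmax <- max(ax) * 0.99
      vcx <- ch_sp * (rx / rmax); vcy <- ch_sp * (ry / rmax)
      vcz <- ch_sp * (rz / rmax)
      cap <- pmax(1, sqrt(vcx^2 + vcy^2 + vcz^2) /
                    max(cfg$peak_chamber_speed_cms, 1e-12))
      vcx <- vcx / cap; vcy <- vcy / cap; vcz <- vcz / cap

      # vessel through-plane flow along the centerline tangent
      vsp <- cfg$peak_vessel_speed_cms * pulse[t] * prof
      vvx <- vsp * slope / tang_norm
      vvy <- vsp / tang_norm
      vvz <- 0

      air_w <- 1 - pmax(body, V_lum)
      nv <- prod(d)
      anx <- rnorm(nv, 0, cfg$air_velocity_noise_sigma_cms)
      any_ <- rnorm(nv, 0, cfg$air_velocity_noise_sigma_cms)
      anz <- rnorm(nv, 0, cfg$air_velocity_noise_sigma_cms)

      vx <- (vmx + vcx * L) * O + vvx * V_lum + anx * air_w
      vy <- (vmy + vcy * L) * O + vvy * V_lum + any_ * air_w
      vz <- (vmz + vcz * L) * O + vvz * V_lum + anz * air_w

      # super-threshold outliers in a fraction of true air voxels
      is_air <- body < 0.01 & V_lum < 0.01
      air_idx <- which(is_air)
      n_out <- round(cfg$air_outlier_fraction * length(air_idx))
      if (n_out > 0L) {
        pick <- sample(air_idx, n_out)
        lim <- 1.5 * cfg$venc_cms * 1.2
        vx[pick] <- runif(n_out, -lim, lim)
        vy[pick] <- runif(n_out, -lim, lim)
        vz[pick] <- runif(n_out, -lim, lim)
        om <- array(FALSE, dim = d); om[pick] <- TRUE
        outlier_mask[, , , t] <- om
      }

      vel[, , , 1L, t] <- vx; vel[, , , 2L, t] <- vy; vel[, , , 3L, t] <- vz

      chamber_mask[, , , t] <- rho_lumen / s <= 1 - w_lum
      vessel_mask[, , , t] <- vessel_mask3 & !chamber_mask[, , , t]
      air_mask[, , , t] <- is_air

      # analytic truth: reference coordinates x map to x - amp * (x - c) * w
      fvec <- array(0, dim = c(d, 3L))
      fvec[, , , 1L] <- -amp[t] * rx * wtaper
      fvec[, , , 2L] <- -amp[t] * ry * wtaper
      fvec[, , , 3L] <- -amp[t] * rz * wtaper
      fields[[t]] <- displacement_field(fvec)
    }
  })

  ds <- flow_dataset(mag, vel, venc = cfg$venc_cms,
                     spacing = rep(cfg$spacing_mm, 3L),
                     temporal_resolution = cfg$temporal_resolution_ms,
                     frame_times = (seq_len(n) - 1L) * cfg$temporal_resolution_ms)
  truth <- structure(list(fields = fields,
                          chamber_mask = chamber_mask,
                          vessel_mask = vessel_mask,
                          air_mask = air_mask,
                          outlier_mask = outlier_mask,
                          reference_frame = cfg$diastasis_frame,
                          config = cfg),
                     class = "phantom_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$chamber_mask)
  cat(sprintf(paste0("Phantom ground truth: %d frames, reference frame %d\n",
                     "  chamber %d / vessel %d / air %d voxels per frame ",
                     "(frame %d)\n"),
              d[4L], x$reference_frame,
              sum(x$chamber_mask[, , , 1L]), sum(x$vessel_mask[, , , 1L]),
              sum(x$air_mask[, , , 1L]), 1L))
  invisible(x)
}

#' Mean endpoint error of a displacement field against ground truth
#'
#' Mean Euclidean norm (voxels) of the vector difference between an estimated
#' and a true displacement field over a region mask.
#'
#' @param field estimated `displacement_field`.
#' @param truth_field true `displacement_field` of identical shape.
#' @param mask logical 3D array selecting the voxels to average over.
#' @return Scalar mean endpoint error in voxels.
#' @export
truth_endpoint_error <- function(field, truth_field, mask) {
  if (!all(dim(field$vectors) == dim(truth_field$vectors)))
    stop("field shapes differ", call. = FALSE)
  if (!all(dim(mask) == dim(field$vectors)[1:3]))
    stop("mask shape does not match the fields", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  dv <- field$vectors - truth_field$vectors
  nrm <- sqrt(dv[, , , 1L]^2 + dv[, , , 2L]^2 + dv[, , , 3L]^2)
  mean(nrm[mask])
}

#' Write a phantom (dataset, truth and config) to disk
#'
#' Emits the standard flow-dataset NIfTI layout plus a `truth/` subdirectory
#' with the per-frame deformation fields (4D NIfTI each) and the region masks
#' (uint8 NIfTI), and echoes the configuration as YAML.
#'
#' @param phantom result of [generate_phantom()].
#' @param out_dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, out_dir) {
  paths <- write_flow_dataset(phantom$dataset, out_dir)
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  tr <- phantom$truth
  sp <- phantom$dataset$spacing
  for (t in seq_along(tr$fields))
    paths <- c(paths, write_field_nifti(
      tr$fields[[t]], file.path(tdir, sprintf("deformation_%02d.nii.gz", t)),
      sp))
  for (nm in c("chamber_mask", "vessel_mask", "air_mask")) {
    p <- file.path(tdir, paste0(nm, ".nii.gz"))
    arr <- array(as.integer(tr[[nm]]), dim = dim(tr[[nm]]))
    img <- RNifti::asNifti(arr, datatype = "uint8")
    RNifti::writeNifti(img, p, datatype = "uint8")
    paths <- c(paths, p)
  }
  cfg_path <- file.path(out_dir, "phantom_config.yaml")
  cfg <- tr$config
  cfg$vessel_profile <- as.character(cfg$vessel_profile)
  yaml::write_yaml(unclass(cfg), cfg_path)
  invisible(c(paths, cfg_path))
}
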