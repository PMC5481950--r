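# Shared fixtures: all synthetic, generated at test time.

# A small flow dataset with hand-set values, for exact arithmetic checks.
make_toy_dataset <- function(dims = c(4L, 4L, 4L), n = 3L, venc = 120,
                             seed = 7L, vel_scale = 30) {
  set.seed(seed)
  mag <- array(runif(prod(dims) * n, 0.1, 1), dim = c(dims, n))
  vel <- array(rnorm(prod(dims) * 3 * n, 0, vel_scale),
               dim = c(dims, 3L, n))
  flow_dataset(mag, vel, venc = venc, spacing = c(2.7, 2.7, 2.7),
               temporal_resolution = 50)
}

# Compact phantom geometry that keeps the vessel clear of the chamber
# motion field; used by pipeline/CLI tests where speed matters more than
# realism.
small_phantom_config <- function(noise_seed = 11L, ...) {
  phantom_config(grid = 24L, n_frames = 5L, diastasis_frame = 4L,
                 chamber_axes = c(3.5, 3, 2.5), shell_thickness = 1.2,
                 vessel_offset = c(20, 20), vessel_radius = 1.5,
                 vessel_wall_thickness = 1, vessel_bend = 1.5,
                 contraction_amplitude = 0.2, noise_seed = noise_seed, ...)
}

# Zero-motion, noise-free variant: magnitude frames are bit-identical, so
# registration must return exactly zero fields. Geometry scales with the
# grid so small instances stay self-consistent.
static_phantom_config <- function(grid = 32L, n_frames = 8L,
                                  diastasis_frame = 5L, ...) {
  g <- grid[1L]
  phantom_config(grid = grid, n_frames = n_frames,
                 diastasis_frame = diastasis_frame,
                 chamber_axes = g * c(0.16, 0.14, 0.125),
                 shell_thickness = max(1, 0.047 * g),
                 vessel_offset = c(0.82, 0.82) * g,
                 vessel_radius = max(1.2, 0.0625 * g),
                 vessel_wall_thickness = 1, vessel_bend = 0.05 * g,
                 contraction_amplitude = 0, air_noise_sigma = 0,
                 air_velocity_noise_sigma_cms = 0, air_outlier_fraction = 0,
                 noise_seed = 11L, ...)
}

# Brute-force per-voxel oracles for the three angiogram formulas: plain
# loops, no vectorized shortcuts shared with the implementation.
oracle_pcmra <- function(ds, which, t = NULL, gamma = 0.2) {
  d <- dim(ds$magnitude)[1:3]
  n <- dim(ds$magnitude)[4L]
  out <- array(0, dim = d)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    if (which == "frame") {
      s2 <- ds$velocity[i, j, k, 1L, t]^2 + ds$velocity[i, j, k, 2L, t]^2 +
        ds$velocity[i, j, k, 3L, t]^2
      out[i, j, k] <- ds$magnitude[i, j, k, t] * s2^gamma
    } else {
      acc <- 0
      for (tt in seq_len(n)) {
        s2 <- ds$velocity[i, j, k, 1L, tt]^2 + ds$velocity[i, j, k, 2L, tt]^2 +
          ds$velocity[i, j, k, 3L, tt]^2
        acc <- acc + if (which == "eq1")
          ds$magnitude[i, j, k, tt]^2 * sqrt(s2)
        else ds$magnitude[i, j, k, tt]^2 * s2
      }
      out[i, j, k] <- if (which == "eq1") acc / n else sqrt(acc / n)
    }
  }
  out
}

# Exhaustive enumeration oracle for the suppression rules.
oracle_suppression_counts <- function(ds, fraction = 0.10, factor = 1.5) {
  d <- dim(ds$magnitude)[1:3]
  n <- dim(ds$magnitude)[4L]
  thr_m <- fraction * max(ds$magnitude)
  thr_v <- factor * ds$venc
  n_mag <- 0L; n_vel <- 0L
  for (t in seq_len(n))
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
      if (ds$magnitude[i, j, k, t] < thr_m) n_mag <- n_mag + 1L
      if (any(abs(ds$velocity[i, j, k, , t]) > thr_v)) n_vel <- n_vel + 1L
    }
  list(n_mag = n_mag, n_vel = n_vel)
}
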