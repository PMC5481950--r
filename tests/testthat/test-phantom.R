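test_that("phantom generation is deterministic given config + seed", {
  ph1 <- generate_phantom(small_phantom_config())
  ph2 <- generate_phantom(small_phantom_config())
  expect_identical(ph1$dataset$magnitude, ph2$dataset$magnitude)
  expect_identical(ph1$dataset$velocity, ph2$dataset$velocity)
  expect_identical(ph1$truth$outlier_mask, ph2$truth$outlier_mask)
  # a different seed changes the noise
  ph3 <- generate_phantom(small_phantom_config(noise_seed = 12L))
  expect_false(identical(ph1$dataset$magnitude, ph3$dataset$magnitude))
})

test_that("truth deformation is zero at the diastasis frame and masks are disjoint", {
  ph <- generate_phantom(small_phantom_config())
  tr <- ph$truth
  ref <- tr$reference_frame
  expect_equal(max(abs(tr$fields[[ref]]$vectors)), 0)
  # non-reference frames do move
  peak <- ((ref + floor(length(tr$fields) / 2) - 1L) %% length(tr$fields)) + 1L
  expect_gt(max(abs(tr$fields[[peak]]$vectors)), 0.5)
  for (t in seq_along(tr$fields)) {
    overlap <- (tr$chamber_mask[, , , t] & tr$vessel_mask[, , , t]) |
      (tr$chamber_mask[, , , t] & tr$air_mask[, , , t]) |
      (tr$vessel_mask[, , , t] & tr$air_mask[, , , t])
    expect_equal(sum(overlap), 0L)
  }
})

test_that("peak vessel speed matches the configured value within 2%", {
  ph <- generate_phantom(phantom_config(peak_vessel_speed_cms = 100))
  ds <- ph$dataset
  mx <- 0
  for (t in seq_len(n_frames(ds)))
    mx <- max(mx, max(frame_speed(ds, t)[ph$truth$vessel_mask[, , , t]]))
  expect_gt(mx, 98); expect_lt(mx, 102)
})

test_that("automatic reference selection finds the configured still frame", {
  ph <- generate_phantom(small_phantom_config())
  expect_equal(select_reference_frame(ph$dataset, "auto"),
               ph$truth$reference_frame)
  expect_equal(select_reference_frame(ph$dataset, "manual", index = 2L), 2L)
  expect_error(select_reference_frame(ph$dataset, "manual", index = 99L),
               "out of range")
  expect_error(select_reference_frame(ph$dataset, "manual"), "index")
  # static dataset: every frame ties; lowest index wins
  st <- generate_phantom(static_phantom_config(grid = 20L, n_frames = 4L,
                                               diastasis_frame = 2L))
  expect_equal(select_reference_frame(st$dataset, "auto"), 1L)
})

test_that("suppression spares the lumen and removes injected outliers", {
  ph <- generate_phantom(small_phantom_config())
  ds <- normalize_magnitude(ph$dataset)
  sup <- suppress_noise(ds)
  keep <- sup$magnitude_mask$keep & sup$velocity_mask$keep
  lumen <- ph$truth$chamber_mask | ph$truth$vessel_mask
  expect_equal(sum(!keep[lumen]), 0L)
  # injected outliers that actually exceed the threshold must all go
  thr <- 1.5 * ds$venc
  super <- ph$truth$outlier_mask &
    (abs(ds$velocity[, , , 1L, ]) > thr | abs(ds$velocity[, , , 2L, ]) > thr |
       abs(ds$velocity[, , , 3L, ]) > thr)
  expect_gt(sum(super), 0L)
  expect_gte(mean(!sup$velocity_mask$keep[super]), 0.95)
  # velocity-rule suppression stays a small fraction of the volume
  expect_lt(mean(!sup$velocity_mask$keep), 0.05)
})

test_that("vessel flow is divergence-free in the straight tube segment", {
  ph <- generate_phantom(phantom_config())
  ds <- ph$dataset
  cfg <- ph$truth$config
  t <- 5L  # systolic frame
  d <- spatial_dim(ds)
  # straight mid-segment of the vessel, strictly inside the lumen
  ys <- (ceiling(0.42 * d[2L])):(floor(0.58 * d[2L]))
  vx <- ds$velocity[, , , 1L, t]; vy <- ds$velocity[, , , 2L, t]
  vz <- ds$velocity[, , , 3L, t]
  div <- (vx[3:d[1L], ys, ] - vx[1:(d[1L] - 2L), ys, ]) / 2 +
    (vy[2:(d[1L] - 1L), ys + 1L, ] - vy[2:(d[1L] - 1L), ys - 1L, ]) / 2 +
    (vz[2:(d[1L] - 1L), ys, c(2:d[3L], d[3L])] -
       vz[2:(d[1L] - 1L), ys, c(1L, 1:(d[3L] - 1L))]) / 2
  lum <- ph$truth$vessel_mask[2:(d[1L] - 1L), ys, , t]
  # interior lumen only (exclude the smoothed wall)
  peak <- max(abs(vy))
  expect_lt(max(abs(div[lum])) / peak, 0.1)
})

test_that("truth_endpoint_error implements the mean vector norm", {
  d <- c(6L, 6L, 6L)
  z <- pcmrca:::zero_field(d)
  f <- z; f$vectors[, , , 1L] <- 1
  mask <- array(TRUE, dim = d)
  expect_equal(truth_endpoint_error(f, f, mask), 0)
  expect_equal(truth_endpoint_error(f, z, mask), 1)
  # offset by a constant vector: error is its norm
  g <- z; g$vectors[, , , 2L] <- 3; g$vectors[, , , 3L] <- 4
  expect_equal(truth_endpoint_error(g, z, mask), 5)
  # analytic mean over the grid for a sinusoid truth
  gr <- pcmrca:::coord_grids(d)
  s <- z; s$vectors[, , , 1L] <- 3 * sin(2 * pi * gr$y / d[2L])
  expect_equal(truth_endpoint_error(z, s, mask),
               mean(abs(3 * sin(2 * pi * gr$y / d[2L]))))
  expect_error(truth_endpoint_error(f, z, array(FALSE, d)), "empty")
  expect_error(truth_endpoint_error(f, pcmrca:::zero_field(c(3L, 3L, 3L)),
                                    mask), "differ")
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(contraction_amplitude = 0.9), "0.5")
  expect_error(phantom_config(peak_vessel_speed_cms = 200, venc_cms = 120),
               "1.5 x venc")
  expect_error(phantom_config(diastasis_frame = 25L, n_frames = 20L),
               "out of range")
})

test_that("write_phantom emits the dataset, truth and config files", {
  ph <- generate_phantom(static_phantom_config(grid = 16L, n_frames = 3L,
                                               diastasis_frame = 1L))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(dir, "truth", "chamber_mask.nii.gz")))
  expect_true(file.exists(file.path(dir, "phantom_config.yaml")))
  # truth fields reload intact
  f1 <- read_field_nifti(file.path(dir, "truth", "deformation_01.nii.gz"))
  expect_equal(f1$vectors, ph$truth$fields[[1L]]$vectors, tolerance = 1e-6)
})
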