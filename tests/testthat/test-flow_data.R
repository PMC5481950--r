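test_that("flow_dataset enforces its invariants with informative errors", {
  ds <- make_toy_dataset(dims = c(3L, 3L, 3L), n = 2L)
  expect_s3_class(ds, "flow_dataset")
  expect_equal(n_frames(ds), 2L)

  # shape mismatch between channels names both shapes
  bad_vel <- array(0, dim = c(3, 3, 3, 3, 3))
  expect_error(flow_dataset(ds$magnitude, bad_vel, 120, 2.7),
               "shape mismatch.*3x3x3x2.*3x3x3x3x3")

  m2 <- ds$magnitude; m2[1] <- NaN
  expect_error(flow_dataset(m2, ds$velocity, 120, 2.7),
               "non-finite voxels: 1 in magnitude")
  m3 <- ds$magnitude; m3[1] <- -1
  expect_error(flow_dataset(m3, ds$velocity, 120, 2.7), "non-negative")
  expect_error(flow_dataset(ds$magnitude, ds$velocity, -5, 2.7), "venc")
  expect_error(flow_dataset(ds$magnitude, ds$velocity, 120, c(1, -1, 1)),
               "spacing")
})

test_that("write + load round-trips a dataset within float32 precision", {
  ds <- make_toy_dataset(dims = c(6L, 5L, 4L), n = 3L, vel_scale = 80)
  dir <- withr::local_tempdir()
  manifest <- write_flow_dataset(ds, dir)
  expect_length(manifest, 5L)  # 4 NIfTI channels + 1 sidecar
  expect_true(all(file.exists(manifest)))

  ds2 <- load_flow_dataset(
    file.path(dir, "magnitude.nii.gz"),
    file.path(dir, sprintf("velocity_%s.nii.gz", c("x", "y", "z"))))
  # float32 storage: relative error bounded by single-precision eps
  tol <- 2^-23 * max(abs(ds$velocity))
  expect_lt(max(abs(ds2$magnitude - ds$magnitude)), tol)
  expect_lt(max(abs(ds2$velocity - ds$velocity)), tol)
  expect_equal(ds2$venc, ds$venc)
  expect_equal(ds2$spacing, ds$spacing, tolerance = 1e-6)
  expect_equal(ds2$temporal_resolution, ds$temporal_resolution)
})

test_that("a 5D velocity file loads like three 4D component files", {
  ds <- make_toy_dataset(dims = c(5L, 4L, 3L), n = 2L)
  dir <- withr::local_tempdir()
  write_flow_dataset(ds, dir)
  v5 <- array(0, dim = c(5, 4, 3, 2, 3))
  for (k in 1:3) v5[, , , , k] <- ds$velocity[, , , k, ]
  p5 <- file.path(dir, "velocity5d.nii.gz")
  pcmrca:::write_nifti_vol(v5, p5, ds$spacing)
  ds5 <- load_flow_dataset(file.path(dir, "magnitude.nii.gz"), p5)
  ds3 <- load_flow_dataset(
    file.path(dir, "magnitude.nii.gz"),
    file.path(dir, sprintf("velocity_%s.nii.gz", c("x", "y", "z"))))
  expect_equal(ds5$velocity, ds3$velocity)
})

test_that("loader rejects inconsistent or incomplete inputs", {
  ds <- make_toy_dataset(dims = c(4L, 4L, 4L), n = 3L)
  dir <- withr::local_tempdir()
  write_flow_dataset(ds, dir)
  # drop a frame from one velocity component
  short <- ds$velocity[, , , 2L, 1:2]
  dim(short) <- c(4, 4, 4, 2)
  pcmrca:::write_nifti_vol(short, file.path(dir, "velocity_y.nii.gz"),
                           ds$spacing)
  expect_error(load_flow_dataset(
    file.path(dir, "magnitude.nii.gz"),
    file.path(dir, sprintf("velocity_%s.nii.gz", c("x", "y", "z")))),
    "shape mismatch")
  expect_error(load_flow_dataset(file.path(dir, "missing.nii.gz"),
                                 file.path(dir, "velocity_x.nii.gz")),
               "not found")
  # remove the sidecar: venc becomes unknowable
  file.remove(file.path(dir, "meta.yaml"))
  pcmrca:::write_nifti_vol(ds$velocity[, , , 2L, ],
                           file.path(dir, "velocity_y.nii.gz"), ds$spacing)
  expect_error(load_flow_dataset(
    file.path(dir, "magnitude.nii.gz"),
    file.path(dir, sprintf("velocity_%s.nii.gz", c("x", "y", "z")))),
    "venc")
})

test_that("normalize_magnitude rescales by the global maximum only", {
  ds <- make_toy_dataset(dims = c(3L, 3L, 3L), n = 2L)
  ds$magnitude[] <- 0
  ds$magnitude[1:3] <- c(2, 4, 8)
  nm <- normalize_magnitude(ds)
  expect_equal(nm$magnitude[1:3], c(0.25, 0.5, 1.0))
  expect_equal(max(nm$magnitude), 1.0)
  expect_equal(nm$velocity, ds$velocity)  # velocities untouched

  # idempotent, order preserving
  nm2 <- normalize_magnitude(nm)
  expect_equal(nm2$magnitude, nm$magnitude)
  expect_equal(order(nm$magnitude), order(ds$magnitude))

  ds$magnitude[] <- 0
  expect_error(normalize_magnitude(ds), "all-zero")
})
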