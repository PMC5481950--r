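make_blob_image <- function(d = c(32L, 32L, 32L), shift = c(0, 0, 0)) {
  g <- pcmrca:::coord_grids(d)
  c1 <- d / 2
  exp(-((g$x - c1[1L] - shift[1L])^2 + (g$y - c1[2L] - shift[2L])^2 +
          (g$z - c1[3L] - shift[3L])^2) / (2 * 4^2)) +
    0.5 * exp(-((g$x - c1[1L] - 6 - shift[1L])^2 +
                  (g$y - c1[2L] + 4 - shift[2L])^2 +
                  (g$z - c1[3L] - 2 - shift[3L])^2) / (2 * 3^2))
}

test_that("registration_params validates and prints", {
  p <- registration_params()
  expect_equal(p$n_scales, 2L)
  expect_equal(p$iterations_per_scale, 3L)
  expect_equal(p$sigma_fluid, 1.5)
  expect_equal(p$sigma_elastic, 1.5)
  expect_error(registration_params(n_scales = 0), "positive")
  expect_error(registration_params(sigma_fluid = -1), "positive")
  expect_output(print(p), "2 scales")
})

test_that("self-registration yields a (numerically) zero field", {
  img <- make_blob_image()
  fld <- register(img, img)
  expect_lt(max(abs(fld$vectors)), 0.05)
  expect_equal(jacobian_positive_fraction(fld), 1)
})

test_that("a 2-voxel translation is recovered inside the moving structure", {
  fixed <- make_blob_image()
  moving <- make_blob_image(shift = c(2, 0, 0))
  fld <- register(fixed, moving)
  msk <- fixed > 0.3
  expect_gt(mean(fld$vectors[, , , 1L][msk]), 1.75)
  expect_lt(mean(fld$vectors[, , , 1L][msk]), 2.25)
  expect_lt(abs(mean(fld$vectors[, , , 2L][msk])), 0.3)
  expect_lt(abs(mean(fld$vectors[, , , 3L][msk])), 0.3)
  expect_gte(jacobian_positive_fraction(fld), 0.99)
})

test_that("degenerate constant images short-circuit to a zero field", {
  img <- array(1, dim = c(12, 12, 12))
  expect_warning(fld <- register(img, img), "degenerate")
  expect_equal(max(abs(fld$vectors)), 0)
  expect_error(register(img, array(1, dim = c(10, 12, 12))), "shapes differ")
})

test_that("warp respects its border and interpolation contracts", {
  set.seed(2)
  vol <- array(runif(14^3), dim = c(14, 14, 14))
  zf <- pcmrca:::zero_field(dim(vol))
  expect_identical(warp_volume(vol, zf, "nearest"), vol)
  expect_equal(warp_volume(vol, zf, "linear"), vol, tolerance = 1e-12)

  # integer translation with nearest interpolation equals an index shift
  tf <- zf; tf$vectors[, , , 1L] <- 2
  shifted <- warp_volume(vol, tf, "nearest")
  expect_equal(shifted[1:12, , ], vol[3:14, , ])
  # replicate border: the last rows clamp to the edge voxel
  expect_equal(shifted[13:14, , ], vol[c(14, 14), , ])

  expect_error(warp_volume(vol, pcmrca:::zero_field(c(5, 5, 5))), "match")
})

test_that("field composition has the right identity and additive behavior", {
  d <- c(10L, 10L, 10L)
  z <- pcmrca:::zero_field(d)
  set.seed(4)
  smooth <- pcmrca:::gauss_smooth3d(array(rnorm(prod(d)), dim = d), 2)
  B <- z; for (k in 1:3) B$vectors[, , , k] <- smooth * (k / 3)
  expect_equal(compose_fields(z, B)$vectors, B$vectors, tolerance = 1e-12)
  expect_equal(compose_fields(B, z)$vectors, B$vectors, tolerance = 1e-12)

  # constant translations add (everywhere: constant fields sample exactly)
  t1 <- z; t1$vectors[, , , 1L] <- 1.25; t1$vectors[, , , 2L] <- -0.5
  t2 <- z; t2$vectors[, , , 1L] <- 0.5; t2$vectors[, , , 3L] <- 2
  comp <- compose_fields(t1, t2)
  expect_equal(comp$vectors[, , , 1L], array(1.75, d), tolerance = 1e-12)
  expect_equal(comp$vectors[, , , 2L], array(-0.5, d), tolerance = 1e-12)
  expect_equal(comp$vectors[, , , 3L], array(2, d), tolerance = 1e-12)

  # associativity within interpolation tolerance on smooth fields (interior)
  C <- z; for (k in 1:3) C$vectors[, , , k] <- 0.5 * smooth
  lhs <- compose_fields(compose_fields(B, C), t1)
  rhs <- compose_fields(B, compose_fields(C, t1))
  interior <- 3:8
  expect_equal(lhs$vectors[interior, interior, interior, ],
               rhs$vectors[interior, interior, interior, ], tolerance = 0.05)

  expect_error(compose_fields(B, pcmrca:::zero_field(c(4, 4, 4))),
               "different shapes")
})

test_that("inverse-consistency error is zero for trivial fields and bounded", {
  img <- make_blob_image(c(24L, 24L, 24L))
  img <- img / max(img)
  z <- pcmrca:::zero_field(dim(img))
  expect_equal(inverse_consistency_error(img, z, z), 0)
  expect_error(inverse_consistency_error(img * 2, z, z), "normalized")
  # any field pair: error cannot exceed 1 (intensities in [0, 1])
  set.seed(6)
  r <- z; r$vectors[] <- rnorm(length(r$vectors), 0, 2)
  e <- inverse_consistency_error(img, r, r)
  expect_gte(e, 0); expect_lte(e, 1)
})

test_that("displacement fields survive a NIfTI round trip", {
  d <- c(8L, 8L, 8L)
  set.seed(8)
  fld <- pcmrca:::zero_field(d)
  fld$vectors[] <- rnorm(length(fld$vectors))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "field.nii.gz")
  write_field_nifti(fld, p, spacing = c(2.7, 2.7, 2.7))
  fld2 <- read_field_nifti(p)
  expect_equal(fld2$vectors, fld$vectors, tolerance = 1e-6)
  expect_equal(fld2$direction, "fixed_to_moving")
})
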