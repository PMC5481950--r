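test_that("MIP of a constant volume is constant over interior pixels", {
  vol <- array(2.5, dim = c(21, 21, 21))
  img <- mip_project(vol, 0)
  expect_equal(max(abs(img - 2.5)), 0)
  # a rotated constant cube still projects to 2.5 wherever the cube covers
  # the ray; interior pixels (away from the rotated corners) stay constant
  img45 <- mip_project(vol, 45)
  inner <- 8:14
  expect_equal(max(abs(img45[inner, inner] - 2.5)), 0)
})

test_that("angle-0 nearest projection equals the axis-aligned maximum", {
  set.seed(31)
  vol <- array(runif(19^3), dim = c(19, 19, 19))
  for (ax in c("x", "y", "z")) {
    spec <- projection_spec(rotation_axis = ax, interpolation = "nearest")
    proj_axis <- match(ax, c("x", "y", "z")) %% 3L + 1L
    other <- setdiff(1:3, c(match(ax, c("x", "y", "z")), proj_axis))
    oracle <- apply(vol, c(other, match(ax, c("x", "y", "z"))), max)
    expect_identical(mip_project(vol, 0, spec), oracle)
  }
})

test_that("a bright voxel on the rotation axis survives every angle", {
  d <- c(25L, 25L, 25L)
  vol <- array(0, dim = d)
  vol[13, 13, 7] <- 1  # in-plane center for rotation about z
  for (a in c(0, 10, 45, 90, 137)) {
    img <- mip_project(vol, a, projection_spec(rotation_axis = "z"))
    expect_gt(max(img), 0.95)
    # exactly one local maximum: the peak pixel is unique and dominant
    expect_equal(sum(img > 0.5), 1L)
  }
})

test_that("MIP is monotone and bounded by the volume maximum", {
  set.seed(33)
  v <- array(runif(15^3), dim = c(15, 15, 15))
  w <- v + array(runif(15^3, 0, 0.5), dim = dim(v))
  for (a in c(0, 30)) {
    iv <- mip_project(v, a); iw <- mip_project(w, a)
    expect_true(all(iv <= iw + 1e-12))
    expect_lte(max(iv), max(v) + 1e-12)
  }
  expect_error(projection_spec(n_angles = 0), "n_angles")
})

test_that("mip_series produces the requested stacks", {
  frames <- array(runif(10^3 * 3), dim = c(10, 10, 10, 3))
  mrca <- cardio_angio_4d(frames, 1L, 0.2, "max", c(1, 1, 1))
  spec <- projection_spec(n_angles = 36L)
  stacks <- mip_series(mrca, spec)
  expect_length(stacks, 3L)
  expect_equal(dim(stacks[[1L]])[3L], 36L)
  # static scene: identical frames give identical stacks
  frames[, , , 2L] <- frames[, , , 1L]
  mrca2 <- cardio_angio_4d(frames, 1L, 0.2, "max", c(1, 1, 1))
  st2 <- mip_series(mrca2, projection_spec(n_angles = 4L), frames = 1:2)
  expect_equal(st2[[1L]], st2[[2L]])
  # n_angles = 1 degenerates to a single projection at angle 0
  one <- mip_series(mrca, projection_spec(n_angles = 1L), frames = 1L)
  expect_equal(one[[1L]][, , 1L], mip_project(frames[, , , 1L], 0))
})

test_that("isosurface of a sphere has the analytic area within 5%", {
  d <- c(26L, 26L, 26L)
  g <- pcmrca:::coord_grids(d)
  r <- sqrt((g$x - 13.5)^2 + (g$y - 13.5)^2 + (g$z - 13.5)^2)
  R <- 8
  mesh <- isosurface(R - r, 0, spacing = c(1, 1, 1))
  expect_equal(mesh_area(mesh), 4 * pi * R^2, tolerance = 0.05)
  # scaled to physical units: area scales with spacing^2
  mesh_mm <- isosurface(R - r, 0, spacing = c(2, 2, 2))
  expect_equal(mesh_area(mesh_mm), 4 * mesh_area(mesh), tolerance = 1e-6)

  # watertight: every edge is shared by exactly two triangles
  ed <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
              mesh$faces[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  counts <- table(paste(ed[, 1], ed[, 2]))
  expect_true(all(counts == 2L))

  # determinism
  mesh2 <- isosurface(R - r, 0, spacing = c(1, 1, 1))
  expect_identical(mesh, mesh2)

  expect_error(isosurface(R - r, 100), "outside")
  expect_error(isosurface(R - r, -100), "outside")
})

test_that("mesh and image writers emit parseable files", {
  d <- c(12L, 12L, 12L)
  g <- pcmrca:::coord_grids(d)
  r <- sqrt((g$x - 6.5)^2 + (g$y - 6.5)^2 + (g$z - 6.5)^2)
  mesh <- isosurface(4 - r, 0)
  dir <- withr::local_tempdir()
  stl <- write_stl(mesh, file.path(dir, "m.stl"))
  obj <- write_obj(mesh, file.path(dir, "m.obj"))
  expect_true(file.exists(stl) && file.exists(obj))
  stl_lines <- readLines(stl)
  expect_equal(sum(grepl("^facet", stl_lines)), nrow(mesh$faces))
  obj_lines <- readLines(obj)
  expect_equal(sum(grepl("^v ", obj_lines)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", obj_lines)), nrow(mesh$faces))

  img <- mip_project(array(runif(8^3), dim = c(8, 8, 8)), 0)
  p <- write_mip_png(img, file.path(dir, "m.png"))
  expect_true(file.exists(p))
  expect_equal(dim(png::readPNG(p)), rev(dim(img)))
})

test_that("default iso-level tracks the upper intensity percentile", {
  vol <- array(runif(20^3), dim = c(20, 20, 20))
  lev <- default_iso_level(vol)
  expect_equal(lev, 0.5 * as.numeric(quantile(vol, 0.995)))
})
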