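# Dense displacement fields, resampling, composition, smoothing.
#
# Convention: a displacement field u maps fixed-frame voxel coordinates x
# (1-based) to sample positions x + u(x) in the moving frame, in voxel units.
# warp(moving, u)(x) = moving(x + u(x)) then approximates the fixed image.

#' Construct a dense displacement field
#'
#' @param vectors 4D numeric array `[X, Y, Z, 3]` of voxel-unit displacement
#'   components.
#' @param direction semantic tag; the default documents that the field maps
#'   fixed-frame coordinates to sample positions in the moving frame.
#' @return An object of class `displacement_field`.
#' @seealso [register()], [warp_volume()], [compose_fields()]
#' @export
displacement_field <- function(vectors, direction = "fixed_to_moving") {
  d <- dim(vectors)
  if (length(d) != 4L || d[4L] != 3L)
    stop("vectors must be a 4D array [X, Y, Z, 3]", call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement field must be finite everywhere", call. = FALSE)
  structure(list(vectors = vectors, direction = direction),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  nrm <- sqrt(x$vectors[, , , 1L]^2 + x$vectors[, , , 2L]^2 +
                x$vectors[, , , 3L]^2)
  cat(sprintf(
    "Displacement field (%s): %d x %d x %d, |u| mean %.3f / max %.3f voxels\n",
    x$direction, d[1], d[2], d[3], mean(nrm), max(nrm)))
  invisible(x)
}

zero_field <- function(d) displacement_field(array(0, dim = c(d, 3L)))

field_norms <- function(field) {
  v <- field$vectors
  sqrt(v[, , , 1L]^2 + v[, , , 2L]^2 + v[, , , 3L]^2)
}

# 1-based voxel-center coordinate grids for a volume of dims d
coord_grids <- function(d) {
  list(x = array(rep(seq_len(d[1L]), times = d[2L] * d[3L]), dim = d),
       y = array(rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
                 dim = d),
       z = array(rep(seq_len(d[3L]), each = d[1L] * d[2L]), dim = d))
}

# Sample `vol` at (xi, yi, zi) (1-based, fractional). Border policy:
# fill = NULL clamps to the nearest edge voxel (replicate), otherwise
# out-of-bounds samples take `fill`.
sample_volume <- function(vol, xi, yi, zi,
                          interpolation = c("linear", "nearest"),
                          fill = NULL) {
  interpolation <- match.arg(interpolation)
  d <- dim(vol)
  oob <- NULL
  if (!is.null(fill))
    oob <- xi < 1 | xi > d[1L] | yi < 1 | yi > d[2L] | zi < 1 | zi > d[3L]
  if (interpolation == "nearest") {
    ix <- pmin.int(pmax.int(round(xi), 1L), d[1L])
    iy <- pmin.int(pmax.int(round(yi), 1L), d[2L])
    iz <- pmin.int(pmax.int(round(zi), 1L), d[3L])
    out <- vol[ix + d[1L] * (iy - 1L) + d[1L] * d[2L] * (iz - 1L)]
  } else {
    xc <- pmin(pmax(xi, 1), d[1L])
    yc <- pmin(pmax(yi, 1), d[2L])
    zc <- pmin(pmax(zi, 1), d[3L])
    x0 <- pmin.int(floor(xc), d[1L] - 1L); fx <- xc - x0
    y0 <- pmin.int(floor(yc), d[2L] - 1L); fy <- yc - y0
    z0 <- pmin.int(floor(zc), d[3L] - 1L); fz <- zc - z0
    sx <- d[1L]; sxy <- d[1L] * d[2L]
    i000 <- x0 + sx * (y0 - 1L) + sxy * (z0 - 1L)
    v000 <- vol[i000];           v100 <- vol[i000 + 1L]
    v010 <- vol[i000 + sx];      v110 <- vol[i000 + sx + 1L]
    v001 <- vol[i000 + sxy];     v101 <- vol[i000 + sxy + 1L]
    v011 <- vol[i000 + sx + sxy]; v111 <- vol[i000 + sx + sxy + 1L]
    c00 <- v000 + fx * (v100 - v000)
    c10 <- v010 + fx * (v110 - v010)
    c01 <- v001 + fx * (v101 - v001)
    c11 <- v011 + fx * (v111 - v011)
    c0 <- c00 + fy * (c10 - c00)
    c1 <- c01 + fy * (c11 - c01)
    out <- c0 + fz * (c1 - c0)
  }
  if (!is.null(fill)) out[oob] <- fill
  out
}

#' Warp a volume by a displacement field
#'
#' Resamples `volume` at `x + field(x)`: the output at fixed-frame voxel `x`
#' is the input interpolated at the displaced position. Out-of-bounds samples
#' replicate the nearest border voxel, which keeps maximum intensity
#' projections free of dark halos at the volume edge.
#'
#' @param volume 3D array or `angio_volume`.
#' @param field a `displacement_field` of matching spatial shape.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A 3D array (or `angio_volume` if one was supplied) of warped
#'   intensities.
#' @export
warp_volume <- function(volume, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_av <- inherits(volume, "angio_volume")
  vol <- as_volume_array(volume)
  d <- dim(vol)
  if (!all(dim(field$vectors)[1:3] == d))
    stop(sprintf("field shape [%s] does not match volume [%s]",
                 paste(dim(field$vectors)[1:3], collapse = "x"),
                 paste(d, collapse = "x")), call. = FALSE)
  g <- coord_grids(d)
  out <- sample_volume(vol,
                       g$x + field$vectors[, , , 1L],
                       g$y + field$vectors[, , , 2L],
                       g$z + field$vectors[, , , 3L],
                       interpolation = interpolation)
  dim(out) <- d
  if (is_av) {
    volume$data <- pmax(out, 0)
    volume
  } else out
}

#' Compose two displacement fields
#'
#' Returns the field of the composite transform "apply `fieldB`, then
#' `fieldA`": `(A o B)(x) = B(x) + A(x + B(x))`, with `A` resampled linearly
#' (clamped at the border). Used for diffeomorphic accumulation of
#' incremental updates during registration.
#'
#' @param fieldA,fieldB `displacement_field`s of identical shape.
#' @return A `displacement_field`.
#' @export
compose_fields <- function(fieldA, fieldB) {
  dA <- dim(fieldA$vectors); dB <- dim(fieldB$vectors)
  if (!all(dA == dB))
    stop("cannot compose fields of different shapes", call. = FALSE)
  d <- dA[1:3]
  g <- coord_grids(d)
  xi <- g$x + fieldB$vectors[, , , 1L]
  yi <- g$y + fieldB$vectors[, , , 2L]
  zi <- g$z + fieldB$vectors[, , , 3L]
  out <- fieldB$vectors
  for (k in 1:3) {
    s <- sample_volume(fieldA$vectors[, , , k], xi, yi, zi, "linear")
    out[, , , k] <- out[, , , k] + s
  }
  displacement_field(out, direction = fieldA$direction)
}

# ---------------------------------------------------------------------------
# Separable Gaussian smoothing with truncated-renormalized border handling.

gauss_line_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma^2))
  Tm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1L & j <= n
    Tm[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  Tm
}

# Smooth a 3D array with an isotropic Gaussian of standard deviation `sigma`
# voxels, applied separably along each axis (dense banded matrices; border
# kernels renormalized).
gauss_smooth3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  key <- sprintf("gm_%d_%g", d[1L], sigma)
  Tx <- .pcmrca_cache[[key]] %||% (.pcmrca_cache[[key]] <- gauss_line_matrix(d[1L], sigma))
  v <- Tx %*% matrix(vol, d[1L], d[2L] * d[3L])
  dim(v) <- d
  key <- sprintf("gm_%d_%g", d[2L], sigma)
  Ty <- .pcmrca_cache[[key]] %||% (.pcmrca_cache[[key]] <- gauss_line_matrix(d[2L], sigma))
  v <- aperm(v, c(2L, 1L, 3L))
  v <- Ty %*% matrix(v, d[2L], d[1L] * d[3L])
  dim(v) <- c(d[2L], d[1L], d[3L])
  v <- aperm(v, c(2L, 1L, 3L))
  key <- sprintf("gm_%d_%g", d[3L], sigma)
  Tz <- .pcmrca_cache[[key]] %||% (.pcmrca_cache[[key]] <- gauss_line_matrix(d[3L], sigma))
  v <- aperm(v, c(3L, 1L, 2L))
  v <- Tz %*% matrix(v, d[3L], d[1L] * d[2L])
  dim(v) <- c(d[3L], d[1L], d[2L])
  aperm(v, c(2L, 3L, 1L))
}

# Downsample by 2 with Gaussian anti-aliasing (sigma 1 voxel).
downsample2 <- function(vol) {
  v <- gauss_smooth3d(vol, 1.0)
  d <- dim(v)
  v[seq(1L, d[1L], 2L), seq(1L, d[2L], 2L), seq(1L, d[3L], 2L), drop = FALSE]
}

# Upsample a displacement field from a coarse grid (subsampled at odd fine
# indices) back to `fine_dim`, doubling the vectors.
upsample_field2 <- function(field, fine_dim) {
  g <- coord_grids(fine_dim)
  xi <- (g$x + 1) / 2; yi <- (g$y + 1) / 2; zi <- (g$z + 1) / 2
  out <- array(0, dim = c(fine_dim, 3L))
  for (k in 1:3)
    out[, , , k] <- 2 * sample_volume(field$vectors[, , , k], xi, yi, zi,
                                      "linear")
  displacement_field(out, direction = field$direction)
}

# ---------------------------------------------------------------------------
# Jacobian of (identity + field): diffeomorphism diagnostic.

#' Fraction of interior voxels with positive Jacobian determinant
#'
#' Computes `det(I + grad u)` by central differences on the interior of the
#' grid. Values near 1 mean a gentle deformation; any non-positive value
#' signals folding. Fields produced by [register()] should stay positive on
#' at least 99% of interior voxels.
#'
#' @param field a `displacement_field`.
#' @return Scalar in `[0, 1]`.
#' @export
jacobian_positive_fraction <- function(field) {
  v <- field$vectors
  d <- dim(v)[1:3]
  if (any(d < 3L)) return(1)
  ii <- 2:(d[1L] - 1L); jj <- 2:(d[2L] - 1L); kk <- 2:(d[3L] - 1L)
  g <- function(comp, axis) {
    u <- v[, , , comp]
    switch(axis,
           (u[ii + 1L, jj, kk] - u[ii - 1L, jj, kk]) / 2,
           (u[ii, jj + 1L, kk] - u[ii, jj - 1L, kk]) / 2,
           (u[ii, jj, kk + 1L] - u[ii, jj, kk - 1L]) / 2)
  }
  a11 <- 1 + g(1L, 1L); a12 <- g(1L, 2L); a13 <- g(1L, 3L)
  a21 <- g(2L, 1L); a22 <- 1 + g(2L, 2L); a23 <- g(2L, 3L)
  a31 <- g(3L, 1L); a32 <- g(3L, 2L); a33 <- 1 + g(3L, 3L)
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  mean(det > 0)
}

#' Serialize a displacement field as a 4D NIfTI
#'
#' Components are stored on the 4th axis in voxel units; the direction tag is
#' written to a YAML sidecar.
#'
#' @param field a `displacement_field`.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param spacing voxel spacing in mm for the header.
#' @return The written paths, invisibly.
#' @export
write_field_nifti <- function(field, path, spacing = c(1, 1, 1)) {
  write_nifti_vol(field$vectors, path, rep(spacing, length.out = 3L))
  side <- sub("\\.nii(\\.gz)?$", ".yaml", path)
  yaml::write_yaml(list(direction = field$direction, units = "voxels"), side)
  invisible(c(path, side))
}

#' Read a displacement field written by [write_field_nifti()]
#' @param path NIfTI path.
#' @return A `displacement_field`.
#' @export
read_field_nifti <- function(path) {
  arr <- read_nifti_array(path)$data
  side <- sub("\\.nii(\\.gz)?$", ".yaml", path)
  dir <- if (file.exists(side)) yaml::read_yaml(side)$direction else
    "fixed_to_moving"
  displacement_field(arr, direction = dir)
}
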