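#' Projection settings for rotating maximum intensity projections
#'
#' @param n_angles number of evenly spaced projection angles over 360
#'   degrees (default 36).
#' @param rotation_axis `"x"`, `"y"` or `"z"`: axis the volume rotates
#'   about; the projection (max) is taken along the next axis cyclically
#'   (x -> y, y -> z, z -> x).
#' @param interpolation `"linear"` or `"nearest"` resampling of the rotated
#'   volume.
#' @return An object of class `projection_spec`.
#' @export
projection_spec <- function(n_angles = 36L, rotation_axis = c("z", "x", "y"),
                            interpolation = c("linear", "nearest")) {
  n_angles <- as.integer(n_angles)
  if (n_angles < 1L) stop("n_angles must be >= 1", call. = FALSE)
  structure(list(n_angles = n_angles,
                 rotation_axis = match.arg(rotation_axis),
                 interpolation = match.arg(interpolation)),
            class = "projection_spec")
}

axis_index <- function(axis) match(axis, c("x", "y", "z"))

#' Maximum intensity projection of a rotated volume
#'
#' Rotates the volume about `spec$rotation_axis` through its center by
#' `angle_deg` (resampling the volume; out-of-bounds voxels are filled with
#' 0 so rotated corners never outshine anatomy) and takes the voxelwise
#' maximum along the projection direction.
#'
#' @param volume `angio_volume` or 3D array.
#' @param angle_deg rotation angle in degrees.
#' @param spec a [projection_spec()].
#' @return A 2D matrix of projected intensities.
#' @export
mip_project <- function(volume, angle_deg = 0, spec = projection_spec()) {
  vol <- as_volume_array(volume)
  if (any(!is.finite(vol))) stop("volume must be finite", call. = FALSE)
  ax <- axis_index(spec$rotation_axis)
  proj <- ax %% 3L + 1L                       # x->y, y->z, z->x
  other <- setdiff(1:3, c(ax, proj))
  v <- aperm(vol, c(proj, other, ax))
  d <- dim(v)
  theta <- angle_deg * pi / 180
  if (abs(theta %% (2 * pi)) < 1e-12) {
    rot <- v
  } else {
    g <- coord_grids(d)
    c1 <- (d[1L] + 1) / 2; c2 <- (d[2L] + 1) / 2
    ca <- cos(theta); sa <- sin(theta)
    a <- g$x - c1; b <- g$y - c2
    rot <- sample_volume(v, ca * a - sa * b + c1, sa * a + ca * b + c2, g$z,
                         interpolation = spec$interpolation, fill = 0)
    dim(rot) <- d
  }
  apply(rot, c(2L, 3L), max)
}

#' Rotating MIP stacks for every timeframe of a 4D PC-MRCA
#'
#' For each requested timeframe, computes `n_angles` projections at uniform
#' angular spacing over 360 degrees, ready for animation export.
#'
#' @param mrca a `cardio_angio_4d`.
#' @param spec a [projection_spec()].
#' @param frames frame indices to render (default: all).
#' @return A list (one element per frame) of 3D arrays
#'   `[height, width, n_angles]`.
#' @export
mip_series <- function(mrca, spec = projection_spec(), frames = NULL) {
  stopifnot(inherits(mrca, "cardio_angio_4d"))
  n <- dim(mrca$frames)[4L]
  if (is.null(frames)) frames <- seq_len(n)
  angles <- (seq_len(spec$n_angles) - 1L) * 360 / spec$n_angles
  lapply(frames, function(t) {
    vol <- mrca$frames[, , , t]
    imgs <- lapply(angles, function(a) mip_project(vol, a, spec))
    array(unlist(imgs), dim = c(dim(imgs[[1L]]), spec$n_angles))
  })
}

# ---------------------------------------------------------------------------
# Isosurface extraction by marching tetrahedra: each grid cell is split into
# six tetrahedra sharing the main diagonal; within a tetrahedron the
# level-set of the linear interpolant is a triangle or a quad, so no
# ambiguous cases exist and the mesh is watertight for surfaces closed
# inside the grid.

# tetrahedron decomposition of the unit cube (corner ids 0..7, vertex 0 at
# the cell origin, binary order x, y, z)
TET_SPLIT <- rbind(c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L), c(0L, 2L, 6L, 7L),
                   c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L), c(0L, 5L, 1L, 7L))
CUBE_OFFS <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
# tet edges by local vertex pair; ids 1..6
TET_EDGES <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                   c(2L, 3L), c(2L, 4L), c(3L, 4L))
# triangles (as edge-id triples) per sign case (bit k set = local vertex k
# above the level)
TET_CASES <- list(
  `1` = list(c(1L, 3L, 2L)),
  `2` = list(c(1L, 4L, 5L)),
  `3` = list(c(2L, 3L, 5L), c(2L, 5L, 4L)),
  `4` = list(c(2L, 4L, 6L)),
  `5` = list(c(1L, 3L, 6L), c(1L, 6L, 4L)),
  `6` = list(c(1L, 5L, 6L), c(1L, 6L, 2L)),
  `7` = list(c(3L, 5L, 6L)),
  `8` = list(c(3L, 5L, 6L)),
  `9` = list(c(1L, 2L, 6L), c(1L, 6L, 5L)),
  `10` = list(c(1L, 4L, 6L), c(1L, 6L, 3L)),
  `11` = list(c(2L, 4L, 6L)),
  `12` = list(c(2L, 4L, 5L), c(2L, 5L, 3L)),
  `13` = list(c(1L, 4L, 5L)),
  `14` = list(c(1L, 2L, 3L)))

#' Extract an isosurface as a triangle mesh
#'
#' Marching-tetrahedra extraction of the level set `volume == level`, with
#' linear interpolation along cell edges. Vertices are returned in world
#' millimetres (`(voxel index - 1) * spacing`); duplicate vertices are
#' merged, so surfaces entirely interior to the grid are watertight.
#' Deterministic: identical input yields an identical mesh.
#'
#' @param volume `angio_volume` or 3D array.
#' @param level iso-level, strictly between the volume minimum and maximum.
#' @param spacing voxel spacing in mm (taken from an `angio_volume`
#'   automatically).
#' @return A list with `vertices` (n x 3 matrix, mm) and `faces`
#'   (m x 3 integer matrix of 1-based vertex indices).
#' @export
isosurface <- function(volume, level, spacing = NULL) {
  if (inherits(volume, "angio_volume") && is.null(spacing))
    spacing <- volume$spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  vol <- as_volume_array(volume)
  if (!(level > min(vol) && level < max(vol)))
    stop(sprintf("level %g outside the volume intensity range [%g, %g]",
                 level, min(vol), max(vol)), call. = FALSE)
  d <- dim(vol)
  nc <- d - 1L
  # corner values for every cell, as vectors over cells
  corner <- function(k) {
    o <- CUBE_OFFS[k + 1L, ]
    as.vector(vol[(1L + o[1L]):(nc[1L] + o[1L]),
                  (1L + o[2L]):(nc[2L] + o[2L]),
                  (1L + o[3L]):(nc[3L] + o[3L])])
  }
  vals <- lapply(0:7, corner)
  gc <- coord_grids(nc)
  cx <- as.vector(gc$x); cy <- as.vector(gc$y); cz <- as.vector(gc$z)

  tri_x <- list(); tri_y <- list(); tri_z <- list(); nt <- 0L
  for (tet in seq_len(nrow(TET_SPLIT))) {
    ids <- TET_SPLIT[tet, ]
    v <- lapply(ids, function(k) vals[[k + 1L]])
    above <- (v[[1L]] > level) + 2L * (v[[2L]] > level) +
      4L * (v[[3L]] > level) + 8L * (v[[4L]] > level)
    act <- which(above > 0L & above < 15L)
    if (!length(act)) next
    offs <- CUBE_OFFS[ids + 1L, , drop = FALSE]
    edge_point <- function(cells, e) {
      i <- TET_EDGES[e, 1L]; j <- TET_EDGES[e, 2L]
      vi <- v[[i]][cells]; vj <- v[[j]][cells]
      tt <- (level - vi) / (vj - vi)
      list(x = cx[cells] + offs[i, 1L] + tt * (offs[j, 1L] - offs[i, 1L]),
           y = cy[cells] + offs[i, 2L] + tt * (offs[j, 2L] - offs[i, 2L]),
           z = cz[cells] + offs[i, 3L] + tt * (offs[j, 3L] - offs[i, 3L]))
    }
    ab <- above[act]
    for (cs in 1:14) {
      cells <- act[ab == cs]
      if (!length(cells)) next
      for (tri in TET_CASES[[as.character(cs)]]) {
        p1 <- edge_point(cells, tri[1L])
        p2 <- edge_point(cells, tri[2L])
        p3 <- edge_point(cells, tri[3L])
        nt <- nt + 1L
        tri_x[[nt]] <- cbind(p1$x, p2$x, p3$x)
        tri_y[[nt]] <- cbind(p1$y, p2$y, p3$y)
        tri_z[[nt]] <- cbind(p1$z, p2$z, p3$z)
      }
    }
  }
  if (nt == 0L)
    return(list(vertices = matrix(numeric(0), 0L, 3L),
                faces = matrix(integer(0), 0L, 3L)))
  X <- do.call(rbind, tri_x); Y <- do.call(rbind, tri_y)
  Z <- do.call(rbind, tri_z)
  m <- nrow(X)
  px <- as.vector(t(X)); py <- as.vector(t(Y)); pz <- as.vector(t(Z))
  key <- paste(round(px, 6L), round(py, 6L), round(pz, 6L))
  uid <- match(key, unique(key))
  first <- !duplicated(uid)
  verts <- cbind((px[first] - 1) * spacing[1L],
                 (py[first] - 1) * spacing[2L],
                 (pz[first] - 1) * spacing[3L])
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  # drop degenerate triangles (repeated vertices after merging)
  ok <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
    faces[, 1L] != faces[, 3L]
  colnames(verts) <- c("x", "y", "z")
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}

#' Total surface area of a triangle mesh
#' @param mesh a mesh from [isosurface()].
#' @return Area in squared world units (mm^2).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Default iso-level: half of the 99.5th intensity percentile
#' @param volume `angio_volume` or 3D array.
#' @return Scalar level.
#' @export
default_iso_level <- function(volume) {
  vol <- as_volume_array(volume)
  0.5 * as.numeric(stats::quantile(vol, 0.995))
}

#' Write a triangle mesh as ASCII STL
#' @param mesh mesh from [isosurface()].
#' @param path output path.
#' @param name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "isosurface") {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  if (nrow(f)) {
    a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    nx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
    ny <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
    nz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
    lines <- character(7L * nrow(f))
    for (i in seq_len(nrow(f))) {
      j <- 7L * (i - 1L)
      lines[j + 1L] <- sprintf("facet normal %g %g %g",
                               nx[i] / nn[i], ny[i] / nn[i], nz[i] / nn[i])
      lines[j + 2L] <- "  outer loop"
      lines[j + 3L] <- sprintf("    vertex %g %g %g", v[f[i, 1L], 1L],
                               v[f[i, 1L], 2L], v[f[i, 1L], 3L])
      lines[j + 4L] <- sprintf("    vertex %g %g %g", v[f[i, 2L], 1L],
                               v[f[i, 2L], 2L], v[f[i, 2L], 3L])
      lines[j + 5L] <- sprintf("    vertex %g %g %g", v[f[i, 3L], 1L],
                               v[f[i, 3L], 2L], v[f[i, 3L], 3L])
      lines[j + 6L] <- "  endloop"
      lines[j + 7L] <- "endfacet"
    }
    writeLines(lines, con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write a triangle mesh as Wavefront OBJ
#' @param mesh mesh from [isosurface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %g %g %g", v[, 1L], v[, 2L], v[, 3L]), con)
  if (nrow(f))
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Write a projection image as 8-bit grayscale PNG
#'
#' @param img 2D matrix of intensities.
#' @param path output path.
#' @param max_value intensity mapped to white (default: image maximum).
#' @return `path`, invisibly.
#' @export
write_mip_png <- function(img, path, max_value = NULL) {
  if (is.null(max_value)) max_value <- max(img)
  if (max_value <= 0) max_value <- 1
  m <- pmin(pmax(img / max_value, 0), 1)
  # image row 1 at the top; transpose so x runs along image columns
  png::writePNG(t(m)[rev(seq_len(ncol(m))), , drop = FALSE], path)
  invisible(path)
}
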