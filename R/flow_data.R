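#' Construct a 4D Flow CMR dataset
#'
#' Bundles the per-timeframe magnitude and three-directional velocity volumes
#' of a 4D Flow CMR acquisition together with its acquisition metadata. This
#' is the sole input type of the angiography pipeline.
#'
#' @param magnitude 4D numeric array `[X, Y, Z, N]`, signal magnitude per
#'   timeframe (arbitrary non-negative units).
#' @param velocity 5D numeric array `[X, Y, Z, 3, N]`, velocity components
#'   (x, y, z order) in cm/s.
#' @param venc velocity encoding limit in cm/s (scalar, > 0).
#' @param spacing voxel spacing in mm, length-3 (or scalar, recycled).
#' @param temporal_resolution time between frames in ms (scalar, optional).
#' @param frame_times optional length-N vector of frame times in ms from the
#'   R-wave.
#' @return An object of class `flow_dataset`.
#' @seealso [load_flow_dataset()], [write_flow_dataset()], [generate_phantom()]
#' @export
flow_dataset <- function(magnitude, velocity, venc, spacing,
                         temporal_resolution = NA_real_, frame_times = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  ds <- structure(list(
    magnitude = magnitude,
    velocity = velocity,
    venc = as.numeric(venc),
    spacing = as.numeric(spacing),
    temporal_resolution = as.numeric(temporal_resolution),
    frame_times = frame_times
  ), class = "flow_dataset")
  validate_flow_dataset(ds)
  ds
}

#' Validate a flow_dataset against its type invariants
#'
#' Checks shape agreement between magnitude and velocity, finiteness,
#' non-negative magnitude, and positive venc/spacing.
#'
#' @param ds a `flow_dataset`.
#' @return `ds`, invisibly; errors otherwise.
#' @export
validate_flow_dataset <- function(ds) {
  dm <- dim(ds$magnitude)
  dv <- dim(ds$velocity)
  if (length(dm) != 4L)
    stop("magnitude must be a 4D array [X, Y, Z, N]; got ",
         length(dm), " dimensions", call. = FALSE)
  if (length(dv) != 5L || dv[4L] != 3L)
    stop("velocity must be a 5D array [X, Y, Z, 3, N]", call. = FALSE)
  if (!all(dm[1:3] == dv[1:3]) || dm[4L] != dv[5L])
    stop(sprintf(
      "shape mismatch between magnitude [%s] and velocity [%s]",
      paste(dm, collapse = "x"), paste(dv, collapse = "x")), call. = FALSE)
  if (dm[4L] < 1L) stop("dataset must contain at least one frame", call. = FALSE)
  n_bad_m <- sum(!is.finite(ds$magnitude))
  n_bad_v <- sum(!is.finite(ds$velocity))
  if (n_bad_m + n_bad_v > 0L)
    stop(sprintf("non-finite voxels: %d in magnitude, %d in velocity",
                 n_bad_m, n_bad_v), call. = FALSE)
  if (any(ds$magnitude < 0))
    stop("magnitude values must be non-negative", call. = FALSE)
  if (!is.finite(ds$venc) || ds$venc <= 0)
    stop("venc must be a positive scalar (cm/s)", call. = FALSE)
  if (length(ds$spacing) != 3L || any(!is.finite(ds$spacing)) ||
      any(ds$spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  if (!is.null(ds$frame_times) && length(ds$frame_times) != dm[4L])
    stop("frame_times length must equal the number of frames", call. = FALSE)
  invisible(ds)
}

#' Number of timeframes of a flow dataset
#' @param ds a `flow_dataset`.
#' @return integer frame count.
#' @export
n_frames <- function(ds) dim(ds$magnitude)[4L]

#' Spatial dimensions of a flow dataset
#' @param ds a `flow_dataset`.
#' @return integer length-3 vector.
#' @export
spatial_dim <- function(ds) dim(ds$magnitude)[1:3]

#' Voxelwise speed of one timeframe
#'
#' @param ds a `flow_dataset`.
#' @param t frame index (1-based).
#' @return 3D array of `sqrt(Vx^2 + Vy^2 + Vz^2)` in cm/s.
#' @export
frame_speed <- function(ds, t) {
  check_frame_index(ds, t)
  array(sqrt(ds$velocity[, , , 1L, t]^2 + ds$velocity[, , , 2L, t]^2 +
               ds$velocity[, , , 3L, t]^2), spatial_dim(ds))
}

check_frame_index <- function(ds, t) {
  n <- n_frames(ds)
  if (length(t) != 1L || is.na(t) || t < 1L || t > n)
    stop(sprintf("frame index %s out of range [1, %d]", format(t), n),
         call. = FALSE)
  invisible(as.integer(t))
}

#' @export
print.flow_dataset <- function(x, ...) {
  d <- spatial_dim(x)
  cat(sprintf("4D Flow CMR dataset: %d x %d x %d voxels, %d timeframes\n",
              d[1], d[2], d[3], n_frames(x)))
  cat(sprintf("  venc: %g cm/s; spacing: %s mm; temporal resolution: %g ms\n",
              x$venc, paste(format(x$spacing), collapse = " x "),
              x$temporal_resolution))
  cat(sprintf("  magnitude range: [%.4g, %.4g]; max speed: %.4g cm/s\n",
              min(x$magnitude), max(x$magnitude),
              sqrt(max(x$velocity[, , , 1L, ]^2 + x$velocity[, , , 2L, ]^2 +
                         x$velocity[, , , 3L, ]^2))))
  invisible(x)
}

#' Construct a single 3D angiographic volume
#'
#' @param data 3D numeric array of non-negative intensities.
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param provenance which formula produced the volume: `"eq1"`, `"eq2"`,
#'   `"eq3_frame"` or `"mrca3d"`.
#' @return An object of class `angio_volume`.
#' @export
angio_volume <- function(data, spacing,
                         provenance = c("eq1", "eq2", "eq3_frame", "mrca3d")) {
  provenance <- match.arg(provenance)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(dim(data)) != 3L)
    stop("angio volume data must be a 3D array", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("angio volume values must be finite and non-negative", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing),
                 provenance = provenance),
            class = "angio_volume")
}

#' @export
print.angio_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Angiographic volume (%s): %d x %d x %d, intensity [%.4g, %.4g]\n",
              x$provenance, d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

# accept an angio_volume or a bare 3D array wherever a volume is expected
as_volume_array <- function(x) {
  if (inherits(x, "angio_volume")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected an angio_volume or a 3D array", call. = FALSE)
}

#' Construct a time-resolved 4D cardioangiography object
#'
#' Holds the N per-frame angiographic volumes of a 4D PC-MRCA together with
#' its provenance: the diastasis reference frame, the gamma used in the
#' per-frame angiograms, and the temporal fusion mode.
#'
#' @param frames 4D numeric array `[X, Y, Z, N]` of angiographic intensities.
#' @param reference_frame 1-based index of the reference (diastasis) frame.
#' @param gamma gamma-correction exponent used in the per-frame angiograms.
#' @param fusion_mode `"max"` or `"mean"`.
#' @param spacing voxel spacing in mm.
#' @return An object of class `cardio_angio_4d`.
#' @export
cardio_angio_4d <- function(frames, reference_frame, gamma, fusion_mode,
                            spacing) {
  if (length(dim(frames)) != 4L)
    stop("frames must be a 4D array [X, Y, Z, N]", call. = FALSE)
  n <- dim(frames)[4L]
  if (reference_frame < 1L || reference_frame > n)
    stop("reference_frame out of range", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(frames = frames,
                 reference_frame = as.integer(reference_frame),
                 gamma = as.numeric(gamma),
                 fusion_mode = fusion_mode,
                 spacing = as.numeric(spacing)),
            class = "cardio_angio_4d")
}

#' @export
print.cardio_angio_4d <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("4D PC-MRCA: %d x %d x %d voxels, %d timeframes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  reference frame: %d; gamma: %g; fusion: %s\n",
              x$reference_frame, x$gamma, x$fusion_mode))
  invisible(x)
}

# ---------------------------------------------------------------------------
# NIfTI + sidecar I/O

write_nifti_vol <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  pd <- rep(1, nd)
  pd[1:3] <- spacing
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "float")
  path
}

#' Write a flow dataset to a directory of NIfTI files plus a metadata sidecar
#'
#' Layout: one 4D NIfTI per channel (`magnitude.nii.gz`, `velocity_x.nii.gz`,
#' `velocity_y.nii.gz`, `velocity_z.nii.gz`, frame as 4th axis) and a YAML
#' sidecar `meta.yaml` carrying `venc_cms`, `spacing_mm` and
#' `temporal_resolution_ms`. Volumes are stored as float32, so a reload
#' reproduces the dataset within single-precision rounding.
#'
#' @param ds a `flow_dataset`.
#' @param out_dir output directory (created if absent).
#' @return Character vector of written file paths (the manifest), invisibly.
#' @export
write_flow_dataset <- function(ds, out_dir) {
  validate_flow_dataset(ds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  comp <- c("x", "y", "z")
  paths <- file.path(out_dir, "magnitude.nii.gz")
  write_nifti_vol(ds$magnitude, paths[1L], ds$spacing)
  for (k in 1:3) {
    p <- file.path(out_dir, sprintf("velocity_%s.nii.gz", comp[k]))
    write_nifti_vol(ds$velocity[, , , k, , drop = TRUE], p, ds$spacing)
    paths <- c(paths, p)
  }
  meta <- list(venc_cms = ds$venc,
               spacing_mm = as.numeric(ds$spacing),
               temporal_resolution_ms = ds$temporal_resolution)
  if (!is.null(ds$frame_times)) meta$frame_times_ms <- as.numeric(ds$frame_times)
  meta_path <- file.path(out_dir, "meta.yaml")
  yaml::write_yaml(meta, meta_path)
  invisible(c(paths, meta_path))
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  arr <- array(as.numeric(img), dim = dim(img))
  list(data = arr, spacing = sp)
}

#' Load a flow dataset from NIfTI files and a metadata sidecar
#'
#' Accepts either three per-component 4D velocity files (x, y, z order) or a
#' single 5D file with the component on the 5th axis. `meta` may be a list or
#' the path of a YAML sidecar with keys `venc_cms`, `spacing_mm` and
#' optionally `temporal_resolution_ms` / `frame_times_ms`; if omitted, a
#' `meta.yaml` next to the magnitude file is used when present. Spacing from
#' the NIfTI header takes precedence over the sidecar on conflict (with a
#' warning).
#'
#' @param magnitude_path path of the 4D magnitude NIfTI.
#' @param velocity_paths three 4D NIfTI paths, or one 5D NIfTI path.
#' @param meta metadata list or YAML path (must supply venc).
#' @return A validated `flow_dataset`.
#' @export
load_flow_dataset <- function(magnitude_path, velocity_paths, meta = NULL) {
  for (p in c(magnitude_path, velocity_paths))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  if (is.null(meta)) {
    cand <- file.path(dirname(magnitude_path), "meta.yaml")
    if (file.exists(cand)) meta <- cand
  }
  if (is.character(meta)) meta <- yaml::read_yaml(meta)
  if (is.null(meta)) meta <- list()

  mg <- read_nifti_array(magnitude_path)
  mag <- mg$data
  if (length(dim(mag)) == 3L) mag <- array(mag, dim = c(dim(mag), 1L))
  if (length(dim(mag)) != 4L)
    stop("magnitude must be a 3D or 4D NIfTI", call. = FALSE)

  if (length(velocity_paths) == 3L) {
    vl <- lapply(velocity_paths, function(p) read_nifti_array(p)$data)
    vl <- lapply(vl, function(v) {
      if (length(dim(v)) == 3L) array(v, dim = c(dim(v), 1L)) else v
    })
    dv <- dim(vl[[1L]])
    for (v in vl) if (!all(dim(v) == dv))
      stop(sprintf("velocity component shape mismatch: [%s] vs [%s]",
                   paste(dv, collapse = "x"),
                   paste(dim(v), collapse = "x")), call. = FALSE)
    vel <- array(0, dim = c(dv[1:3], 3L, dv[4L]))
    for (k in 1:3) vel[, , , k, ] <- vl[[k]]
  } else if (length(velocity_paths) == 1L) {
    v5 <- read_nifti_array(velocity_paths)$data
    if (length(dim(v5)) != 5L || !(3L %in% dim(v5)[4:5]))
      stop("single velocity file must be 5D with a length-3 component axis",
           call. = FALSE)
    if (dim(v5)[4L] == 3L && dim(v5)[5L] != 3L) {
      vel <- v5
    } else {
      # component on the 5th axis -> permute to [X, Y, Z, 3, N]
      vel <- aperm(v5, c(1L, 2L, 3L, 5L, 4L))
    }
  } else {
    stop("velocity_paths must contain 1 or 3 paths", call. = FALSE)
  }

  if (!all(dim(mag)[1:3] == dim(vel)[1:3]) || dim(mag)[4L] != dim(vel)[5L])
    stop(sprintf("shape mismatch between magnitude [%s] and velocity [%s]",
                 paste(dim(mag), collapse = "x"),
                 paste(dim(vel), collapse = "x")), call. = FALSE)

  venc <- meta$venc_cms %||% meta$venc
  if (is.null(venc)) stop("metadata must supply venc (venc_cms)", call. = FALSE)

  hdr_spacing <- mg$spacing
  sidecar_spacing <- meta$spacing_mm
  spacing <- if (!is.null(hdr_spacing) && all(is.finite(hdr_spacing)) &&
                 all(hdr_spacing > 0)) {
    if (!is.null(sidecar_spacing) &&
        any(abs(rep(sidecar_spacing, length.out = 3L) - hdr_spacing) > 1e-4))
      warning("sidecar spacing_mm conflicts with NIfTI header; header wins",
              call. = FALSE)
    hdr_spacing
  } else if (!is.null(sidecar_spacing)) {
    rep(sidecar_spacing, length.out = 3L)
  } else {
    stop("no voxel spacing in NIfTI header or sidecar", call. = FALSE)
  }

  flow_dataset(mag, vel, venc = venc, spacing = spacing,
               temporal_resolution = meta$temporal_resolution_ms %||% NA_real_,
               frame_times = meta$frame_times_ms)
}

#' Rescale magnitude to the unit interval
#'
#' Divides all magnitude frames by the single global maximum over the whole
#' series, so relative frame brightness is preserved and the result lies in
#' `[0, 1]`. Velocities are untouched. Idempotent.
#'
#' @param ds a `flow_dataset`.
#' @return The dataset with normalized magnitude.
#' @export
normalize_magnitude <- function(ds) {
  validate_flow_dataset(ds)
  m <- max(ds$magnitude)
  if (m <= 0) stop("cannot normalize an all-zero magnitude series",
                   call. = FALSE)
  ds$magnitude <- ds$magnitude / m
  ds
}
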