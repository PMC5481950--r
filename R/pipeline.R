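#' Select the reference (diastasis) timeframe
#'
#' Manual mode returns the supplied index. Automatic mode looks for the
#' quietest frame — a stillness proxy for diastasis: for each frame it
#' computes the mean absolute magnitude difference to its two temporal
#' neighbours (the cycle is treated as periodic) over a central region of
#' interest (the middle half of the volume in each dimension), and returns
#' the frame minimizing it. Ties break to the lowest index.
#'
#' @param ds a `flow_dataset`.
#' @param mode `"auto"` or `"manual"`.
#' @param index frame index, required for manual mode.
#' @return Integer frame index (1-based).
#' @export
select_reference_frame <- function(ds, mode = c("auto", "manual"),
                                   index = NULL) {
  validate_flow_dataset(ds)
  mode <- match.arg(mode)
  n <- n_frames(ds)
  if (mode == "manual") {
    if (is.null(index)) stop("manual mode requires an index", call. = FALSE)
    return(check_frame_index(ds, index))
  }
  d <- spatial_dim(ds)
  roi <- lapply(d, function(k) seq(floor(k / 4) + 1L, ceiling(3 * k / 4)))
  if (n == 1L) return(1L)
  score <- numeric(n)
  for (t in seq_len(n)) {
    prv <- if (t == 1L) n else t - 1L
    nxt <- if (t == n) 1L else t + 1L
    m <- ds$magnitude[roi[[1L]], roi[[2L]], roi[[3L]], t]
    score[t] <- mean(abs(m - ds$magnitude[roi[[1L]], roi[[2L]], roi[[3L]], prv])) +
      mean(abs(m - ds$magnitude[roi[[1L]], roi[[2L]], roi[[3L]], nxt]))
  }
  which.min(score)
}

#' Backward registrations: every timeframe to the reference
#'
#' Registers the magnitude image of every non-reference frame (moving) to the
#' reference magnitude frame (fixed), producing the fields `B_t` used to pull
#' per-frame angiograms into the reference geometry. The reference frame
#' itself has an implicit identity transform and is not included.
#'
#' @param ds a `flow_dataset` (magnitude should be normalized).
#' @param ref reference frame index.
#' @param params a [registration_params()].
#' @param verbose print per-frame progress.
#' @param ... further arguments passed to [register()].
#' @return A named list of `displacement_field`s, one per frame `t != ref`
#'   (names are the frame indices).
#' @export
backward_fields <- function(ds, ref, params = registration_params(),
                            verbose = FALSE, ...) {
  validate_flow_dataset(ds)
  ref <- check_frame_index(ds, ref)
  fixed <- ds$magnitude[, , , ref]
  out <- list()
  for (t in setdiff(seq_len(n_frames(ds)), ref)) {
    if (verbose) message("backward registration, frame ", t)
    out[[as.character(t)]] <- tryCatch(
      register(fixed, ds$magnitude[, , , t], params, ...),
      error = function(e) stop("backward registration failed at frame ", t,
                               ": ", conditionMessage(e), call. = FALSE))
  }
  out
}

#' Forward registrations: the reference to every timeframe
#'
#' Registers the reference magnitude frame (moving) to every non-reference
#' magnitude frame (fixed), producing the fields `F_t`; warping the fused
#' angiogram by `F_t` renders it in frame `t`'s geometry.
#'
#' @inheritParams backward_fields
#' @return A named list of `displacement_field`s keyed by frame index.
#' @export
forward_fields <- function(ds, ref, params = registration_params(),
                           verbose = FALSE) {
  validate_flow_dataset(ds)
  ref <- check_frame_index(ds, ref)
  moving <- ds$magnitude[, , , ref]
  out <- list()
  for (t in setdiff(seq_len(n_frames(ds)), ref)) {
    if (verbose) message("forward registration, frame ", t)
    out[[as.character(t)]] <- tryCatch(
      register(ds$magnitude[, , , t], moving, params),
      error = function(e) stop("forward registration failed at frame ", t,
                               ": ", conditionMessage(e), call. = FALSE))
  }
  out
}

#' Fuse warped per-frame angiograms into a 3D PC-MRCA
#'
#' Computes the gamma-corrected angiogram of every timeframe
#' ([pcmra_frame()]), warps each non-reference frame into the reference
#' geometry by its backward field `B_t` (the reference frame enters
#' unwarped), and fuses the N aligned volumes voxelwise by maximum (default)
#' or mean over time. The maximum preserves visibility in the heart
#' chambers, where high flow occurs only transiently; the mean can be
#' preferable for noisy input.
#'
#' @param ds a `flow_dataset` (normalized, suppressed).
#' @param fields named list of backward fields from [backward_fields()].
#' @param ref reference frame index.
#' @param gamma gamma exponent of the per-frame angiograms.
#' @param fusion `"max"` or `"mean"`.
#' @return An `angio_volume` with provenance `"mrca3d"`.
#' @export
fuse_mrca3d <- function(ds, fields, ref, gamma = 0.2,
                        fusion = c("max", "mean")) {
  validate_flow_dataset(ds)
  ref <- check_frame_index(ds, ref)
  fusion <- match.arg(fusion)
  n <- n_frames(ds)
  acc <- NULL
  for (t in seq_len(n)) {
    a <- pcmra_frame(ds, t, gamma)$data
    if (t != ref) {
      fld <- fields[[as.character(t)]]
      if (is.null(fld))
        stop("missing backward field for frame ", t, call. = FALSE)
      a <- warp_volume(a, fld)
    }
    acc <- if (is.null(acc)) {
      a
    } else if (fusion == "max") {
      pmax(acc, a)
    } else {
      acc + a
    }
  }
  if (fusion == "mean") acc <- acc / n
  angio_volume(pmax(acc, 0), ds$spacing, "mrca3d")
}

#' Build the time-resolved 4D PC-MRCA
#'
#' Runs the five-step construction: per-frame gamma-corrected angiograms,
#' backward registration of every timeframe to the reference, temporal
#' fusion in the reference geometry, forward registration of the reference
#' to every timeframe, and warping of the fused angiogram to each frame. The
#' reference frame of the result is the fused volume itself, exactly.
#'
#' Supply `backward` / `forward` to reuse precomputed field sets; both
#' registration passes are run otherwise.
#'
#' @param ds a `flow_dataset`, already normalized ([normalize_magnitude()])
#'   and noise-suppressed ([suppress_noise()]).
#' @param ref reference frame index (e.g. from [select_reference_frame()]).
#' @param gamma gamma exponent (default 0.2).
#' @param fusion temporal fusion mode, `"max"` (default) or `"mean"`.
#' @param params a [registration_params()].
#' @param backward,forward optional precomputed field lists.
#' @param keep_fields if `TRUE`, attach the field lists to the result (for
#'   diagnostics such as [inverse_consistency_error()]).
#' @param verbose print per-stage progress.
#' @return A `cardio_angio_4d`; element `fused` holds the 3D PC-MRCA
#'   `angio_volume`, and `frames[, , , t]` the angiogram warped to frame `t`.
#' @export
build_mrca <- function(ds, ref, gamma = 0.2, fusion = c("max", "mean"),
                       params = registration_params(),
                       backward = NULL, forward = NULL,
                       keep_fields = FALSE, verbose = FALSE) {
  validate_flow_dataset(ds)
  ref <- check_frame_index(ds, ref)
  fusion <- match.arg(fusion)
  n <- n_frames(ds)
  if (is.null(backward)) {
    if (verbose) message("stage: backward registration (", n - 1L, " frames)")
    backward <- backward_fields(ds, ref, params, verbose)
  }
  if (verbose) message("stage: temporal fusion (", fusion, ")")
  fused <- fuse_mrca3d(ds, backward, ref, gamma, fusion)
  if (is.null(forward)) {
    if (verbose) message("stage: forward registration (", n - 1L, " frames)")
    forward <- forward_fields(ds, ref, params, verbose)
  }
  frames <- array(0, dim = c(spatial_dim(ds), n))
  for (t in seq_len(n)) {
    if (t == ref) {
      frames[, , , t] <- fused$data
    } else {
      fld <- forward[[as.character(t)]]
      if (is.null(fld))
        stop("missing forward field for frame ", t, call. = FALSE)
      frames[, , , t] <- warp_volume(fused$data, fld)
    }
  }
  out <- cardio_angio_4d(frames, ref, gamma, fusion, ds$spacing)
  out$fused <- fused
  if (keep_fields) {
    out$backward <- backward
    out$forward <- forward
  }
  out
}

#' Write a 4D PC-MRCA as a 4D NIfTI
#'
#' @param mrca a `cardio_angio_4d`.
#' @param path output NIfTI path; a YAML sidecar records reference frame,
#'   gamma and fusion mode.
#' @return The written paths, invisibly.
#' @export
write_mrca_nifti <- function(mrca, path) {
  stopifnot(inherits(mrca, "cardio_angio_4d"))
  write_nifti_vol(mrca$frames, path, mrca$spacing)
  side <- sub("\\.nii(\\.gz)?$", ".yaml", path)
  yaml::write_yaml(list(reference_frame = mrca$reference_frame,
                        gamma = mrca$gamma,
                        fusion_mode = mrca$fusion_mode,
                        spacing_mm = as.numeric(mrca$spacing)), side)
  invisible(c(path, side))
}
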