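#' @name suppression
#' @title Noise suppression of air and velocity-noise voxels
#'
#' @description Two thresholding rules clean up the velocity data before
#' angiogram computation: voxels whose signal magnitude falls below a
#' fraction (default 10%) of the global magnitude maximum are treated as air,
#' and voxels with a velocity component whose absolute value exceeds a factor
#' (default 1.5) times the velocity encoding limit are treated as velocity
#' noise. Suppression zeroes the velocity of flagged voxels (so they
#' contribute nothing to any angiogram formula) and leaves magnitude intact.
NULL

new_suppression_mask <- function(keep, n_mag, n_vel) {
  structure(list(keep = keep,
                 n_suppressed_magnitude = as.integer(n_mag),
                 n_suppressed_velocity = as.integer(n_vel)),
            class = "suppression_mask")
}

#' @export
print.suppression_mask <- function(x, ...) {
  cat(sprintf(paste0("Suppression mask: %d voxels kept of %d ",
                     "(%d by magnitude rule, %d by velocity rule)\n"),
              sum(x$keep), length(x$keep),
              x$n_suppressed_magnitude, x$n_suppressed_velocity))
  invisible(x)
}

#' Air-noise mask from the magnitude threshold
#'
#' Flags voxels whose magnitude is below `fraction` times the global maximum
#' of the magnitude series (all frames pooled).
#'
#' @param ds a `flow_dataset`.
#' @param fraction threshold as a fraction of the global magnitude maximum
#'   (default 0.10).
#' @return A `suppression_mask` whose `keep` array is `FALSE` at suppressed
#'   voxels; `n_suppressed_magnitude` counts them.
#' @rdname suppression
#' @export
magnitude_noise_mask <- function(ds, fraction = 0.10) {
  validate_flow_dataset(ds)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  thr <- fraction * max(ds$magnitude)
  keep <- ds$magnitude >= thr
  new_suppression_mask(keep, sum(!keep), 0L)
}

#' Velocity-outlier mask from the VENC threshold
#'
#' Flags voxels where velocity exceeds `factor` times the velocity encoding
#' limit (strict inequality; the boundary value is kept). In `"component"`
#' mode (default) any single component with `|V_i| > factor * venc` flags the
#' voxel; in `"speed"` mode the vector norm is compared instead.
#'
#' @param factor multiple of venc above which a voxel is suppressed
#'   (default 1.5).
#' @param mode `"component"` (per-component absolute value) or `"speed"`
#'   (vector norm).
#' @rdname suppression
#' @export
velocity_outlier_mask <- function(ds, factor = 1.5,
                                  mode = c("component", "speed")) {
  validate_flow_dataset(ds)
  mode <- match.arg(mode)
  if (!is.finite(factor) || factor <= 1)
    stop("factor must exceed 1", call. = FALSE)
  thr <- factor * ds$venc
  if (mode == "component") {
    bad <- abs(ds$velocity[, , , 1L, ]) > thr |
      abs(ds$velocity[, , , 2L, ]) > thr |
      abs(ds$velocity[, , , 3L, ]) > thr
  } else {
    bad <- sqrt(ds$velocity[, , , 1L, ]^2 + ds$velocity[, , , 2L, ]^2 +
                  ds$velocity[, , , 3L, ]^2) > thr
  }
  dim(bad) <- dim(ds$magnitude)
  new_suppression_mask(!bad, 0L, sum(bad))
}

#' Apply suppression masks to a dataset
#'
#' Voxels failing any mask get all three velocity components set to zero;
#' magnitude is left intact. Idempotent, and monotone in the thresholds that
#' generated the masks.
#'
#' @param masks a single `suppression_mask` or a list of them.
#' @rdname suppression
#' @export
apply_suppression <- function(ds, masks) {
  validate_flow_dataset(ds)
  if (inherits(masks, "suppression_mask")) masks <- list(masks)
  if (length(masks) == 0L) return(ds)
  keep <- NULL
  for (m in masks) {
    if (!inherits(m, "suppression_mask"))
      stop("masks must be suppression_mask objects", call. = FALSE)
    if (!all(dim(m$keep) == dim(ds$magnitude)))
      stop(sprintf("mask shape [%s] does not match dataset [%s]",
                   paste(dim(m$keep), collapse = "x"),
                   paste(dim(ds$magnitude), collapse = "x")), call. = FALSE)
    keep <- if (is.null(keep)) m$keep else keep & m$keep
  }
  kill <- which(!keep)
  if (length(kill)) {
    nvox <- prod(dim(ds$magnitude)[1:3])
    n <- dim(ds$magnitude)[4L]
    # keep is [X,Y,Z,N]; velocity is [X,Y,Z,3,N] -- map indices per component
    frame <- (kill - 1L) %/% nvox
    within <- (kill - 1L) %% nvox
    for (k in 1:3) {
      idx <- within + nvox * (k - 1L) + nvox * 3 * frame + 1L
      ds$velocity[idx] <- 0
    }
  }
  ds
}

#' Default noise suppression
#'
#' Convenience wrapper applying both rules at their default thresholds
#' (magnitude below 10% of global maximum; any velocity component above
#' 1.5 x venc).
#'
#' @param fraction magnitude threshold fraction.
#' @param factor venc multiple for the velocity rule.
#' @param mode velocity comparison mode, see [velocity_outlier_mask()].
#' @return A list with the suppressed `dataset` and the two masks
#'   (`magnitude_mask`, `velocity_mask`).
#' @rdname suppression
#' @export
suppress_noise <- function(ds, fraction = 0.10, factor = 1.5,
                           mode = c("component", "speed")) {
  mode <- match.arg(mode)
  mm <- magnitude_noise_mask(ds, fraction)
  vm <- velocity_outlier_mask(ds, factor, mode)
  list(dataset = apply_suppression(ds, list(mm, vm)),
       magnitude_mask = mm, velocity_mask = vm)
}

#' Write a suppression mask as a uint8 NIfTI for inspection
#'
#' @param mask a `suppression_mask`.
#' @param path output NIfTI path.
#' @param spacing voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path, spacing = c(1, 1, 1)) {
  arr <- array(as.integer(mask$keep), dim = dim(mask$keep))
  img <- RNifti::asNifti(arr)
  pd <- rep(1, length(dim(arr)))
  pd[1:3] <- rep(spacing, length.out = 3L)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
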