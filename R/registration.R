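#' Registration parameters
#'
#' Settings of the multi-scale phase-based non-rigid registration. Defaults
#' follow the tuned settings for cardiac magnitude images: 2 scales, 3
#' iterations per scale, and a Gaussian of sigma 1.5 voxels for both the
#' fluid regularization (smoothing of each incremental update) and the
#' elastic regularization (smoothing of the accumulated field).
#'
#' @param n_scales number of resolution octaves (>= 1).
#' @param iterations_per_scale iterations at each scale.
#' @param sigma_fluid Gaussian sigma (voxels) applied to each incremental
#'   displacement update.
#' @param sigma_elastic Gaussian sigma (voxels) applied to the accumulated
#'   field after every iteration.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(n_scales = 2L, iterations_per_scale = 3L,
                                sigma_fluid = 1.5, sigma_elastic = 1.5) {
  p <- list(n_scales = as.integer(n_scales),
            iterations_per_scale = as.integer(iterations_per_scale),
            sigma_fluid = as.numeric(sigma_fluid),
            sigma_elastic = as.numeric(sigma_elastic))
  if (p$n_scales < 1L || p$iterations_per_scale < 1L ||
      p$sigma_fluid <= 0 || p$sigma_elastic <= 0)
    stop("all registration parameters must be positive (n_scales >= 1)",
         call. = FALSE)
  class(p) <- "registration_params"
  p
}

#' @export
print.registration_params <- function(x, ...) {
  cat(sprintf(paste0("Registration parameters: %d scales, %d iterations/scale,",
                     " sigma fluid %.2f / elastic %.2f voxels\n"),
              x$n_scales, x$iterations_per_scale, x$sigma_fluid,
              x$sigma_elastic))
  invisible(x)
}

# Local spatial frequency of a quadrature response along direction n:
# omega = |Im(conj(q) (n . grad) q)| / |q|^2, by central differences.
# Converts local-phase differences into voxel displacements. Clamped to a
# band around the filter center frequency for robustness in flat regions.
local_frequency <- function(q, n) {
  d <- dim(q)
  cdiff <- function(a, ax) {
    out <- array(0i, dim = d)
    switch(ax,
           {out[2:(d[1L]-1L), , ] <- (a[3:d[1L], , ] - a[1:(d[1L]-2L), , ]) / 2},
           {out[, 2:(d[2L]-1L), ] <- (a[, 3:d[2L], ] - a[, 1:(d[2L]-2L), ]) / 2},
           {out[, , 2:(d[3L]-1L)] <- (a[, , 3:d[3L]] - a[, , 1:(d[3L]-2L)]) / 2})
    out
  }
  dq <- n[1L] * cdiff(q, 1L) + n[2L] * cdiff(q, 2L) + n[3L] * cdiff(q, 3L)
  w <- abs(Im(Conj(q) * dq)) / pmax(Mod(q)^2, 1e-20)
  pmin(pmax(w, 0.25 * QUAD_RHO), 2.5 * QUAD_RHO)
}

# One Morphon iteration: estimate a dense incremental displacement between
# `fixed` and `warped` from quadrature-filter local-phase differences along
# the 6 orientations, weighted by local certainty, solved per voxel by
# weighted least squares. qf are the cached filter responses of `fixed`,
# freq the matching local-frequency estimates.
morphon_increment <- function(qf, freq, warped, dirs, sigma_fluid) {
  qm <- quadrature_responses(warped)
  d <- dim(warped)
  a11 <- a12 <- a13 <- a22 <- a23 <- a33 <- array(0, dim = d)
  b1 <- b2 <- b3 <- array(0, dim = d)
  ctot <- array(0, dim = d)
  for (k in seq_along(qf)) {
    pr <- qf[[k]] * Conj(qm[[k]])
    dphi <- Arg(pr)
    # certainty: product of the two filter magnitudes (power 1), damped
    # where the phases disagree strongly
    ck <- Mod(pr) * cos(dphi / 2)^2
    dk <- dphi / freq[[k]]          # displacement along the orientation
    n <- dirs[k, ]
    a11 <- a11 + ck * n[1L] * n[1L]; a12 <- a12 + ck * n[1L] * n[2L]
    a13 <- a13 + ck * n[1L] * n[3L]; a22 <- a22 + ck * n[2L] * n[2L]
    a23 <- a23 + ck * n[2L] * n[3L]; a33 <- a33 + ck * n[3L] * n[3L]
    cd <- ck * dk
    b1 <- b1 + cd * n[1L]; b2 <- b2 + cd * n[2L]; b3 <- b3 + cd * n[3L]
    ctot <- ctot + ck
  }
  # regularized symmetric 3x3 solve per voxel (adjugate formula); a small
  # ridge proportional to the local trace keeps ill-conditioned voxels tame,
  # and voxels with (near-)zero certainty get a zero update
  ridge <- 1e-3 * (a11 + a22 + a33) + 1e-12
  a11 <- a11 + ridge; a22 <- a22 + ridge; a33 <- a33 + ridge
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  det[det <= 0] <- Inf
  u1 <- ((a22 * a33 - a23^2) * b1 + (a13 * a23 - a12 * a33) * b2 +
           (a12 * a23 - a13 * a22) * b3) / det
  u2 <- ((a13 * a23 - a12 * a33) * b1 + (a11 * a33 - a13^2) * b2 +
           (a12 * a13 - a11 * a23) * b3) / det
  u3 <- ((a12 * a23 - a13 * a22) * b1 + (a12 * a13 - a11 * a23) * b2 +
           (a11 * a22 - a12^2) * b3) / det
  # phase is only unambiguous within half a wavelength: cap the update norm
  umax <- pi / QUAD_RHO
  nrm <- sqrt(u1^2 + u2^2 + u3^2)
  scale <- pmin(1, umax / pmax(nrm, 1e-12))
  u1 <- u1 * scale; u2 <- u2 * scale; u3 <- u3 * scale
  # fluid regularization: certainty-normalized Gaussian smoothing
  cs <- gauss_smooth3d(ctot, sigma_fluid)
  eps <- 1e-6 * max(cs)
  list(u1 = gauss_smooth3d(u1 * ctot, sigma_fluid) / (cs + eps),
       u2 = gauss_smooth3d(u2 * ctot, sigma_fluid) / (cs + eps),
       u3 = gauss_smooth3d(u3 * ctot, sigma_fluid) / (cs + eps),
       certainty = ctot)
}

#' Non-rigid registration of two volumes (Morphon-style)
#'
#' Estimates a dense displacement field `B` such that `moving` sampled at
#' `x + B(x)` approximates `fixed`. The algorithm runs coarse-to-fine over
#' `n_scales` octaves; at each scale and iteration it (1) estimates a local
#' displacement update from quadrature-filter local-phase differences along 6
#' orientations weighted by local certainty, (2) smooths the update with a
#' Gaussian of `sigma_fluid` (fluid step), (3) accumulates it
#' diffeomorphically by composing with the running field, and (4) smooths the
#' accumulated field with `sigma_elastic` (elastic step). Deterministic:
#' identical inputs and parameters give identical fields.
#'
#' @param fixed,moving 3D arrays or `angio_volume`s of identical shape.
#' @param params a [registration_params()] object.
#' @param keep_scale_fields if `TRUE`, attach a `scale_fields` attribute: the
#'   accumulated field after each scale, upsampled to full resolution
#'   (coarsest first), for convergence diagnostics.
#' @return A `displacement_field` mapping fixed-frame coordinates to sample
#'   positions in the moving frame.
#' @examples
#' a <- array(0, c(16, 16, 16)); a[6:10, 6:10, 6:10] <- 1
#' f <- register(a, a)
#' max(abs(f$vectors))  # self-registration: zero field
#' @export
register <- function(fixed, moving, params = registration_params(),
                     keep_scale_fields = FALSE) {
  f <- as_volume_array(fixed)
  m <- as_volume_array(moving)
  if (!all(dim(f) == dim(m)))
    stop(sprintf("fixed [%s] and moving [%s] shapes differ",
                 paste(dim(f), collapse = "x"),
                 paste(dim(m), collapse = "x")), call. = FALSE)
  if (!inherits(params, "registration_params"))
    stop("params must be a registration_params object", call. = FALSE)
  if (sd(f) < 1e-12 || sd(m) < 1e-12) {
    warning("degenerate (constant) image; returning a zero field",
            call. = FALSE)
    return(zero_field(dim(f)))
  }
  # intensity scale does not matter to phase, but normalize for conditioning
  f <- f / max(abs(f)); m <- m / max(abs(m))
  dirs <- quad_directions()

  pyr_f <- list(f); pyr_m <- list(m)
  if (params$n_scales > 1L)
    for (s in 2:params$n_scales) {
      pyr_f[[s]] <- downsample2(pyr_f[[s - 1L]])
      pyr_m[[s]] <- downsample2(pyr_m[[s - 1L]])
    }

  field <- NULL
  snapshots <- list()
  for (s in params$n_scales:1) {
    fs <- pyr_f[[s]]; ms <- pyr_m[[s]]
    field <- if (is.null(field)) zero_field(dim(fs)) else
      upsample_field2(field, dim(fs))
    qf <- quadrature_responses(fs)
    freq <- lapply(seq_along(qf), function(k)
      local_frequency(qf[[k]], dirs[k, ]))
    cacc <- array(0, dim = dim(fs))   # accumulated certainty at this scale
    for (it in seq_len(params$iterations_per_scale)) {
      warped <- warp_volume(ms, field)
      u <- morphon_increment(qf, freq, warped, dirs, params$sigma_fluid)
      inc <- displacement_field(array(c(u$u1, u$u2, u$u3),
                                      dim = c(dim(fs), 3L)))
      field <- compose_fields(field, inc)
      # elastic regularization by normalized convolution: smoothing weighted
      # by the accumulated certainty, so structureless background does not
      # drag estimated displacements toward zero
      cacc <- pmax(cacc, u$certainty)
      cs <- gauss_smooth3d(cacc, params$sigma_elastic)
      eps <- 1e-6 * max(cs)
      for (k in 1:3)
        field$vectors[, , , k] <-
          gauss_smooth3d(field$vectors[, , , k] * cacc,
                         params$sigma_elastic) / (cs + eps)
    }
    if (keep_scale_fields) {
      sf <- field
      if (s > 1L)
        for (ss in (s - 1L):1L) sf <- upsample_field2(sf, dim(pyr_f[[ss]]))
      snapshots[[length(snapshots) + 1L]] <- sf
    }
  }
  if (keep_scale_fields) attr(field, "scale_fields") <- snapshots
  field
}

#' Inverse-consistency error of a backward/forward field pair
#'
#' Warps `image` by the backward field and the result by the forward field,
#' then returns the mean squared intensity difference to the original over an
#' interior mask (a border margin is excluded, where replicate-border
#' resampling is uninformative). The image must be normalized to `[0, 1]` so
#' the maximum possible per-voxel error is 1.
#'
#' @param image 3D array with intensities in `[0, 1]`.
#' @param backward,forward `displacement_field`s of matching shape.
#' @param margin border width (voxels) excluded from the average.
#' @return Mean per-voxel squared error (scalar in `[0, 1]`).
#' @export
inverse_consistency_error <- function(image, backward, forward, margin = 4L) {
  img <- as_volume_array(image)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("image must be normalized to [0, 1] (see normalize_magnitude)",
         call. = FALSE)
  round_trip <- warp_volume(warp_volume(img, backward), forward)
  d <- dim(img)
  if (any(d <= 2L * margin))
    stop("volume too small for the requested interior margin", call. = FALSE)
  ii <- (margin + 1L):(d[1L] - margin)
  jj <- (margin + 1L):(d[2L] - margin)
  kk <- (margin + 1L):(d[3L] - margin)
  mean((img[ii, jj, kk] - round_trip[ii, jj, kk])^2)
}
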