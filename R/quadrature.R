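# Log-normal quadrature filter bank for phase-based registration.
#
# Six complex 3D filters along the icosahedral-symmetric orientations. Each
# filter is designed in the Fourier domain as a log-normal radial function
# (center frequency rho, bandwidth B octaves) times a squared-cosine
# directional function on the half-space u . n > 0, then inverse-transformed
# and cropped to a compact 9x9x9 spatial kernel. The complex filter response
# of an image carries a local phase along n whose difference between two
# images is proportional to the displacement component along n.

QUAD_RHO <- pi / 3        # center frequency, radians/voxel
QUAD_BANDWIDTH <- 2       # relative bandwidth, octaves
QUAD_SIZE <- 9L           # spatial kernel support
QUAD_DESIGN_N <- 32L      # design grid for the Fourier-domain prototype

# Unit orientation vectors: 6 of the 12 icosahedron vertices (one per
# antipodal pair).
quad_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  m <- rbind(c(0, 1, phi), c(0, 1, -phi),
             c(1, phi, 0), c(1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1))
  m / sqrt(1 + phi^2)
}

fftfreq3 <- function(n) {
  f <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / n
  2 * pi * f
}

fftshift3 <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) c(seq(floor(n / 2) + 1L, n), seq_len(floor(n / 2))))
  a[idx[[1L]], idx[[2L]], idx[[3L]]]
}

design_quadrature_kernel <- function(dir_vec,
                                     rho = QUAD_RHO,
                                     bandwidth = QUAD_BANDWIDTH,
                                     size = QUAD_SIZE,
                                     design_n = QUAD_DESIGN_N) {
  w <- fftfreq3(design_n)
  wx <- array(rep(w, times = design_n^2), dim = rep(design_n, 3L))
  wy <- array(rep(rep(w, each = design_n), times = design_n),
              dim = rep(design_n, 3L))
  wz <- array(rep(w, each = design_n^2), dim = rep(design_n, 3L))
  wr <- sqrt(wx^2 + wy^2 + wz^2)
  radial <- array(0, dim = dim(wr))
  nz <- wr > 0
  cB <- 4 / (bandwidth^2 * log(2))
  radial[nz] <- exp(-cB * log(wr[nz] / rho)^2)
  cosang <- (wx * dir_vec[1L] + wy * dir_vec[2L] + wz * dir_vec[3L])
  dirf <- array(0, dim = dim(wr))
  pos <- nz & (cosang > 0)
  dirf[pos] <- (cosang[pos] / wr[pos])^2
  Ff <- radial * dirf
  spatial <- fft(Ff, inverse = TRUE) / length(Ff)
  spatial <- fftshift3(spatial)
  c0 <- design_n / 2 + 1L
  h <- (size - 1L) / 2
  ker <- spatial[(c0 - h):(c0 + h), (c0 - h):(c0 + h), (c0 - h):(c0 + h)]
  # unit-energy normalization of the cropped kernel
  ker / sqrt(sum(Mod(ker)^2))
}

quadrature_bank <- function() {
  bank <- .pcmrca_cache$quad_bank
  if (is.null(bank)) {
    dirs <- quad_directions()
    bank <- lapply(seq_len(nrow(dirs)), function(k)
      design_quadrature_kernel(dirs[k, ]))
    .pcmrca_cache$quad_bank <- bank
  }
  bank
}

# smallest integer >= n with no prime factor above 7 (fast FFT sizes)
good_fft_size <- function(n) {
  is_good <- function(m) {
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  while (!is_good(n)) n <- n + 1L
  n
}

pad_replicate <- function(vol, p) {
  d <- dim(vol)
  ix <- c(rep(1L, p), seq_len(d[1L]), rep(d[1L], p))
  iy <- c(rep(1L, p), seq_len(d[2L]), rep(d[2L], p))
  iz <- c(rep(1L, p), seq_len(d[3L]), rep(d[3L], p))
  vol[ix, iy, iz]
}

# FFTs of the 6 kernels embedded (wrapped) in a padded grid of dims pd
kernel_ffts <- function(pd) {
  key <- sprintf("kf_%d_%d_%d", pd[1L], pd[2L], pd[3L])
  kf <- .pcmrca_cache[[key]]
  if (is.null(kf)) {
    bank <- quadrature_bank()
    h <- (QUAD_SIZE - 1L) / 2
    kf <- lapply(bank, function(ker) {
      big <- array(0 + 0i, dim = pd)
      big[seq_len(QUAD_SIZE), seq_len(QUAD_SIZE), seq_len(QUAD_SIZE)] <- ker
      # center the kernel at the origin (circular shift by -h-1)
      for (ax in 1:3) {
        n <- pd[ax]
        sh <- c((h + 2):n, 1:(h + 1))
        big <- switch(ax, big[sh, , ], big[, sh, ], big[, , sh])
      }
      fft(big)
    })
    .pcmrca_cache[[key]] <- kf
  }
  kf
}

# Complex responses of the 6 quadrature filters, same dims as vol.
# One forward FFT of the (padded) image, six products + inverse FFTs.
quadrature_responses <- function(vol) {
  d <- dim(vol)
  p <- (QUAD_SIZE - 1L) %/% 2L
  pd0 <- d + 2L * p
  pd <- vapply(pd0, good_fft_size, integer(1L))
  padded <- array(0, dim = pd)
  padded[seq_len(pd0[1L]), seq_len(pd0[2L]), seq_len(pd0[3L])] <-
    pad_replicate(vol, p)
  Fv <- fft(padded)
  kf <- kernel_ffts(pd)
  ii <- p + seq_len(d[1L]); jj <- p + seq_len(d[2L]); kk2 <- p + seq_len(d[3L])
  lapply(kf, function(K) {
    r <- fft(Fv * K, inverse = TRUE) / length(Fv)
    r[ii, jj, kk2]
  })
}
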