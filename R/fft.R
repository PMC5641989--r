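# Centred, unitary discrete Fourier transforms.
#
# All k-space arrays in this package are stored in the centred layout: the DC
# sample sits at index floor(n/2) + 1 along each transformed axis.  Forward
# and inverse transforms are unitary (scaled by 1/sqrt(n)), so Parseval's
# identity holds exactly and round trips are identities to numerical
# precision.  These conventions are relied on by the reconstruction tests.

fftshift_index <- function(n) ((seq_len(n) - 1L - floor(n / 2)) %% n) + 1L

ifftshift_index <- function(n) ((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L

fftshift2 <- function(m) m[fftshift_index(nrow(m)), fftshift_index(ncol(m)), drop = FALSE]

ifftshift2 <- function(m) m[ifftshift_index(nrow(m)), ifftshift_index(ncol(m)), drop = FALSE]

# 2D unitary centred FFT of a matrix (image -> k-space)
ft2c <- function(m) {
  fftshift2(stats::fft(ifftshift2(m))) / sqrt(length(m))
}

# inverse (k-space -> image)
ift2c <- function(m) {
  fftshift2(stats::fft(ifftshift2(m), inverse = TRUE)) / sqrt(length(m))
}

# Unitary centred FFT along the first axis of a matrix (each column
# transformed independently).  Used for phase-encode-only operations.
ft1c_cols <- function(m) {
  i <- ifftshift_index(nrow(m))
  o <- fftshift_index(nrow(m))
  (stats::mvfft(m[i, , drop = FALSE]) / sqrt(nrow(m)))[o, , drop = FALSE]
}

ift1c_cols <- function(m) {
  i <- ifftshift_index(nrow(m))
  o <- fftshift_index(nrow(m))
  (stats::mvfft(m[i, , drop = FALSE], inverse = TRUE) / sqrt(nrow(m)))[o, , drop = FALSE]
}

# Temporal transform: unitary centred FFT along the third axis of an
# (y, x, t) array, returning the x-f representation (f centred).
ft_time <- function(arr) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(3L, 1L, 2L)), nrow = d[3])
  m <- ft1c_cols(m)
  aperm(array(m, dim = c(d[3], d[1], d[2])), c(2L, 3L, 1L))
}

ift_time <- function(arr) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(3L, 1L, 2L)), nrow = d[3])
  m <- ift1c_cols(m)
  aperm(array(m, dim = c(d[3], d[1], d[2])), c(2L, 3L, 1L))
}

# Zoomed inverse transform: evaluate the zero-filled centred inverse 2D
# transform only at selected output rows/cols, directly from the acquired
# k-space, via explicit partial DFT matrices. Exactly equals
# ift2c(pad_kspace(k, zf))[rows, cols] (padding contributes nothing), at a
# fraction of the cost when the window is small.
zoom_dft_matrix <- function(n, zf, idx) {
  q <- seq_len(n) - 1 - floor(n / 2)
  exp(2i * pi * outer(idx - 1 - floor(zf / 2), q) / zf)
}

ift2c_zoom <- function(k, zoom_y, zoom_x) {
  (zoom_y %*% k %*% t(zoom_x)) / sqrt(nrow(k) * ncol(k))
}

# Symmetric zero-padding of centred 2D k-space from (n1, n2) to (z1, z2),
# scaled so that image-domain amplitudes are preserved under the unitary
# convention (interpolation, not energy injection).
pad_kspace <- function(k, zf) {
  n <- dim(k)
  if (any(zf < n)) stop("zerofill matrix must be >= acquired matrix")
  out <- matrix(0 + 0i, zf[1], zf[2])
  o1 <- floor(zf[1] / 2) - floor(n[1] / 2)
  o2 <- floor(zf[2] / 2) - floor(n[2] / 2)
  out[o1 + seq_len(n[1]), o2 + seq_len(n[2])] <- k
  out * sqrt(prod(zf) / prod(n))
}
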