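# k-t lattice undersampling and x-f unfolding.
#
# Undersampling is applied along the phase-encode (row) axis on a sheared
# lattice: each frame samples every r-th line, with the lattice offset
# advancing by one line per frame, phased so the central k-space line is
# sampled in the first frame. In the (y, f) domain this folds the signal
# onto itself at r discrete shift pairs. The unfolding filter resolves each
# folded value into its r aliasing partners, weighting by a squared-
# magnitude signal estimate from the fully sampled central training lines:
#
#   rho = M^2 1^H (1 M^2 1^H)^{-1} rho_alias
#
# where M^2 is the (diagonal) training estimate at the partner positions
# and 1 the aliasing summation. Because the normal term is scalar per
# alias group the filter reduces to a soft division, regularised by a small
# fraction of the mean normal term.

#' Sheared lattice k-t sampling pattern
#'
#' Each frame samples every `r`-th phase-encode line, the offset advancing
#' by one line per frame; the lattice is phased so the central line is
#' sampled in frame 1. The `n_train` most central lines are additionally
#' sampled in every frame as training data.
#'
#' @param n_lines number of phase-encode lines
#' @param r lattice acceleration factor (1 = fully sampled)
#' @param n_train number of central training lines
#' @param n_frames number of cine frames
#' @return an object of class `sampling_pattern` with the combined binary
#'   `mask` (line x frame), the pure `lattice` mask, and `train_idx`
#' @export
make_lattice_pattern <- function(n_lines, r, n_train, n_frames) {
  n_lines <- as.integer(n_lines); r <- as.integer(r)
  n_train <- as.integer(n_train); n_frames <- as.integer(n_frames)
  if (r < 1L || r > n_lines) stop("r must satisfy 1 <= r <= n_lines")
  if (n_train > n_lines) stop("n_train must not exceed n_lines")
  ic <- floor(n_lines / 2) + 1L  # centred-layout DC line
  rows <- seq_len(n_lines)
  lattice <- matrix(0L, n_lines, n_frames)
  for (f in seq_len(n_frames))
    lattice[(rows - ic - (f - 1L)) %% r == 0L, f] <- 1L
  train_idx <- sort(rows[order(abs(rows - ic), rows)][seq_len(n_train)])
  mask <- lattice
  mask[train_idx, ] <- 1L
  structure(list(mask = mask, lattice = lattice, r = r,
                 train_idx = train_idx, n_lines = n_lines,
                 n_frames = n_frames, n_train = n_train),
            class = "sampling_pattern")
}

#' Effective acceleration of a k-t sampling pattern
#'
#' The lattice acquires `n_lines / r` lines per frame and the training data
#' a further `n_train` lines per frame as a separate low-resolution scan,
#' so the scan-time saving is `n_lines / (n_lines/r + n_train)`: with 150
#' lines, r = 10 and 10 training lines this is 150 / 25 = 6. A fully
#' sampled pattern (r = 1) needs no training data and has acceleration 1.
#'
#' @param pattern a [make_lattice_pattern()] object
#' @return the effective acceleration factor
#' @export
effective_acceleration <- function(pattern) {
  stopifnot(inherits(pattern, "sampling_pattern"))
  if (pattern$r == 1L) return(1)
  pattern$n_lines / (mean(colSums(pattern$lattice)) + pattern$n_train)
}

#' Construct a k-t data container
#'
#' @param kdata complex array (line, column, frame, encoding), zero at
#'   unsampled positions
#' @param pattern a [make_lattice_pattern()] object, or `NULL` for fully
#'   sampled data
#' @param params an [acquisition_params()]
#' @param meta optional list carried through reconstruction (ground truth,
#'   origin)
#' @return an object of class `kt_data`
#' @export
kt_data <- function(kdata, pattern, params, meta = list()) {
  stopifnot(inherits(params, "acq_params"))
  if (length(dim(kdata)) != 4L) stop("kdata must be 4D (line, column, frame, encoding)")
  if (!is.null(pattern)) {
    stopifnot(inherits(pattern, "sampling_pattern"))
    if (pattern$n_lines != dim(kdata)[1] || pattern$n_frames != dim(kdata)[3])
      stop("pattern dimensions do not match kdata")
  }
  structure(list(kdata = kdata, pattern = pattern, params = params, meta = meta),
            class = "kt_data")
}

#' @export
print.kt_data <- function(x, ...) {
  d <- dim(x$kdata)
  r <- if (is.null(x$pattern)) 1L else x$pattern$r
  cat(sprintf("k-t data: %d lines x %d cols, %d frames, %d encodings (lattice r = %d)\n",
              d[1], d[2], d[3], d[4], r))
  invisible(x)
}

#' Forward-encode a cine stack into fully sampled k-t space
#'
#' Centred unitary 2D spatial Fourier transform per frame and encoding;
#' [reconstruct_full()] inverts it exactly.
#'
#' @param cine a full field-of-view [cine_stack()] at the acquisition matrix
#' @return a fully sampled [kt_data()]
#' @export
encode_kspace <- function(cine) {
  stopifnot(inherits(cine, "cine_stack"))
  d <- dim(cine$data)
  if (d[1] != cine$params$matrix || d[2] != cine$params$matrix)
    stop("encode_kspace needs a full field-of-view stack at the acquisition matrix")
  k <- array(0i, dim = d)
  for (t in seq_len(d[3])) for (e in seq_len(d[4]))
    k[, , t, e] <- ft2c(cine$data[, , t, e])
  kt_data(k, NULL, cine$params,
          meta = list(truth = cine$truth, flags = cine$flags))
}

#' Apply a sampling pattern to fully sampled k-t data
#'
#' Sampled entries are copied verbatim; unsampled entries are exactly zero.
#'
#' @param kt a fully sampled [kt_data()]
#' @param pattern a [make_lattice_pattern()] object
#' @return an undersampled [kt_data()]
#' @export
undersample <- function(kt, pattern) {
  stopifnot(inherits(kt, "kt_data"), inherits(pattern, "sampling_pattern"))
  d <- dim(kt$kdata)
  if (pattern$n_lines != d[1] || pattern$n_frames != d[3])
    stop("pattern dimensions do not match kdata")
  k <- kt$kdata
  for (t in seq_len(d[3])) {
    keep <- pattern$mask[, t] != 0L
    k[!keep, , t, ] <- 0i
  }
  kt_data(k, pattern, kt$params, meta = kt$meta)
}

# Temporal-average k-space per line, estimated from the frames in which
# each line was sampled (every line is sampled at least once per lattice
# period). Returns (line, column, encoding).
kt_baseline <- function(kdata, mask) {
  d <- dim(kdata)
  B <- array(0i, dim = c(d[1], d[2], d[4]))
  counts <- rowSums(mask)
  for (e in seq_len(d[4])) {
    S <- matrix(0i, d[1], d[2])
    for (t in seq_len(d[3])) {
      sel <- mask[, t] != 0L
      S[sel, ] <- S[sel, ] + kdata[sel, , t, e]
    }
    B[, , e] <- S / pmax(counts, 1L)
  }
  B
}

# Separable spatial apodization window for an n x n centred k-space.
# "fermi" keeps a flat passband and rolls off near the band edge
# (transition centred at 80% of the band, width 8%), the usual
# Gibbs-ringing suppression on preclinical systems; "hann" is the
# stronger full raised-cosine roll-off; "none" leaves the band untouched.
apod_window <- function(n, apodize = c("none", "fermi", "hann")) {
  apodize <- match.arg(apodize)
  if (apodize == "none") return(NULL)
  q <- seq_len(n) - 1 - floor(n / 2)
  qm <- max(abs(q))
  h <- switch(apodize,
    hann = 0.5 + 0.5 * cos(pi * q / qm),
    fermi = 1 / (1 + exp((abs(q) - 0.8 * qm) / (0.08 * qm))))
  outer(h, h)
}

# Shared zero-filling stage: window indices, zoom matrices and pixel
# geometry for a given zerofill matrix and optional crop.
zerofill_geometry <- function(n, zf, fov_mm, crop_mm) {
  px <- fov_mm / zf
  if (is.null(crop_mm)) {
    iy <- ix <- seq_len(zf)
    zy <- zx <- NULL
  } else {
    i0 <- pmax(1L, floor((crop_mm$center_mm - crop_mm$half_width_mm) / px + 0.5))
    i1 <- pmin(zf, ceiling((crop_mm$center_mm + crop_mm$half_width_mm) / px + 0.5))
    iy <- i0[1]:i1[1]; ix <- i0[2]:i1[2]
    zy <- zoom_dft_matrix(n, zf, iy)
    zx <- zoom_dft_matrix(n, zf, ix)
  }
  list(iy = iy, ix = ix, zoom_y = zy, zoom_x = zx, px = px, zf = zf,
       origin_mm = c(iy[1] - 1L, ix[1] - 1L) * px)
}

zerofill_image <- function(k, geom, W = NULL) {
  if (!is.null(W)) k <- k * W
  if (is.null(geom$zoom_y))
    ift2c(pad_kspace(k, c(geom$zf, geom$zf)))
  else
    ift2c_zoom(k, geom$zoom_y, geom$zoom_x)
}

#' Reference reconstruction of fully sampled k-t data
#'
#' Symmetric zero-padding of centred k-space to `zerofill_matrix` followed
#' by the inverse 2D transform per frame/encoding. Zero-filling
#' interpolates (it does not add resolution); amplitudes are preserved.
#' With 22 mm field of view, 150 lines padded to 256 give 86 um pixels and
#' padding to 1024 gives 21 um. When a crop window is requested the
#' zero-filled image is evaluated only there, via an exact partial DFT, so
#' high zero-fill factors stay affordable. An optional Hann apodization of
#' the sampled band suppresses Gibbs ringing (used for the segmentation
#' reconstruction).
#'
#' @param kt a fully sampled [kt_data()]
#' @param zerofill_matrix reconstructed matrix size (defaults to
#'   `params$zerofill_matrix`)
#' @param crop_mm optional `list(center_mm =, half_width_mm =)` to retain
#'   only a window of the reconstructed image
#' @param apodize `"none"` or `"hann"`
#' @return a [cine_stack()] at the reconstructed resolution
#' @export
reconstruct_full <- function(kt, zerofill_matrix = NULL, crop_mm = NULL,
                             apodize = "none") {
  stopifnot(inherits(kt, "kt_data"))
  if (!is.null(kt$pattern) && any(kt$pattern$mask == 0L))
    stop("reconstruct_full requires fully sampled input")
  zf <- as.integer(zerofill_matrix %||% kt$params$zerofill_matrix)
  d <- dim(kt$kdata)
  if (zf < d[1]) stop("zerofill matrix must be >= acquired matrix")
  geom <- zerofill_geometry(d[1], zf, kt$params$fov_mm, crop_mm)
  W <- apod_window(d[1], apodize)
  out <- array(0i, dim = c(length(geom$iy), length(geom$ix), d[3], d[4]))
  for (t in seq_len(d[3])) for (e in seq_len(d[4]))
    out[, , t, e] <- zerofill_image(kt$kdata[, , t, e], geom, W)
  flags <- kt$meta$flags %||% list()
  flags$recon <- "full"
  cine_stack(out, kt$params, pixel_mm = geom$px, origin_mm = geom$origin_mm,
             truth = kt$meta$truth, flags = flags)
}

# Empirically calibrate the (y, f) aliasing kernel of a lattice mask by
# pushing an x-f impulse through the exact sampling chain. Returns the r
# shift pairs (0-based) and their complex weights; offset (0, 0) first.
calibrate_alias_kernel <- function(lattice) {
  ny <- nrow(lattice); nt <- ncol(lattice)
  X <- matrix(0i, ny, nt); X[1, 1] <- 1
  g <- t(ift1c_cols(t(X)))          # x-f impulse -> (y, t)
  K <- ft1c_cols(g) * lattice       # sample in (ky, t)
  Fq <- t(ft1c_cols(t(ift1c_cols(K))))  # back to (y, f)
  keep <- which(Mod(Fq) > max(Mod(Fq)) * 1e-8, arr.ind = TRUE)
  dy <- keep[, 1] - 1L
  df <- keep[, 2] - 1L
  w <- Fq[keep]
  o <- order(dy != 0L | df != 0L, dy, df)
  list(dy = dy[o], df = df[o], weights = w[o])
}

# Partition the (y, f) grid into aliasing groups: member p of the group
# represented by (y0, f0) sits at (y0, f0) - offset_p (mod grid). Returns a
# (n_groups x r) matrix of linear indices into the (ny x nf) plane, column
# 1 being the representative.
make_alias_groups <- function(ny, nf, dy, df) {
  r <- length(dy)
  if ((ny * nf) %% r != 0L)
    stop("lattice aliasing offsets do not partition the y-f grid; ",
         "r must divide both the line count and the frame count")
  visited <- matrix(FALSE, ny, nf)
  li <- matrix(0L, (ny * nf) %/% r, r)
  g <- 0L
  for (f0 in seq_len(nf)) for (y0 in seq_len(ny)) {
    if (visited[y0, f0]) next
    ys <- ((y0 - 1L - dy) %% ny) + 1L
    fs <- ((f0 - 1L - df) %% nf) + 1L
    if (any(visited[cbind(ys, fs)]))
      stop("aliasing offsets are not a proper lattice subgroup")
    g <- g + 1L
    li[g, ] <- ys + (fs - 1L) * ny
    visited[cbind(ys, fs)] <- TRUE
  }
  li
}

#' Build the x-f unfolding filter from the training lines
#'
#' Forms low-resolution images from the central training lines only,
#' transforms them to x-f space and takes the squared magnitude as the
#' signal-distribution estimate used to apportion each folded value among
#' its aliasing partners. The limited number of training lines blurs the
#' estimate over roughly `n_lines / n_train` pixels along the phase-encode
#' axis, which suppresses high temporal frequencies in the reconstruction
#' (the low-pass behaviour the accelerated QA measurement exploits).
#'
#' By default the temporal-average (DC) signal, estimated per k-space line
#' from the frames in which it was sampled, is removed first; the dominant
#' static anatomy would otherwise swamp the dynamic signal estimate. The
#' same baseline is removed from the folded data during reconstruction and
#' restored afterwards.
#'
#' @param kt an undersampled [kt_data()] whose pattern carries training lines
#' @param reg_lambda regularisation, as a fraction of the mean normal term,
#'   added to the denominator of the unfolding filter
#' @param subtract_baseline remove the temporal-average signal before
#'   estimating the signal distribution
#' @return an object of class `recon_filter`
#' @export
train_signal_estimate <- function(kt, reg_lambda = 1e-6, subtract_baseline = TRUE) {
  stopifnot(inherits(kt, "kt_data"))
  pattern <- kt$pattern
  if (is.null(pattern)) stop("kt data carry no sampling pattern")
  if (any(pattern$mask[pattern$train_idx, ] == 0L))
    stop("training lines must be sampled in every frame")
  d <- dim(kt$kdata)
  ny <- d[1]; nx <- d[2]; nt <- d[3]; K <- d[4]
  B <- if (subtract_baseline) kt_baseline(kt$kdata, pattern$mask) else
    array(0i, dim = c(ny, nx, K))
  M2 <- array(0, dim = c(ny * nt, nx, K))
  for (e in seq_len(K)) {
    img <- array(0i, dim = c(ny, nx, nt))
    for (t in seq_len(nt)) {
      ktr <- matrix(0i, ny, nx)
      ktr[pattern$train_idx, ] <- kt$kdata[pattern$train_idx, , t, e] -
        B[pattern$train_idx, , e]
      img[, , t] <- ift2c(ktr)
    }
    xf <- ft_time(img)
    M2[, , e] <- matrix(Mod(aperm(xf, c(1L, 3L, 2L)))^2, ny * nt, nx)
  }
  kern <- calibrate_alias_kernel(pattern$lattice)
  if (length(kern$dy) != pattern$r)
    stop("lattice aliasing kernel has ", length(kern$dy), " components, expected r = ",
         pattern$r, "; use a frame count and line count divisible by r")
  groups <- make_alias_groups(ny, nt, kern$dy, kern$df)
  structure(list(signal_estimate_sq = M2,
                 alias_offsets = cbind(dy = kern$dy, df = kern$df),
                 alias_weights = kern$weights,
                 groups = groups, reg_lambda = reg_lambda,
                 dims = c(ny = ny, nx = nx, nt = nt, n_enc = K),
                 r = pattern$r, subtract_baseline = subtract_baseline),
            class = "recon_filter")
}

#' @export
print.recon_filter <- function(x, ...) {
  cat(sprintf("x-f unfolding filter: r = %d, %d alias groups, lambda = %g\n",
              x$r, nrow(x$groups), x$reg_lambda))
  invisible(x)
}

#' k-t BLAST reconstruction of lattice-undersampled data
#'
#' Resolves the r-fold x-f aliasing of a sheared-lattice acquisition using
#' the training-data signal estimate, then returns to the image domain and
#' zero-fills. The temporal-average signal is unfolded exactly (it is
#' removed before unfolding and restored after), so a static object is
#' reconstructed exactly at any acceleration; the fully sampled training
#' rows of k-space are substituted with their measured values before
#' zero-filling. With `r = 1` there is no aliasing to resolve and the
#' result equals [reconstruct_full()].
#'
#' @param kt an undersampled [kt_data()]
#' @param filter a [train_signal_estimate()] filter; computed from `kt` if
#'   missing
#' @param reg_lambda overrides the filter's regularisation if given
#' @param zerofill_matrix reconstructed matrix size (defaults to
#'   `params$zerofill_matrix`)
#' @param crop_mm optional `list(center_mm =, half_width_mm =)` window of
#'   the reconstructed image
#' @param apodize `"none"` or `"hann"` spatial apodization of the final
#'   zero-filling stage
#' @return a [cine_stack()] at the reconstructed resolution
#' @export
reconstruct_ktblast <- function(kt, filter = NULL, reg_lambda = NULL,
                                zerofill_matrix = NULL, crop_mm = NULL,
                                apodize = "none") {
  stopifnot(inherits(kt, "kt_data"))
  pattern <- kt$pattern
  if (is.null(pattern) || pattern$r == 1L)
    return(reconstruct_full(kt, zerofill_matrix, crop_mm, apodize))
  if (is.null(filter)) filter <- train_signal_estimate(kt)
  stopifnot(inherits(filter, "recon_filter"))
  lambda <- reg_lambda %||% filter$reg_lambda
  d <- dim(kt$kdata)
  ny <- d[1]; nx <- d[2]; nt <- d[3]; K <- d[4]
  if (!all(filter$dims[1:4] == c(ny, nx, nt, K)))
    stop("filter dimensions do not match the k-t data")
  zf <- as.integer(zerofill_matrix %||% kt$params$zerofill_matrix)
  geom <- zerofill_geometry(ny, zf, kt$params$fov_mm, crop_mm)
  W <- apod_window(ny, apodize)
  li <- filter$groups
  cw <- filter$alias_weights
  r <- filter$r
  B <- kt_baseline(kt$kdata, pattern$mask)
  out <- array(0i, dim = c(length(geom$iy), length(geom$ix), nt, K))
  for (e in seq_len(K)) {
    img <- array(0i, dim = c(ny, nx, nt))
    for (t in seq_len(nt)) {
      res <- (kt$kdata[, , t, e] - B[, , e]) * pattern$lattice[, t]
      img[, , t] <- ift2c(res)
    }
    P <- matrix(aperm(ft_time(img), c(1L, 3L, 2L)), ny * nt, nx)
    M2 <- filter$signal_estimate_sq[, , e]
    b <- P[li[, 1], , drop = FALSE]
    s <- matrix(0, nrow(li), nx)
    for (p in seq_len(r))
      s <- s + Mod(cw[p])^2 * M2[li[, p], , drop = FALSE]
    if (lambda == 0 && any(s == 0))
      stop("singular normal term in the unfolding filter; set reg_lambda > 0")
    denom <- s + lambda * mean(s)
    denom[denom == 0] <- 1  # zero signal estimate and zero data: 0/1 = 0
    Rho <- matrix(0i, ny * nt, nx)
    for (p in seq_len(r))
      Rho[li[, p], ] <- (M2[li[, p], , drop = FALSE] * Conj(cw[p])) * b / denom
    resimg <- ift_time(aperm(array(Rho, c(ny, nt, nx)), c(1L, 3L, 2L)))
    Bimg <- ift2c(B[, , e])
    for (t in seq_len(nt)) {
      Kt <- ft2c(resimg[, , t] + Bimg)
      Kt[pattern$train_idx, ] <- kt$kdata[pattern$train_idx, , t, e]
      out[, , t, e] <- zerofill_image(Kt, geom, W)
    }
  }
  flags <- kt$meta$flags %||% list()
  flags$recon <- "ktblast"
  cine_stack(out, kt$params, pixel_mm = geom$px, origin_mm = geom$origin_mm,
             truth = kt$meta$truth, flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
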