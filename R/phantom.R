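# Synthetic pulsatile-vessel phantom.
#
# The phantom is a straight compliant tube imaged in cross section with
# through-plane flow encoding. Its construction guarantees the QA relation
# exactly in the continuous model: on the systolic upstroke
#   Q(t) = q_base + 1000 * pwv_true * (A(t) - area_base),
# so the slope of Q against A is the prescribed pulse wave velocity. Flow is
# laminar with a parabolic profile, magnitude carries an inflow enhancement
# proportional to the instantaneous mean velocity, and complex Gaussian
# noise is added per channel.

#' Unit-amplitude systolic waveform
#'
#' A raised-cosine upstroke from 0 to 1 over the configured frame window,
#' followed by a raised-cosine decay back to 0 over twice the rise time
#' (clipped at the end of the cine). The minimum is exactly 0 and the
#' maximum exactly 1.
#'
#' @param spec a [phantom_spec()]; `spec$upstroke_frames` sets the rise
#' @param n_frames number of cine frames (>= 8)
#' @return numeric vector of length `n_frames` in `[0, 1]`
#' @export
make_waveform <- function(spec, n_frames) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 8L)
    stop("n_frames must be at least 8 to hold a resolvable pulse")
  u <- spec$upstroke_frames
  if (u[2] > n_frames) stop("upstroke end frame exceeds n_frames")
  w <- numeric(n_frames)
  rise <- u[1]:u[2]
  w[rise] <- (1 - cos(pi * (rise - u[1]) / (u[2] - u[1]))) / 2
  decay_len <- min(2L * (u[2] - u[1]), n_frames - u[2])
  if (decay_len > 0L) {
    j <- seq_len(decay_len)
    w[u[2] + j] <- (1 + cos(pi * j / decay_len)) / 2
  }
  w
}

# Continuous-model time series shared by simulate_truth and render_cine.
phantom_series <- function(spec, params) {
  n_frames <- params$n_frames
  w <- make_waveform(spec, n_frames)
  A <- spec$area_base_mm2 + spec$area_pulse_mm2 * w
  Q <- spec$q_base_mm3s + spec$pwv_true * 1000 * (A - spec$area_base_mm2)
  R <- sqrt(A / pi)
  if (2 * max(R) >= params$fov_mm)
    stop("vessel radius exceeds half the field of view")
  center <- spec$center_mm
  if (is.null(center)) center <- params$fov_mm * c(0.53, 0.49)
  list(time_ms = (seq_len(n_frames) - 1) * effective_temporal_resolution(params),
       w = w, A_mm2 = A, Q_mm3s = Q, R_mm = R,
       vbar_m_s = (Q / A) / 1000, center_mm = center)
}

# Block-average an (a*ss) x (b*ss) matrix down to a x b (works for complex).
block_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  a <- nrow(m) / ss
  b <- ncol(m) / ss
  s1 <- colMeans(array(m, c(ss, a, ss * b)))      # (a, ss*b)
  s2 <- aperm(array(s1, c(a, ss, b)), c(2L, 1L, 3L))
  colMeans(s2)                                     # (a, b)
}

# Index window (rows/cols) covering the vessel plus margin, clipped to the
# grid; rows/cols are relative to an image whose pixel i is centred at
# origin + (i - 0.5) * px.
vessel_window <- function(center_mm, rmax_mm, nrow, ncol, px, origin_mm,
                          margin_px = 3L) {
  iy <- floor((center_mm[1] - rmax_mm - origin_mm[1]) / px + 0.5) - margin_px
  jy <- ceiling((center_mm[1] + rmax_mm - origin_mm[1]) / px + 0.5) + margin_px
  ix <- floor((center_mm[2] - rmax_mm - origin_mm[2]) / px + 0.5) - margin_px
  jx <- ceiling((center_mm[2] + rmax_mm - origin_mm[2]) / px + 0.5) + margin_px
  list(rows = max(1L, iy):min(nrow, jy), cols = max(1L, ix):min(ncol, jx))
}

# Radial distance from the vessel centre on the supersampled sub-grid of a
# pixel window.
radial_subgrid <- function(win, px, origin_mm, center_mm, ss) {
  sub <- (seq_len(ss) - 0.5) / ss
  y <- origin_mm[1] + rep((win$rows - 1) * px, each = ss) + rep(sub * px, length(win$rows))
  x <- origin_mm[2] + rep((win$cols - 1) * px, each = ss) + rep(sub * px, length(win$cols))
  dy <- y - center_mm[1]
  dx <- x - center_mm[2]
  sqrt(outer(dy^2, dx^2, `+`))
}

#' Ground-truth series and velocity field of the phantom
#'
#' Returns the continuous-model area, flow and waveform series together
#' with the through-plane velocity field discretised on the acquisition
#' grid. With `supersample > 1` each pixel value is the average of
#' `supersample^2` sub-samples (partial-volume quadrature); with
#' `supersample = 1` it is the centre-point value.
#'
#' @param spec a [phantom_spec()]
#' @param params an [acquisition_params()]
#' @param supersample sub-samples per pixel edge for the velocity field
#' @return a list of class `phantom_truth` with elements `time_ms`, `w`,
#'   `A_mm2`, `Q_mm3s`, `R_mm`, `vbar_m_s`, `center_mm`, `pwv_true`,
#'   `v_m_s` (array y, x, frame) and `degenerate`
#' @export
simulate_truth <- function(spec, params, supersample = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(params, "acq_params"))
  ser <- phantom_series(spec, params)
  n <- params$matrix
  px <- params$fov_mm / n
  ss <- as.integer(supersample)
  win <- vessel_window(ser$center_mm, max(ser$R_mm), n, n, px, c(0, 0))
  rho <- radial_subgrid(win, px, c(0, 0), ser$center_mm, ss)
  v <- array(0, dim = c(n, n, params$n_frames))
  for (t in seq_len(params$n_frames)) {
    vmax <- 2 * (ser$Q_mm3s[t] / ser$A_mm2[t]) / 1000
    vsub <- vmax * pmax(1 - (rho / ser$R_mm[t])^2, 0)
    v[win$rows, win$cols, t] <- block_mean(vsub, ss)
  }
  structure(c(ser, list(pwv_true = spec$pwv_true,
                        area_base_mm2 = spec$area_base_mm2,
                        q_base_mm3s = spec$q_base_mm3s,
                        v_m_s = v,
                        degenerate = spec$area_pulse_mm2 == 0)),
            class = "phantom_truth")
}

#' Render the phantom as a complex PC-CINE stack
#'
#' For each flow encoding with first moment m the noiseless pixel signal is
#' `Mag * exp(1i * 2 * pi * m * v)` with v in m/s and m in s/m (so moments
#' of +/- 0.3 s/m give a velocity-encoding limit of 1/(2 * 0.3) ~ 1.667
#' m/s). Lumen magnitude is `1 + inflow_gain * vbar(t)`; static tissue sits
#' at `tissue_frac`. By default each pixel is rendered as the complex
#' average of 16 x 16 sub-samples, emulating the partial-volume integration
#' of a band-limited acquisition; `supersample = 1` gives a binary
#' centre-point lumen membership instead. Complex Gaussian noise with per
#' channel standard deviation `1/snr` (units of the lumen baseline) is
#' added reproducibly from `spec$seed`.
#'
#' If the encoded phase reaches `|2 pi m v| >= pi` anywhere the stack is
#' flagged (`flags$velocity_aliasing`) and a warning is issued; wrapped
#' phase is simulated as-is, no unwrapping is attempted.
#'
#' @param spec a [phantom_spec()]
#' @param params an [acquisition_params()]
#' @param supersample sub-samples per pixel edge (1 = centre-point test)
#' @param crop_mm optional `list(center_mm =, half_width_mm =)` rendering
#'   only a window around that point (used for high-resolution studies)
#' @return a [cine_stack()] carrying the ground truth
#' @export
render_cine <- function(spec, params, supersample = 16L, crop_mm = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(params, "acq_params"))
  ser <- phantom_series(spec, params)
  n <- params$matrix
  px <- params$fov_mm / n
  ss <- as.integer(supersample)
  moments <- params$moments_s_per_m
  K <- length(moments)
  gains <- rep_len(spec$inflow_gain, K)
  t0 <- spec$tissue_frac

  if (is.null(crop_mm)) {
    nr <- nc <- n
    origin <- c(0, 0)
  } else {
    i0 <- pmax(1L, floor((crop_mm$center_mm - crop_mm$half_width_mm) / px + 0.5))
    i1 <- pmin(n, ceiling((crop_mm$center_mm + crop_mm$half_width_mm) / px + 0.5))
    nr <- i1[1] - i0[1] + 1L
    nc <- i1[2] - i0[2] + 1L
    origin <- c(i0[1] - 1L, i0[2] - 1L) * px
  }

  win <- vessel_window(ser$center_mm, max(ser$R_mm), nr, nc, px, origin)
  rho <- radial_subgrid(win, px, origin, ser$center_mm, ss)

  nt <- params$n_frames
  data <- array(complex(real = t0, imaginary = 0), dim = c(nr, nc, nt, K))
  vmax_all <- 2 * (ser$Q_mm3s / ser$A_mm2) / 1000
  aliased <- max(abs(2 * pi * moments)) * max(vmax_all) >= pi
  for (t in seq_len(nt)) {
    inside <- rho <= ser$R_mm[t]
    vsub <- vmax_all[t] * pmax(0, 1 - (rho / ser$R_mm[t])^2) * inside
    for (k in seq_len(K)) {
      lum <- 1 + gains[k] * ser$vbar_m_s[t]
      mag <- t0 + inside * (lum - t0)
      data[win$rows, win$cols, t, k] <- block_mean(mag * exp(2i * pi * moments[k] * vsub), ss)
    }
  }
  flags <- list()
  if (aliased) {
    flags$velocity_aliasing <- TRUE
    warning("encoded phase reaches |pi| inside the lumen: velocity aliasing")
  }
  if (is.finite(spec$snr)) {
    set.seed(spec$seed)
    sd <- 1 / spec$snr
    nn <- length(data)
    data <- data + complex(real = stats::rnorm(nn, sd = sd),
                           imaginary = stats::rnorm(nn, sd = sd))
  }
  truth <- c(ser, list(pwv_true = spec$pwv_true,
                       area_base_mm2 = spec$area_base_mm2,
                       q_base_mm3s = spec$q_base_mm3s,
                       degenerate = spec$area_pulse_mm2 == 0))
  cine_stack(data, params, pixel_mm = px, origin_mm = origin,
             truth = truth, flags = flags)
}

#' Ground-truth lumen masks on an arbitrary grid
#'
#' Centre-point disk masks of the true lumen, per frame, on the pixel grid
#' implied by `pixel_mm`/`origin_mm` and matrix size. Used as the reference
#' ("manual") segmentation on synthetic data.
#'
#' @param truth the `truth` record of a phantom [cine_stack()]
#' @param dim image dims (rows, cols)
#' @param pixel_mm pixel size of the target grid (mm)
#' @param origin_mm physical offset of the target grid (mm)
#' @return logical array (y, x, frame)
#' @export
truth_lumen_masks <- function(truth, dim, pixel_mm, origin_mm = c(0, 0)) {
  nt <- length(truth$R_mm)
  y <- origin_mm[1] + (seq_len(dim[1]) - 0.5) * pixel_mm - truth$center_mm[1]
  x <- origin_mm[2] + (seq_len(dim[2]) - 0.5) * pixel_mm - truth$center_mm[2]
  rho <- sqrt(outer(y^2, x^2, `+`))
  out <- array(FALSE, dim = c(dim[1], dim[2], nt))
  for (t in seq_len(nt)) out[, , t] <- rho <= truth$R_mm[t]
  out
}
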