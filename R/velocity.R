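#' Voxel-wise velocity from multi-point flow encoding
#'
#' For every pixel and frame, the phase of the complex signal is regressed
#' on the first gradient moments of the flow-encoding steps by ordinary
#' least squares; under the phase convention phi = 2 pi m v the slope
#' divided by 2 pi is the through-plane velocity in m/s. Acquiring three
#' encodings instead of two leaves a degree of freedom to judge the fit:
#' the per-pixel coefficient of determination R^2 of the 3-point regression
#' is computed from the same fit, and pixels with R^2 below the threshold
#' (default 0.85) are marked invalid. Phase is taken as the argument of the
#' complex pixel with no unwrapping; wrapped pixels generally fail the R^2
#' screen, which is the intended guard.
#'
#' @param cine a [cine_stack()] with at least three encodings
#' @param r2_threshold exclusion cutoff on R^2
#' @return an object of class `velocity_result` with arrays `v` (m/s),
#'   `r2` and `valid` of dims (y, x, frame)
#' @export
fit_velocity <- function(cine, r2_threshold = 0.85) {
  stopifnot(inherits(cine, "cine_stack"))
  m <- cine$params$moments_s_per_m
  K <- length(m)
  if (K < 3L)
    stop("at least 3 flow encodings are required to estimate the fit error")
  if (length(unique(m)) < 2L) stop("all encoding moments are equal")
  dm <- m - mean(m)
  smm <- sum(dm^2)
  d <- dim(cine$data)
  sxy <- array(0, dim = d[1:3])
  sp <- array(0, dim = d[1:3])
  sp2 <- array(0, dim = d[1:3])
  for (k in seq_len(K)) {
    ph <- Arg(cine$data[, , , k, drop = TRUE])
    dim(ph) <- d[1:3]
    sxy <- sxy + dm[k] * ph
    sp <- sp + ph
    sp2 <- sp2 + ph^2
  }
  slope <- sxy / smm
  sst <- sp2 - sp^2 / K
  ssreg <- slope^2 * smm
  r2 <- ifelse(sst > 1e-24, pmin(ssreg / sst, 1), 1)
  structure(list(v = slope / (2 * pi), r2 = r2,
                 valid = r2 >= r2_threshold, r2_threshold = r2_threshold,
                 pixel_mm = cine$pixel_mm,
                 time_ms = (seq_len(d[3]) - 1) *
                   effective_temporal_resolution(cine$params),
                 moments_s_per_m = m),
            class = "velocity_result")
}

#' @export
print.velocity_result <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("velocity maps: %d x %d x %d frames, R^2 >= %.2f on %.1f%% of pixels\n",
              d[1], d[2], d[3], x$r2_threshold, 100 * mean(x$valid)))
  invisible(x)
}

#' Volume flow over a lumen mask
#'
#' Per frame, Q is the sum of velocities over the masked, R^2-valid pixels
#' times the pixel area (velocity converted from m/s to mm/s, giving Q in
#' mm^3/s). Masked pixels excluded by the R^2 screen contribute the mean
#' velocity of the valid masked pixels in the same frame, preserving the
#' area weighting of the flow integral. A frame whose mask contains no
#' valid pixel is flagged and its flow set to `NA`.
#'
#' With `infill = FALSE` excluded pixels simply contribute nothing; this
#' is appropriate when the mask is an inclusive search region rather than
#' a tight lumen mask, since most excluded pixels are then stationary
#' tissue whose true velocity is ~0 and mean-infill would inflate the
#' flow.
#'
#' @param vel a [fit_velocity()] result
#' @param mask logical array (y, x) or (y, x, frame) of lumen membership
#' @param pixel_mm pixel size; defaults to the one carried by `vel`
#' @param infill replace R^2-excluded masked pixels by the mean valid
#'   velocity (default) instead of omitting them
#' @return a data frame (frame, time_ms, Q_mm3s, n_mask, n_invalid,
#'   flagged)
#' @export
compute_flow <- function(vel, mask, pixel_mm = vel$pixel_mm, infill = TRUE) {
  stopifnot(inherits(vel, "velocity_result"))
  d <- dim(vel$v)
  if (length(dim(mask)) == 2L)
    mask <- array(mask, dim = d)
  if (!all(dim(mask) == d)) stop("mask and velocity maps are not aligned")
  nt <- d[3]
  q <- n_mask <- n_inv <- numeric(nt)
  flagged <- logical(nt)
  pxa <- pixel_mm^2
  for (t in seq_len(nt)) {
    sel <- mask[, , t]
    ok <- sel & vel$valid[, , t]
    n_mask[t] <- sum(sel)
    n_inv[t] <- sum(sel) - sum(ok)
    if (!any(ok)) {
      flagged[t] <- TRUE
      q[t] <- NA_real_
      next
    }
    vsum <- sum(vel$v[, , t][ok])
    if (infill) vsum <- vsum + mean(vel$v[, , t][ok]) * n_inv[t]
    q[t] <- vsum * 1000 * pxa
  }
  data.frame(frame = seq_len(nt), time_ms = vel$time_ms, Q_mm3s = q,
             n_mask = n_mask, n_invalid = n_inv, flagged = flagged)
}
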