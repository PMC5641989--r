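# QA-method local pulse wave velocity.
#
# During the early systolic upstroke the flow pulse is unidirectional and
# reflection-free, and volume flow Q and lumen area A are related linearly
# with slope equal to the local pulse wave velocity: PWV = dQ/dA. The
# upstroke is operationalised as the contiguous rising-edge frames whose
# flow lies between 10% and 90% of the pulse height above baseline.

#' Detect the early-systolic upstroke window
#'
#' Baseline is the mean of the lowest decile of frames; the window is the
#' contiguous run of frames on the rising edge towards the global maximum
#' whose flow lies within 10-90% of the pulse height above baseline. An
#' optional moving-average smoothing (odd window) is applied for the
#' detection only.
#'
#' @param q_series volume-flow series Q(t) (mm^3/s); `NA` frames are not
#'   permitted inside the detected window
#' @param smooth_window odd moving-average length used for detection
#'   (1 = none)
#' @param min_frames minimal acceptable window length
#' @return integer vector of frame indices
#' @export
detect_upstroke <- function(q_series, smooth_window = 1L, min_frames = 4L) {
  q <- if (smooth_window > 1L) lowpass_area(q_series, smooth_window) else q_series
  if (anyNA(q)) {
    if (all(is.na(q))) stop("flow series is entirely NA")
    q[is.na(q)] <- min(q, na.rm = TRUE)
  }
  n <- length(q)
  nlow <- max(1L, round(0.1 * n))
  baseline <- mean(sort(q)[seq_len(nlow)])
  rng <- max(q) - baseline
  if (rng <= 0) stop("flow series has no pulse (constant or decreasing)")
  lo <- baseline + 0.1 * rng
  hi <- baseline + 0.9 * rng
  imax <- which.max(q)
  i <- imax
  while (i >= 1L && q[i] > hi) i <- i - 1L  # skip the peak plateau
  window <- integer()
  while (i >= 1L && q[i] >= lo && q[i] <= hi) {
    window <- c(i, window)
    i <- i - 1L
  }
  if (length(window) < min_frames)
    stop("fewer than ", min_frames,
         " frames on the systolic upstroke; slice rejected")
  if (anyNA(q_series[window]))
    stop("flow series has missing frames inside the upstroke window")
  window
}

#' Fit the Q(A) line over the upstroke window
#'
#' Ordinary least squares of Q (mm^3/s) on A (mm^2); the slope has units
#' mm/s and is divided by 1000 to give the PWV in m/s. The 95% confidence
#' interval comes from the standard slope-variance formula.
#'
#' @param q_series volume flow Q(t) (mm^3/s)
#' @param a_series lumen area A(t) (mm^2)
#' @param window frame indices of the systolic upstroke
#' @return an object of class `pwv_estimate`
#' @export
fit_qa <- function(q_series, a_series, window) {
  if (length(q_series) != length(a_series))
    stop("Q and A series have different lengths")
  if (length(window) < 4L) stop("upstroke window must span at least 4 frames")
  q <- q_series[window]
  a <- a_series[window]
  if (anyNA(q) || anyNA(a)) stop("missing values inside the fit window")
  if (stats::sd(a) == 0)
    stop("no area variation inside the window; PWV undefined")
  fit <- stats::lm(q ~ a)
  ci <- stats::confint(fit, "a", level = 0.95)
  structure(list(pwv_m_s = unname(stats::coef(fit)["a"]) / 1000,
                 slope_ci = as.numeric(ci) / 1000,
                 r2_fit = summary(fit)$r.squared,
                 window = window,
                 q_series = q_series, a_series = a_series),
            class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("local PWV: %.3f m/s (95%% CI %.3f - %.3f), R^2 = %.3f, frames %d-%d\n",
              x$pwv_m_s, x$slope_ci[1], x$slope_ci[2], x$r2_fit,
              min(x$window), max(x$window)))
  invisible(x)
}

#' Local PWV from a reconstructed cine stack
#'
#' The full QA pipeline on one slice: voxel-wise velocity fitting with R^2
#' exclusion, semi-automatic lumen segmentation (or a supplied manual
#' series), volume-flow integration over the consensus mask, upstroke
#' detection, and the Q(A) slope fit.
#'
#' The Q(t) and A(t) series are jointly low-pass filtered (zero-phase
#' moving average) before the fit: a linear filter applied to both series
#' preserves the linear Q-A relation of the upstroke while attenuating
#' frame-to-frame segmentation noise that would otherwise dilute the
#' fitted slope.
#'
#' @param cine a reconstructed [cine_stack()]
#' @param roi an [roi_mm()]; defaults to [default_roi()] on synthetic data
#' @param lumen optional [load_manual_masks()] series to use instead of
#'   semi-automatic segmentation
#' @param mode threshold scope for [segment_semiauto()]
#' @param r2_threshold velocity goodness-of-fit cutoff
#' @param qa_lowpass odd moving-average window applied to both Q(t) and
#'   A(t)
#' @param crop crop the stack to a window around the roi before analysis
#'   (identical results, much faster)
#' @return a `pwv_estimate` with the lumen series and flow table attached
#' @export
pwv_qa <- function(cine, roi = NULL, lumen = NULL, mode = "global",
                   r2_threshold = 0.85, qa_lowpass = 5L, crop = TRUE) {
  stopifnot(inherits(cine, "cine_stack"))
  if (is.null(roi)) roi <- default_roi(cine)
  if (crop) cine <- crop_cine(cine, roi)
  vel <- fit_velocity(cine, r2_threshold = r2_threshold)
  manual <- !is.null(lumen)
  if (!manual) lumen <- segment_semiauto(cine, roi, mode = mode)
  a <- lumen$area_mm2
  mask <- if (manual) lumen$masks[, , , 1] != 0 else lumen_mask_consensus(lumen)
  flow <- compute_flow(vel, mask)
  q <- flow$Q_mm3s
  if (qa_lowpass > 1L && !anyNA(q)) {
    q <- lowpass_area(q, qa_lowpass)
    a <- lowpass_area(a, qa_lowpass)
  }
  window <- detect_upstroke(q)
  est <- fit_qa(q, a, window)
  est$lumen <- lumen
  est$flow <- flow
  est
}

#' Full QA reconstruction-and-analysis pipeline for one slice
#'
#' Reconstructs the k-t data twice: once at the standard zero-fill matrix
#' for velocity mapping and flow integration, and once at a high
#' zero-fill factor (21 um pixels by default) with Fermi apodization for
#' the semi-automatic area segmentation — the area pulse of a murine
#' aorta moves the wall by well under one acquisition pixel per frame, so
#' the segmentation needs the finely interpolated, ringing-suppressed
#' edge to track it. Both reconstructions are evaluated only on a window
#' around the vessel (exact partial DFT), which keeps the high-resolution
#' pass cheap. Flow is integrated over the full search disk without
#' invalid-pixel infill: stationary pixels contribute ~0 so the inclusive
#' mask is unbiased and captures the blurred flow tails at the lumen
#' edge. Q(t) and A(t) are then jointly low-passed with the same window
#' and the early-systolic Q(A) slope is fitted.
#'
#' @param kt a [kt_data()], fully sampled or lattice-undersampled
#' @param method `"full"` (requires fully sampled data) or `"ktblast"`
#' @param roi an [roi_mm()]; defaults to the phantom truth carried in the
#'   k-t metadata
#' @param zerofill_seg zero-fill matrix of the segmentation
#'   reconstruction
#' @param mode threshold scope for [segment_semiauto()]
#' @param qa_lowpass odd moving-average window for Q(t) and A(t)
#' @param r2_threshold velocity goodness-of-fit cutoff
#' @return a `pwv_estimate` with the lumen series and flow table attached
#' @export
qa_pipeline <- function(kt, method = c("full", "ktblast"), roi = NULL,
                        zerofill_seg = 1024L, mode = "global",
                        qa_lowpass = NULL, r2_threshold = 0.85) {
  method <- match.arg(method)
  stopifnot(inherits(kt, "kt_data"))
  if (is.null(roi)) {
    tr <- kt$meta$truth
    if (is.null(tr)) stop("no ground truth in the k-t metadata; supply an roi_mm()")
    roi <- roi_mm(unlist(tr$center_mm), max(unlist(tr$R_mm)) + 0.4)
  }
  crop <- list(center_mm = roi$center_mm, half_width_mm = 1.6 * roi$radius_mm)
  recon <- switch(method, full = reconstruct_full,
                  ktblast = function(kt, zf, crop_mm, apodize)
                    reconstruct_ktblast(kt, zerofill_matrix = zf,
                                        crop_mm = crop_mm, apodize = apodize))
  cine_vel <- recon(kt, kt$params$zerofill_matrix, crop, "none")
  cine_seg <- recon(kt, as.integer(zerofill_seg), crop, "fermi")
  vel <- fit_velocity(cine_vel, r2_threshold = r2_threshold)
  lumen <- segment_semiauto(cine_seg, roi, mode = mode)
  disk <- roi_disk(dim(cine_vel$data), cine_vel$pixel_mm, cine_vel$origin_mm, roi)
  flow <- compute_flow(vel, disk, infill = FALSE)
  q <- flow$Q_mm3s
  a <- lumen$area_mm2
  if (is.null(qa_lowpass)) qa_lowpass <- 5L
  if (qa_lowpass > 1L && !anyNA(q)) {
    q <- lowpass_area(q, qa_lowpass)
    a <- lowpass_area(a, qa_lowpass)
  }
  window <- detect_upstroke(q)
  est <- fit_qa(q, a, window)
  est$lumen <- lumen
  est$flow <- flow
  est
}
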