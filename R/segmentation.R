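# Semi-automatic lumen segmentation.
#
# The three flow-encoding magnitude images of the same slice should
# segment identically; operator-free threshold selection exploits this by
# choosing the threshold tau that minimises the variance of the
# thresholded pixel counts across the encodings:
#
#   tau* = arg min_tau  E[ (P(tau) - E[P(tau)])^2 ]
#
# with P(tau) = (P_1, P_2, P_3) the per-encoding counts. Magnitudes are
# first normalised per encoding (99.5th percentile) so a single tau is
# comparable across encodings despite inflow-scaling differences. The
# variance is a population variance over the encodings; saturated
# thresholds — those whose masks keep (almost) the entire search region,
# or are empty in every encoding — are excluded from the arg-min, since
# their small variance reflects a threshold below the background floor,
# not segmentation agreement.

#' Region of interest for lumen search
#'
#' @param center_mm vessel centre (y, x) in mm
#' @param radius_mm search radius in mm
#' @return an object of class `roi_mm`
#' @export
roi_mm <- function(center_mm, radius_mm) {
  stopifnot(length(center_mm) == 2L, radius_mm > 0)
  structure(list(center_mm = center_mm, radius_mm = radius_mm), class = "roi_mm")
}

#' Default region of interest of a synthetic stack
#'
#' Centred on the phantom's true vessel centre with a margin beyond its
#' maximal radius. Real data require an explicit [roi_mm()].
#'
#' @param cine a [cine_stack()] carrying a ground-truth record
#' @param margin_mm search margin beyond the maximal lumen radius
#' @return an [roi_mm()]
#' @export
default_roi <- function(cine, margin_mm = 0.4) {
  if (is.null(cine$truth)) stop("no ground truth present; supply an roi_mm()")
  roi_mm(unlist(cine$truth$center_mm), max(unlist(cine$truth$R_mm)) + margin_mm)
}

# Logical disk of roi membership on the pixel grid of a stack.
roi_disk <- function(dims, pixel_mm, origin_mm, roi) {
  y <- origin_mm[1] + (seq_len(dims[1]) - 0.5) * pixel_mm - roi$center_mm[1]
  x <- origin_mm[2] + (seq_len(dims[2]) - 0.5) * pixel_mm - roi$center_mm[2]
  outer(y^2, x^2, `+`) <= roi$radius_mm^2
}

# Magnitude standardisation before thresholding.
#
# "anchored" (default): per encoding, the static tissue level (25th
# percentile pooled over frames) is mapped to 0 and, per frame, the lumen
# level to 1. A fixed threshold then sits at a fixed fraction of the
# tissue-to-lumen edge in every frame, so inflow enhancement of the lumen
# does not move the segmentation contour — a fixed absolute threshold
# would otherwise inflate systolic areas as the brightening lumen drags
# partial-volume edge pixels above it. The lumen level is the mean over a
# fixed core disk at the search-region centre (always deep inside the
# lumen), never an upper percentile or top-k statistic of the window:
# those creep upwards as the lumen dilates, even at constant brightness,
# and the spurious adaptation attenuates the measured area pulse. Without
# a region of interest, the brightest fixed 2% of window pixels is used
# as a fallback.
#
# "encoding": plain per-encoding scaling to the 99.5th percentile, the
# frame-invariant alternative.
normalize_magnitude <- function(cine, prob = 0.995,
                                method = c("anchored", "encoding"),
                                tissue_prob = 0.25, roi = NULL,
                                core_frac = 0.35, lumen_frac = 0.02) {
  method <- match.arg(method)
  d <- dim(cine$data)
  mag <- Mod(cine$data)
  scale <- numeric(d[4])
  core <- NULL
  if (method == "anchored" && !is.null(roi)) {
    core <- roi_disk(d, cine$pixel_mm, cine$origin_mm,
                     roi_mm(roi$center_mm, core_frac * roi$radius_mm))
  }
  n_top <- max(9L, round(lumen_frac * prod(d[1:2])))
  for (k in seq_len(d[4])) {
    if (method == "encoding") {
      scale[k] <- stats::quantile(mag[, , , k], prob, names = FALSE)
      mag[, , , k] <- mag[, , , k] / scale[k]
    } else {
      t0 <- stats::quantile(mag[, , , k], tissue_prob, names = FALSE)
      for (t in seq_len(d[3])) {
        lt <- if (is.null(core))
          mean(sort(mag[, , t, k], decreasing = TRUE)[seq_len(n_top)])
        else mean(mag[, , t, k][core])
        mag[, , t, k] <- (mag[, , t, k] - t0) / (lt - t0)
      }
      scale[k] <- t0
    }
  }
  list(mag = mag, scale = scale, method = method)
}

#' Threshold a magnitude image within a search region
#'
#' Pixels at or above `tau` inside the region are kept and restricted to
#' the connected component containing the region centre (or, if the centre
#' pixel is below threshold, the component nearest to it). An empty result
#' is returned as an empty mask, not an error.
#'
#' @param mag 2D magnitude image (normalised to `[0, 1]`-scale units)
#' @param tau threshold
#' @param roi an [roi_mm()]
#' @param pixel_mm pixel size of `mag`
#' @param origin_mm physical offset of `mag`
#' @param fill_holes apply morphological hole filling to the component
#' @return logical matrix of lumen membership
#' @export
mask_at_threshold <- function(mag, tau, roi, pixel_mm, origin_mm = c(0, 0),
                              fill_holes = FALSE) {
  disk <- roi_disk(dim(mag), pixel_mm, origin_mm, roi)
  cand <- (mag >= tau) & disk
  if (!any(cand)) return(cand)
  lab <- EBImage::bwlabel(cand)
  cy <- (roi$center_mm[1] - origin_mm[1]) / pixel_mm + 0.5
  cx <- (roi$center_mm[2] - origin_mm[2]) / pixel_mm + 0.5
  icy <- min(max(round(cy), 1L), nrow(mag))
  icx <- min(max(round(cx), 1L), ncol(mag))
  id <- lab[icy, icx]
  if (id == 0) {
    w <- which(cand, arr.ind = TRUE)
    d2 <- (w[, 1] - cy)^2 + (w[, 2] - cx)^2
    id <- lab[w[which.min(d2), , drop = FALSE]]
  }
  out <- lab == id
  if (fill_holes) out <- EBImage::fillHull(out) > 0
  out
}

# Suprathreshold pixel counts inside the roi for a vector of thresholds,
# without the connected-component restriction (used by the cost search).
# Returns an array (n_tau, n_frames, n_enc).
roi_count_curves <- function(mag, disk, tau) {
  d <- dim(mag)
  nroi <- sum(disk)
  out <- array(0L, dim = c(length(tau), d[3], d[4]))
  for (t in seq_len(d[3])) for (k in seq_len(d[4])) {
    vals <- sort(mag[, , t, k][disk])
    out[, t, k] <- nroi - findInterval(tau - 1e-12, vals)
  }
  out
}

#' Inter-encoding variance cost of a segmentation threshold
#'
#' The population variance, across flow encodings, of the number of
#' suprathreshold pixels in the search region. In `global` mode the
#' variance is averaged over frames (one cost curve per slice); in
#' `per_frame` mode a curve is returned per frame.
#'
#' @param cine a [cine_stack()] with at least two encodings
#' @param tau numeric vector of thresholds (normalised magnitude units)
#' @param roi an [roi_mm()]
#' @param mode `"global"` or `"per_frame"`
#' @return numeric vector (global) or matrix `n_tau x n_frames`
#' @export
variance_cost <- function(cine, tau, roi, mode = c("global", "per_frame"),
                          normalize = c("anchored", "encoding")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cine, "cine_stack"))
  if (dim(cine$data)[4] < 2L) stop("at least two encodings are required")
  nm <- normalize_magnitude(cine, method = match.arg(normalize), roi = roi)
  disk <- roi_disk(dim(nm$mag), cine$pixel_mm, cine$origin_mm, roi)
  counts <- roi_count_curves(nm$mag, disk, tau)
  pvar <- apply(counts, c(1, 2), function(p) mean((p - mean(p))^2))
  if (mode == "global") rowMeans(pvar) else pvar
}

# Arg-min with plateau-midpoint tie-break over candidate indices; warns if
# the plateau touches the candidate boundary. The cost is a population
# variance over very few encodings (typically 3), whose sampling noise is
# of the order of the value itself, so the arg-min alone is unstable
# inside the broad low-cost valley between the tissue and lumen intensity
# modes. Costs within a small fraction of the curve's dynamic range above
# the minimum (plus the variance quantum of integer counts) are therefore
# treated as ties, and the midpoint of the contiguous tie run containing
# the arg-min — in practice the centre of the valley — is returned.
argmin_plateau <- function(cost, candidates, tie_range = 0.05, tie_abs = 1) {
  idx <- which(candidates)
  if (!length(idx)) idx <- seq_along(cost)
  cmin <- min(cost[idx])
  cmax <- max(cost[idx])
  tie <- cost[idx] <= cmin + max(tie_range * (cmax - cmin), tie_abs * (cmax > cmin))
  imin <- which.min(cost[idx])
  runs <- rle(tie)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run <- which(runs$values & starts <= imin & imin <= ends)[1]
  lo <- starts[run]; hi <- ends[run]
  if (lo == 1L || hi == length(idx))
    warning("segmentation cost minimum lies at the threshold-grid boundary")
  idx[round((lo + hi) / 2)]
}

#' Semi-automatic lumen segmentation of a cine stack
#'
#' Evaluates the inter-encoding variance cost on a dense threshold grid
#' (default 256 levels spanning 0.05-0.95 of the normalised magnitude),
#' picks the arg-min threshold (plateau midpoint on ties; saturated
#' thresholds excluded), and builds per-frame, per-encoding binary masks at
#' that threshold, each restricted to the connected component anchored at
#' the region centre. The cross-sectional area series is the mean pixel
#' count over encodings times the pixel area.
#'
#' The evaluated cost is smoothed along the threshold axis (moving
#' average, `cost_smooth` grid steps) before the arg-min: the pixel counts
#' are staircase functions whose variance estimate over a handful of
#' encodings is noisy, and the smoothing scale matches the magnitude-noise
#' correlation length of that staircase. Set `cost_smooth = 1`,
#' `tie_range = 0` and `tie_abs = 0` for the bare grid arg-min.
#'
#' @param cine a [cine_stack()]
#' @param roi an [roi_mm()]; defaults to [default_roi()] on synthetic data
#' @param mode one threshold per slice (`"global"`, the default) or per
#'   frame (`"per_frame"`)
#' @param tau threshold grid
#' @param cost_smooth odd moving-average window (grid steps) applied to
#'   the cost curve before minimisation
#' @param tie_range,tie_abs tie band of the plateau-midpoint rule: costs
#'   within `min + max(tie_range * (max - min), tie_abs)` count as ties
#' @param fill_holes apply hole filling to the final masks
#' @return an object of class `lumen_series` with `masks` (y, x, frame,
#'   encoding), `tau`, `pixel_counts` (frame x encoding), `area_mm2`,
#'   `time_ms`, `roi` and `mode`
#' @export
segment_semiauto <- function(cine, roi = NULL, mode = c("global", "per_frame"),
                             tau = seq(0.05, 0.95, length.out = 256),
                             normalize = c("anchored", "encoding"),
                             cost_smooth = 21L, tie_range = 0.05, tie_abs = 1,
                             fill_holes = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cine, "cine_stack"))
  if (is.null(roi)) roi <- default_roi(cine)
  d <- dim(cine$data)
  nm <- normalize_magnitude(cine, method = match.arg(normalize), roi = roi)
  disk <- roi_disk(d, cine$pixel_mm, cine$origin_mm, roi)
  nroi <- sum(disk)
  counts <- roi_count_curves(nm$mag, disk, tau)
  pvar <- apply(counts, c(1, 2), function(p) mean((p - mean(p))^2))
  # a threshold keeping > 95% of the search region (or nothing at all)
  # does not segment; its variance is uninformative
  not_saturated <- function(ct) {
    apply(ct, 1, mean) <= 0.95 * nroi & !apply(ct == 0L, 1, all)
  }
  smooth <- function(cost) {
    if (cost_smooth > 1L) lowpass_area(cost, cost_smooth) else cost
  }
  if (mode == "global") {
    tau_star <- tau[argmin_plateau(smooth(rowMeans(pvar)), not_saturated(counts),
                                   tie_range, tie_abs)]
    tau_frame <- rep(tau_star, d[3])
  } else {
    tau_frame <- numeric(d[3])
    for (t in seq_len(d[3])) {
      ct <- counts[, t, , drop = FALSE]
      dim(ct) <- c(length(tau), d[4])
      tau_frame[t] <- tau[argmin_plateau(smooth(pvar[, t]), not_saturated(ct),
                                         tie_range, tie_abs)]
    }
    tau_star <- tau_frame
  }
  masks <- array(FALSE, dim = d)
  pixel_counts <- matrix(0L, d[3], d[4])
  for (t in seq_len(d[3])) for (k in seq_len(d[4])) {
    mk <- mask_at_threshold(nm$mag[, , t, k], tau_frame[t], roi,
                            cine$pixel_mm, cine$origin_mm, fill_holes)
    masks[, , t, k] <- mk
    pixel_counts[t, k] <- sum(mk)
  }
  structure(list(masks = masks, tau = tau_star, tau_grid = tau,
                 pixel_counts = pixel_counts,
                 area_mm2 = rowMeans(pixel_counts) * cine$pixel_mm^2,
                 time_ms = (seq_len(d[3]) - 1) *
                   effective_temporal_resolution(cine$params),
                 pixel_mm = cine$pixel_mm, roi = roi, mode = mode),
            class = "lumen_series")
}

#' @export
print.lumen_series <- function(x, ...) {
  cat(sprintf("lumen series: %d frames x %d encodings, tau = %s (%s)\n",
              nrow(x$pixel_counts), ncol(x$pixel_counts),
              paste(signif(unique(x$tau), 3), collapse = "/"), x$mode))
  cat(sprintf("  area %.3f - %.3f mm^2\n", min(x$area_mm2), max(x$area_mm2)))
  invisible(x)
}

#' Majority-vote lumen mask across encodings
#'
#' @param lumen a [segment_semiauto()] or [load_manual_masks()] result
#' @return logical array (y, x, frame)
#' @export
lumen_mask_consensus <- function(lumen) {
  stopifnot(inherits(lumen, "lumen_series"))
  d <- dim(lumen$masks)
  votes <- apply(lumen$masks, c(1, 2, 3), sum)
  votes >= (d[4] + 1) / 2
}

#' Zero-phase moving-average filter for area series
#'
#' Symmetric moving average with reflective boundary handling; a window of
#' 1 is the identity. Used to low-pass manually segmented area series
#' before the QA fit.
#'
#' @param x numeric series
#' @param window odd window length in frames
#' @return filtered series of the same length
#' @export
lowpass_area <- function(x, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window > length(x)) stop("window exceeds the series length")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  xp <- c(x[h:1], x, x[length(x):(length(x) - h + 1L)])
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1L):(h + length(x))]
}

#' Ingest manually segmented lumen masks
#'
#' Accepts a logical/0-1 array (y, x, frame) or the path of a NIfTI label
#' volume, and returns the corresponding area series as a single-encoding
#' `lumen_series`.
#'
#' @param masks 3D array or NIfTI file path
#' @param pixel_mm pixel size of the mask grid (mm)
#' @param n_frames expected frame count; a mismatch is an error
#' @param time_ms optional frame times
#' @return a `lumen_series` with one encoding
#' @export
load_manual_masks <- function(masks, pixel_mm, n_frames = NULL, time_ms = NULL) {
  if (is.character(masks)) {
    m <- RNifti::readNifti(masks)
    masks <- array(as.vector(m), dim = dim(m))
  }
  if (length(dim(masks)) != 3L) stop("masks must be a 3D (y, x, frame) volume")
  if (!is.null(n_frames) && dim(masks)[3] != n_frames)
    stop("mask frame count (", dim(masks)[3], ") does not match the cine (", n_frames, ")")
  masks <- masks != 0
  counts <- apply(masks, 3, sum)
  structure(list(masks = array(masks, dim = c(dim(masks), 1L)),
                 tau = NA_real_, tau_grid = numeric(),
                 pixel_counts = matrix(as.integer(counts), ncol = 1L),
                 area_mm2 = counts * pixel_mm^2,
                 time_ms = time_ms %||% (seq_len(dim(masks)[3]) - 1),
                 pixel_mm = pixel_mm, roi = NULL, mode = "manual"),
            class = "lumen_series")
}
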