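#' Acquisition parameters for a phase-contrast cine experiment
#'
#' Bundles the geometry and timing of a 2D through-plane flow-encoded
#' PC-CINE acquisition: field of view, acquired and zero-filled matrix
#' sizes, repetition time, the number of time-shifted interleaved
#' repetitions used to boost the effective temporal resolution, the first
#' gradient moments of the flow-encoding steps, and the k-t undersampling
#' configuration (lattice acceleration factor and number of central
#' training lines).
#'
#' Defaults reproduce a murine abdominal-aorta protocol: 22 mm field of
#' view, 150 acquired lines zero-filled to 256 (86 um pixels), native
#' TR 5 ms with 5 interleaves (1 ms effective frame spacing), 40 cine
#' frames, through-plane first moments (-0.3, 0, +0.3) s/m, lattice
#' acceleration r = 10 with 10 central training lines.
#'
#' @param fov_mm field of view along each in-plane axis (mm)
#' @param matrix acquired matrix size (lines = columns)
#' @param zerofill_matrix reconstructed matrix size after zero-filling
#' @param tr_ms native repetition time (ms)
#' @param n_shots number of time-shifted interleaved repetitions
#' @param n_frames number of cine frames
#' @param moments_s_per_m first gradient moments, one per flow encoding
#'   (s/m); must contain exactly one zero (flow-compensated) entry and at
#'   least two distinct values
#' @param r_accel k-t lattice undersampling factor (integer >= 1)
#' @param n_train number of central training k-space lines
#' @return an object of class `acq_params`
#' @examples
#' p <- acquisition_params()
#' effective_temporal_resolution(p)  # 1 ms
#' @export
acquisition_params <- function(fov_mm = 22, matrix = 150L, zerofill_matrix = 256L,
                               tr_ms = 5, n_shots = 5L, n_frames = 40L,
                               moments_s_per_m = c(-0.3, 0, 0.3),
                               r_accel = 10L, n_train = 10L) {
  matrix <- as.integer(matrix)
  zerofill_matrix <- as.integer(zerofill_matrix)
  if (matrix < 2L) stop("matrix must be >= 2")
  if (zerofill_matrix < matrix) stop("zerofill_matrix must be >= matrix")
  if (fov_mm <= 0 || tr_ms <= 0) stop("fov_mm and tr_ms must be positive")
  if (n_shots < 1L || n_frames < 1L) stop("n_shots and n_frames must be >= 1")
  if (sum(moments_s_per_m == 0) != 1L)
    stop("moments_s_per_m must contain exactly one zero (flow-compensated) entry")
  if (length(unique(moments_s_per_m)) < 2L)
    stop("moments_s_per_m must contain at least two distinct values")
  if (r_accel < 1L) stop("r_accel must be >= 1")
  if (n_train < 1L) stop("n_train must be >= 1")
  structure(list(
    fov_mm = fov_mm, matrix = matrix, zerofill_matrix = zerofill_matrix,
    tr_ms = tr_ms, n_shots = as.integer(n_shots), n_frames = as.integer(n_frames),
    moments_s_per_m = moments_s_per_m, r_accel = as.integer(r_accel),
    n_train = as.integer(n_train)
  ), class = "acq_params")
}

#' Effective cine frame spacing after interleaving
#'
#' Time-shifted repetition of the cine acquisition divides the native TR
#' into `n_shots` interleaved frames: 5 shots at TR 5 ms give 1 ms frames.
#'
#' @param params an [acquisition_params()] object
#' @return frame spacing in ms
#' @export
effective_temporal_resolution <- function(params) {
  stopifnot(inherits(params, "acq_params"))
  params$tr_ms / params$n_shots
}

#' Velocity-encoding limit of a flow-encoding moment
#'
#' Under the phase convention phi = 2 pi m v (m in s/m, v in m/s), the
#' phase reaches +/- pi at v = 1/(2|m|); faster flow wraps.
#'
#' @param moment_s_per_m nonzero first gradient moment (s/m)
#' @return the velocity limit in m/s
#' @export
venc <- function(moment_s_per_m) {
  if (any(moment_s_per_m == 0)) stop("venc is undefined for a zero moment")
  1 / (2 * abs(moment_s_per_m))
}

#' Pulsatile-vessel phantom specification
#'
#' Describes a compliant tube with pulsatile parabolic through-plane flow
#' and a known ground-truth pulse wave velocity. The phantom is built so
#' that on the systolic upstroke the volume flow is exactly
#' `Q(t) = q_base + 1000 * pwv_true * (A(t) - area_base)` (Q in mm^3/s, A in
#' mm^2), i.e. the QA-slope dQ/dA equals `pwv_true` by construction.
#'
#' Magnitude inside the lumen is enhanced linearly with the instantaneous
#' mean velocity (inflow effect); `inflow_gain` may be a scalar or one
#' value per flow encoding (the three encodings are acquired sequentially,
#' so their enhancement can differ slightly).
#'
#' @param pwv_true ground-truth pulse wave velocity (m/s)
#' @param area_base_mm2 diastolic lumen cross-sectional area (mm^2)
#' @param area_pulse_mm2 systolic area increase (mm^2)
#' @param q_base_mm3s baseline (diastolic) volume flow (mm^3/s)
#' @param center_mm vessel centre (y, x) in mm from the image corner;
#'   `NULL` places it slightly off the field-of-view centre
#' @param upstroke_frames first and last frame (1-based) of the systolic
#'   rise of the waveform
#' @param snr magnitude signal-to-noise ratio in the lumen (may be `Inf`
#'   for noiseless simulation)
#' @param inflow_gain magnitude enhancement per unit mean lumen velocity
#'   (s/m); scalar or one value per encoding
#' @param tissue_frac static tissue magnitude as a fraction of the lumen
#'   baseline
#' @param seed RNG seed controlling the noise draw
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(pwv_true = 3.5, area_base_mm2 = 0.8, area_pulse_mm2 = 0.1,
                         q_base_mm3s = 20, center_mm = NULL,
                         upstroke_frames = c(6L, 15L),
                         snr = 30, inflow_gain = 0.3, tissue_frac = 0.35,
                         seed = 1L) {
  if (pwv_true <= 0) stop("pwv_true must be positive")
  if (area_base_mm2 <= 0) stop("area_base_mm2 must be positive")
  if (area_pulse_mm2 < 0) stop("area_pulse_mm2 must be >= 0")
  if (snr <= 0) stop("snr must be positive")
  if (length(upstroke_frames) != 2L || diff(upstroke_frames) < 2L)
    stop("upstroke_frames must be two frames spanning at least 3 frames")
  structure(list(
    pwv_true = pwv_true, area_base_mm2 = area_base_mm2,
    area_pulse_mm2 = area_pulse_mm2, q_base_mm3s = q_base_mm3s,
    center_mm = center_mm, upstroke_frames = as.integer(upstroke_frames),
    snr = snr, inflow_gain = inflow_gain, tissue_frac = tissue_frac,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("PC-CINE acquisition: FOV %g mm, matrix %d -> %d (pixel %.1f um)\n",
              x$fov_mm, x$matrix, x$zerofill_matrix,
              1000 * x$fov_mm / x$zerofill_matrix))
  cat(sprintf("  TR %g ms x %d shots -> %g ms frames, %d frames\n",
              x$tr_ms, x$n_shots, effective_temporal_resolution(x), x$n_frames))
  cat(sprintf("  moments: %s s/m; k-t lattice r = %d, %d training lines\n",
              paste(x$moments_s_per_m, collapse = ", "), x$r_accel, x$n_train))
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Pulsatile vessel phantom: PWV %g m/s, A %g + %g mm^2, Q_base %g mm^3/s\n",
              x$pwv_true, x$area_base_mm2, x$area_pulse_mm2, x$q_base_mm3s))
  cat(sprintf("  SNR %g, inflow gain %s s/m, seed %d\n",
              x$snr, paste(x$inflow_gain, collapse = "/"), x$seed))
  invisible(x)
}
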