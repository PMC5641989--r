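#' Construct a phase-contrast cine image stack
#'
#' The central image currency of the package: a complex-valued array indexed
#' (y, x, frame, encoding) together with its acquisition parameters, the
#' derived pixel size, and (for synthetic data) an optional ground-truth
#' record. `origin_mm` locates the first pixel corner in physical
#' coordinates so that cropped stacks keep a consistent coordinate frame:
#' the centre of pixel (i, j) is at
#' `origin_mm + (c(i, j) - 0.5) * pixel_mm`.
#'
#' @param data complex array with dims (y, x, frame, encoding)
#' @param params an [acquisition_params()] object
#' @param pixel_mm pixel size (mm); defaults to `fov_mm / nrow(data)`
#' @param origin_mm physical (y, x) offset of the array origin (mm)
#' @param truth optional ground-truth record (see [simulate_truth()])
#' @param flags optional named list of quality flags
#' @return an object of class `cine_stack`
#' @export
cine_stack <- function(data, params, pixel_mm = NULL, origin_mm = c(0, 0),
                       truth = NULL, flags = list()) {
  stopifnot(inherits(params, "acq_params"))
  if (length(dim(data)) != 4L)
    stop("data must be a 4D (y, x, frame, encoding) array")
  if (dim(data)[4] != length(params$moments_s_per_m))
    stop("encoding axis length must equal the number of moments")
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("cine data must be finite")
  if (is.null(pixel_mm)) pixel_mm <- params$fov_mm / dim(data)[1]
  structure(list(data = data, params = params, pixel_mm = pixel_mm,
                 origin_mm = origin_mm, truth = truth, flags = flags),
            class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("PC-CINE stack: %d x %d pixels (%.1f um), %d frames, %d encodings\n",
              d[1], d[2], 1000 * x$pixel_mm, d[3], d[4]))
  if (!is.null(x$truth))
    cat(sprintf("  synthetic, ground-truth PWV %.3g m/s\n", x$truth$pwv_true))
  if (isTRUE(x$flags$velocity_aliasing))
    cat("  flag: velocity phase exceeds +/- pi somewhere (aliasing)\n")
  invisible(x)
}

#' Crop a cine stack to a window around a region of interest
#'
#' Returns the sub-stack covering `roi` expanded by `margin` times its
#' radius, with `origin_mm` updated so physical coordinates are preserved.
#'
#' @param cine a [cine_stack()]
#' @param roi a region of interest from [roi_mm()]
#' @param margin window half-width as a multiple of the roi radius
#' @return a cropped `cine_stack`
#' @export
crop_cine <- function(cine, roi, margin = 2) {
  px <- cine$pixel_mm
  d <- dim(cine$data)
  half <- margin * roi$radius_mm
  cy <- (roi$center_mm[1] - cine$origin_mm[1]) / px + 0.5
  cx <- (roi$center_mm[2] - cine$origin_mm[2]) / px + 0.5
  iy <- max(1L, floor(cy - half / px)):min(d[1], ceiling(cy + half / px))
  ix <- max(1L, floor(cx - half / px)):min(d[2], ceiling(cx + half / px))
  cine_stack(cine$data[iy, ix, , , drop = FALSE], cine$params,
             pixel_mm = px,
             origin_mm = cine$origin_mm + c(iy[1] - 1L, ix[1] - 1L) * px,
             truth = cine$truth, flags = cine$flags)
}

#' Write a cine stack as NIfTI volumes plus a JSON sidecar
#'
#' Magnitude and phase are written as two 4D NIfTI volumes with dims
#' (y, x, frame, encoding); acquisition parameters, pixel geometry and any
#' ground-truth record go to `sidecar.json`.
#'
#' @param cine a [cine_stack()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cine <- function(cine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(Mod(cine$data), pixdim = rep(cine$pixel_mm, 2)),
                     file.path(dir, "magnitude.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Arg(cine$data), pixdim = rep(cine$pixel_mm, 2)),
                     file.path(dir, "phase.nii.gz"))
  side <- list(params = unclass(cine$params), pixel_mm = cine$pixel_mm,
               origin_mm = cine$origin_mm,
               frame_spacing_ms = effective_temporal_resolution(cine$params),
               truth = cine$truth, flags = cine$flags)
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cine stack written by [write_cine()]
#'
#' @param dir directory containing `magnitude.nii.gz`, `phase.nii.gz` and
#'   `sidecar.json`
#' @return a [cine_stack()]
#' @export
read_cine <- function(dir) {
  strip <- function(x) array(as.vector(x), dim = dim(x))
  mag <- strip(RNifti::readNifti(file.path(dir, "magnitude.nii.gz")))
  ph <- strip(RNifti::readNifti(file.path(dir, "phase.nii.gz")))
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  p <- side$params
  params <- acquisition_params(p$fov_mm, p$matrix, p$zerofill_matrix, p$tr_ms,
                               p$n_shots, p$n_frames, p$moments_s_per_m,
                               p$r_accel, p$n_train)
  cine_stack(mag * exp(1i * ph), params, pixel_mm = side$pixel_mm,
             origin_mm = side$origin_mm,
             truth = side$truth,
             flags = if (length(side$flags)) as.list(side$flags) else list())
}
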