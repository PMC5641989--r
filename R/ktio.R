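#' Write a k-t data container to disk
#'
#' The complex samples are stored as paired real/imaginary 4D NIfTI
#' volumes, the sampling pattern (combined mask, lattice mask) as CSV, and
#' the acquisition parameters plus training-line indices as JSON.
#'
#' @param kt a [kt_data()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_ktdata <- function(kt, dir) {
  stopifnot(inherits(kt, "kt_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(Re(kt$kdata)), file.path(dir, "kdata_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(kt$kdata)), file.path(dir, "kdata_imag.nii.gz"))
  if (!is.null(kt$pattern)) {
    utils::write.csv(kt$pattern$mask, file.path(dir, "pattern_mask.csv"), row.names = FALSE)
    utils::write.csv(kt$pattern$lattice, file.path(dir, "pattern_lattice.csv"), row.names = FALSE)
  }
  meta <- list(params = unclass(kt$params),
               r = if (is.null(kt$pattern)) 1L else kt$pattern$r,
               train_idx = kt$pattern$train_idx,
               truth = kt$meta$truth)
  jsonlite::write_json(meta, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a k-t data container written by [write_ktdata()]
#'
#' @param dir directory produced by [write_ktdata()]
#' @return a [kt_data()]
#' @export
read_ktdata <- function(dir) {
  strip <- function(x) array(as.vector(x), dim = dim(x))
  re <- strip(RNifti::readNifti(file.path(dir, "kdata_real.nii.gz")))
  im <- strip(RNifti::readNifti(file.path(dir, "kdata_imag.nii.gz")))
  meta <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  p <- meta$params
  params <- acquisition_params(p$fov_mm, p$matrix, p$zerofill_matrix, p$tr_ms,
                               p$n_shots, p$n_frames, p$moments_s_per_m,
                               p$r_accel, p$n_train)
  pattern <- NULL
  mask_file <- file.path(dir, "pattern_mask.csv")
  if (file.exists(mask_file) && meta$r >= 1L) {
    pattern <- make_lattice_pattern(dim(re)[1], meta$r, length(meta$train_idx),
                                    dim(re)[3])
    stored <- as.matrix(utils::read.csv(mask_file))
    dimnames(stored) <- NULL
    if (!all(stored == pattern$mask))
      stop("stored sampling mask is not the lattice implied by params.json")
  }
  kt_data(re + 1i * im, pattern, params, meta = list(truth = meta$truth))
}
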