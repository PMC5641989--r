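# Shared fixtures. Everything is generated in code at test time; the more
# expensive standard phantom acquisitions are cached per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Paper-protocol acquisition.
std_params <- function() acquisition_params()

# Small acquisition for algebraic tests (lattice commensurate: r | lines,
# r | frames).
small_params <- function() {
  acquisition_params(fov_mm = 22, matrix = 20L, zerofill_matrix = 24L,
                     n_frames = 8L, r_accel = 4L, n_train = 4L)
}

# Standard noisy phantom and its fully sampled k-t data (seed 1, SNR 30).
std_kt <- function() {
  memo("std_kt", {
    suppressWarnings(encode_kspace(render_cine(phantom_spec(seed = 1L),
                                               std_params())))
  })
}

# Noiseless counterpart.
std_kt_clean <- function() {
  memo("std_kt_clean", {
    suppressWarnings(encode_kspace(render_cine(phantom_spec(seed = 1L, snr = Inf),
                                               std_params())))
  })
}

roi_of <- function(kt) {
  tr <- kt$meta$truth
  roi_mm(unlist(tr$center_mm), max(unlist(tr$R_mm)) + 0.4)
}

quiet <- function(expr) suppressWarnings(expr)

# Random complex array helper.
rcomplex <- function(dim) {
  array(complex(real = rnorm(prod(dim)), imaginary = rnorm(prod(dim))), dim = dim)
}
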