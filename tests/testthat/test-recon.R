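test_that("lattice pattern obeys the sheared-grid scheme", {
  p <- make_lattice_pattern(6L, 2L, 2L, 4L)
  # centre line (index 4 of 6, 1-based) sampled in frame 1, lattice offset
  # advances by one line per frame
  expect_equal(which(p$lattice[, 1] == 1L), c(2L, 4L, 6L))
  expect_equal(which(p$lattice[, 2] == 1L), c(1L, 3L, 5L))
  expect_equal(which(p$lattice[, 3] == 1L), c(2L, 4L, 6L))
  # training lines are the most central, sampled in every frame
  expect_true(all(p$mask[p$train_idx, ] == 1L))
  expect_error(make_lattice_pattern(6L, 7L, 2L, 4L), "r must")
})

test_that("r = 1 pattern is fully sampled with acceleration 1", {
  p <- make_lattice_pattern(150L, 1L, 10L, 40L)
  expect_true(all(p$mask == 1L))
  expect_equal(effective_acceleration(p), 1)
})

test_that("paper protocol yields 6-fold effective acceleration", {
  p <- make_lattice_pattern(150L, 10L, 10L, 40L)
  expect_equal(unique(colSums(p$lattice)), 15)
  expect_equal(effective_acceleration(p), 6)
})

test_that("undersampling copies sampled entries and zeroes the rest", {
  set.seed(7)
  kd <- rcomplex(c(20, 8, 8, 2))
  kt <- kt_data(kd, NULL, small_params())
  p <- make_lattice_pattern(20L, 4L, 4L, 8L)
  u <- undersample(kt, p)
  expect_true(all(u$kdata[p$mask[, 1] == 0L, , 1, ] == 0))
  expect_identical(u$kdata[p$mask[, 3] == 1L, , 3, ], kd[p$mask[, 3] == 1L, , 3, ])
  expect_lte(sum(Mod(u$kdata)^2), sum(Mod(kd)^2))
  expect_identical(undersample(u, p)$kdata, u$kdata)
  # r = 1 is the identity
  p1 <- make_lattice_pattern(20L, 1L, 4L, 8L)
  expect_identical(undersample(kt, p1)$kdata, kd)
})

test_that("centred unitary transforms round-trip and conserve energy", {
  set.seed(1)
  m <- rcomplex(c(15, 12))
  K <- ktqa:::ft2c(m)
  expect_lt(max(Mod(ktqa:::ift2c(K) - m)), 1e-12)
  expect_equal(sum(Mod(K)^2), sum(Mod(m)^2), tolerance = 1e-12)
  # constant image concentrates in the single central sample
  const <- matrix(1 + 0i, 16, 16)
  Kc <- ktqa:::ft2c(const)
  expect_equal(Mod(Kc[9, 9]), 16)
  expect_lt(max(Mod(Kc[-9, ])), 1e-12)
})

test_that("zero-filling gives the documented pixel sizes", {
  kt <- std_kt()
  rec <- reconstruct_full(kt, 256L, crop_mm = list(center_mm = c(11, 11),
                                                   half_width_mm = 1))
  expect_equal(round(1000 * rec$pixel_mm), 86)
  rec2 <- reconstruct_full(kt, 1024L, crop_mm = list(center_mm = c(11, 11),
                                                     half_width_mm = 0.5))
  expect_equal(round(1000 * rec2$pixel_mm), 21)
  expect_error(reconstruct_full(kt, 100L), "zerofill")
})

test_that("zerofill equal to the matrix is a plain inverse transform", {
  kt <- std_kt()
  rec <- reconstruct_full(kt, kt$params$matrix)
  orig <- suppressWarnings(render_cine(phantom_spec(seed = 1L), std_params()))
  expect_lt(max(Mod(rec$data - orig$data)), 1e-9)
})

test_that("cropped zoom reconstruction equals the full zero-filled image", {
  set.seed(3)
  kd <- rcomplex(c(12, 12, 2, 1))
  params <- acquisition_params(matrix = 12L, zerofill_matrix = 32L,
                               n_frames = 2L, moments_s_per_m = c(-0.3, 0, 0.3))
  kd <- array(kd[, , , c(1, 1, 1)], c(12, 12, 2, 3))
  kt <- kt_data(kd, NULL, params)
  full <- reconstruct_full(kt, 32L)
  crop <- list(center_mm = c(11, 11), half_width_mm = 5)
  part <- reconstruct_full(kt, 32L, crop_mm = crop)
  i0 <- round(part$origin_mm / part$pixel_mm)
  iy <- (i0[1] + 1):(i0[1] + dim(part$data)[1])
  ix <- (i0[2] + 1):(i0[2] + dim(part$data)[2])
  expect_lt(max(Mod(part$data - full$data[iy, ix, , ])), 1e-10)
})

test_that("training estimate of a static object concentrates at zero frequency", {
  spec <- phantom_spec(area_pulse_mm2 = 0, q_base_mm3s = 0, snr = Inf)
  kt <- encode_kspace(render_cine(spec, std_params()))
  ktu <- undersample(kt, make_lattice_pattern(150L, 10L, 10L, 40L))
  f <- train_signal_estimate(ktu, subtract_baseline = FALSE)
  M2 <- array(f$signal_estimate_sq[, , 1], c(150, 40, 150))
  dc_bin <- floor(40 / 2) + 1L
  expect_gt(sum(M2[, dc_bin, ]) / sum(M2), 0.999)
})

test_that("training estimate is quadratically homogeneous", {
  kt <- std_kt()
  ktu <- undersample(kt, make_lattice_pattern(150L, 10L, 10L, 40L))
  kt2 <- ktu
  kt2$kdata <- 2 * kt2$kdata
  f1 <- train_signal_estimate(ktu)
  f2 <- train_signal_estimate(kt2)
  expect_equal(f2$signal_estimate_sq, 4 * f1$signal_estimate_sq, tolerance = 1e-10)
})

test_that("training estimate of a single-pixel sinusoid matches the Dirichlet blur", {
  n <- 20L; nt <- 8L; f0 <- 2L
  params <- small_params()
  y0 <- 11L; x0 <- 9L
  img <- array(0i, c(n, n, nt, 3L))
  for (t in seq_len(nt)) img[y0, x0, t, ] <- cos(2 * pi * f0 * (t - 1) / nt)
  cine <- cine_stack(img, params)
  kt <- undersample(encode_kspace(cine), make_lattice_pattern(n, 4L, 4L, nt))
  f <- train_signal_estimate(kt, subtract_baseline = FALSE)
  M2 <- array(f$signal_estimate_sq[, , 1], c(n, nt, n))
  prof_f <- apply(M2, 2, sum)
  dc <- floor(nt / 2) + 1L
  peaks <- sort(order(prof_f, decreasing = TRUE)[1:2])
  expect_equal(peaks, c(dc - f0, dc + f0))
  # spatial blur along y: |Dirichlet kernel|^2 of the 4 training lines
  prof_y <- M2[, dc + f0, x0]
  tr_idx <- kt$pattern$train_idx
  ic <- floor(n / 2) + 1L
  dy <- seq_len(n) - y0
  dk <- vapply(dy, function(d) {
    s <- sum(exp(-2i * pi * (tr_idx - ic) * d / n))
    Mod(s)^2
  }, numeric(1))
  expect_gt(cor(prof_y, dk), 0.99)
})

test_that("k-t reconstruction at r = 1 equals the full reconstruction", {
  kt <- std_kt()
  p1 <- make_lattice_pattern(150L, 1L, 10L, 40L)
  ktu <- undersample(kt, p1)
  a <- reconstruct_ktblast(ktu)
  b <- reconstruct_full(kt)
  expect_lt(max(Mod(a$data - b$data)) / max(Mod(b$data)), 1e-8)
})

test_that("a static object is reconstructed exactly at r = 10", {
  spec <- phantom_spec(area_pulse_mm2 = 0, snr = Inf)
  kt <- encode_kspace(render_cine(spec, std_params()))
  ktu <- undersample(kt, make_lattice_pattern(150L, 10L, 10L, 40L))
  a <- reconstruct_ktblast(ktu)
  b <- reconstruct_full(kt)
  expect_lt(max(Mod(a$data - b$data)) / max(Mod(b$data)), 1e-6)
})

test_that("unfolding with a fixed filter is linear", {
  set.seed(11)
  params <- small_params()
  p <- make_lattice_pattern(20L, 4L, 4L, 8L)
  mk <- function() {
    kd <- rcomplex(c(20, 8, 8, 3))
    undersample(kt_data(kd, NULL, params), p)
  }
  x <- mk(); y <- mk()
  f <- train_signal_estimate(x)
  z <- x
  z$kdata <- 2 * x$kdata - 3 * y$kdata
  rz <- reconstruct_ktblast(z, filter = f, zerofill_matrix = 20L)
  rx <- reconstruct_ktblast(x, filter = f, zerofill_matrix = 20L)
  ry <- reconstruct_ktblast(y, filter = f, zerofill_matrix = 20L)
  expect_lt(max(Mod(rz$data - (2 * rx$data - 3 * ry$data))) / max(Mod(rz$data)),
            1e-9)
})

test_that("alias-coincident temporal oscillations are attenuated", {
  n <- 20L; nt <- 8L
  params <- small_params()
  y0 <- 12L; x0 <- 10L
  img <- array(0.2 + 0i, c(n, n, nt, 3L))
  f0 <- nt / 4L  # coincides with the alias shift for r = 4
  amp <- 1
  for (t in seq_len(nt)) img[y0, x0, t, ] <- 0.2 + amp * cos(2 * pi * f0 * (t - 1) / nt)
  cine <- cine_stack(img, params)
  ktu <- undersample(encode_kspace(cine), make_lattice_pattern(n, 4L, 4L, nt))
  rec <- reconstruct_ktblast(ktu, zerofill_matrix = n)
  osc <- Re(rec$data[y0, x0, , 1])
  amp_out <- diff(range(osc)) / 2
  expect_lt(amp_out / amp, 1)
})

test_that("singular unfolding without regularisation is refused", {
  # static object + baseline subtraction leaves a zero signal estimate
  spec <- phantom_spec(area_pulse_mm2 = 0, q_base_mm3s = 0, snr = Inf)
  kt <- encode_kspace(render_cine(spec, std_params()))
  ktu <- undersample(kt, make_lattice_pattern(150L, 10L, 10L, 40L))
  expect_error(reconstruct_ktblast(ktu, reg_lambda = 0), "reg_lambda")
})
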