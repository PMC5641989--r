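# Helper: build a stack with prescribed per-encoding phases at every pixel.
phase_stack <- function(phases, params = std_params(), n = 8L, nt = 4L) {
  K <- length(params$moments_s_per_m)
  stopifnot(length(phases) == K)
  d <- array(0i, c(n, n, nt, K))
  for (k in seq_len(K)) d[, , , k] <- exp(1i * phases[k])
  cine_stack(d, params, pixel_mm = 0.1)
}

test_that("exactly linear phases recover the encoded velocity with R^2 = 1", {
  cine <- phase_stack(c(-0.6 * pi, 0, 0.6 * pi))
  vel <- fit_velocity(cine)
  expect_equal(max(abs(vel$v - 1)), 0, tolerance = 1e-12)
  expect_true(all(vel$r2 == 1))
  expect_true(all(vel$valid))
})

test_that("non-monotone phases fail the goodness-of-fit screen", {
  cine <- phase_stack(c(0.1, 0.5, 0.1))
  vel <- fit_velocity(cine)
  expect_true(all(vel$r2 < 0.5))
  expect_false(any(vel$valid))
})

test_that("velocity fitting requires three encodings with distinct moments", {
  params2 <- acquisition_params(moments_s_per_m = c(0, 0.3))
  d <- array(1 + 0i, c(4, 4, 2, 2))
  expect_error(fit_velocity(cine_stack(d, params2)), "3 flow encodings")
})

test_that("velocity scales with phase and ignores encoding order", {
  set.seed(5)
  base <- runif(1, 0.1, 0.4)
  c1 <- phase_stack(base * c(-1, 0, 1))
  c2 <- phase_stack(2 * base * c(-1, 0, 1))
  expect_equal(fit_velocity(c2)$v, 2 * fit_velocity(c1)$v, tolerance = 1e-12)
  # permuting encodings together with their moments leaves v unchanged
  perm <- c(3, 1, 2)
  params_p <- acquisition_params(moments_s_per_m = c(-0.3, 0, 0.3)[perm])
  d <- c1$data[, , , perm]
  vel_p <- fit_velocity(cine_stack(d, params_p, pixel_mm = 0.1))
  expect_equal(vel_p$v, fit_velocity(c1)$v, tolerance = 1e-12)
})

test_that("raising the R^2 threshold never adds valid pixels", {
  kt <- std_kt()
  cc <- crop_cine(reconstruct_full(kt), roi_of(kt))
  v1 <- fit_velocity(cc, r2_threshold = 0.7)
  v2 <- fit_velocity(cc, r2_threshold = 0.9)
  expect_true(all(v2$valid <= v1$valid))
})

test_that("noiseless phantom velocities match the ground-truth field centrally", {
  spec <- phantom_spec(snr = Inf)
  params <- std_params()
  cine <- render_cine(spec, params)
  tr <- simulate_truth(spec, params, supersample = 16L)
  vel <- fit_velocity(cine)
  ctr <- round(unlist(tr$center_mm) * params$matrix / params$fov_mm + 0.5)
  for (t in c(1L, 10L, 15L, 25L)) {
    expect_lt(abs(vel$v[ctr[1], ctr[2], t] - tr$v_m_s[ctr[1], ctr[2], t]) /
                tr$v_m_s[ctr[1], ctr[2], t], 0.01)
  }
})

test_that("flow integration follows the area-weighted sum", {
  params <- std_params()
  d <- array(0i, c(10, 10, 4, 3))
  for (k in 1:3)  # uniform v = 0.1 m/s under the phase convention
    d[, , , k] <- exp(1i * 2 * pi * params$moments_s_per_m[k] * 0.1)
  cine <- cine_stack(d, params, pixel_mm = 0.086)
  vel <- fit_velocity(cine)  # v = 0.1 m/s everywhere
  mask <- matrix(FALSE, 10, 10)
  mask[1:10, 1:10] <- TRUE
  fl <- compute_flow(vel, mask)
  expect_equal(fl$Q_mm3s, rep(0.1 * 1000 * 100 * 0.086^2, 4), tolerance = 1e-9)
  # zero velocity gives zero flow
  cine0 <- cine_stack(array(1 + 0i, c(10, 10, 4, 3)), params, pixel_mm = 0.086)
  expect_equal(compute_flow(fit_velocity(cine0), mask)$Q_mm3s, rep(0, 4))
})

test_that("an empty valid mask flags the frame", {
  params <- std_params()
  cine <- phase_stack(c(0.1, 0.5, 0.1), params)  # all pixels invalid
  vel <- fit_velocity(cine)
  fl <- compute_flow(vel, matrix(TRUE, 8, 8))
  expect_true(all(fl$flagged))
  expect_true(all(is.na(fl$Q_mm3s)))
})

test_that("noiseless full-sampling flow matches the prescribed Q(t)", {
  kt <- std_kt_clean()
  roi <- roi_of(kt)
  crop <- list(center_mm = roi$center_mm, half_width_mm = 1.6 * roi$radius_mm)
  rec <- reconstruct_full(kt, crop_mm = crop)
  vel <- fit_velocity(rec)
  disk <- ktqa:::roi_disk(dim(rec$data), rec$pixel_mm, rec$origin_mm, roi)
  fl <- compute_flow(vel, disk, infill = FALSE)
  qt <- unlist(kt$meta$truth$Q_mm3s)
  expect_lt(max(abs(fl$Q_mm3s - qt)) / max(qt), 0.02)
})

test_that("few lumen pixels are excluded by the R^2 screen at peak systole", {
  kt <- std_kt()
  rec <- crop_cine(reconstruct_full(kt), roi_of(kt))
  vel <- fit_velocity(rec)
  tr <- rec$truth
  lumen <- truth_lumen_masks(tr, dim(rec$data)[1:2], rec$pixel_mm, rec$origin_mm)
  peak <- which.max(unlist(tr$Q_mm3s))
  frac <- 1 - sum(vel$valid[, , peak] & lumen[, , peak]) / sum(lumen[, , peak])
  expect_lt(frac, 0.05)
})
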