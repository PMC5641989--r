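# A simple two-level disk image stack used across the segmentation tests.
disk_stack <- function(radius_px = 10, mag_in = 1, mag_out = 0.35, n = 48L,
                       nt = 2L, center = c(24.5, 24.5), pixel_mm = 0.1,
                       noise_sd = 0, seed = 1L) {
  rho <- sqrt(outer(((1:n) - center[1])^2, ((1:n) - center[2])^2, `+`))
  img <- ifelse(rho <= radius_px, mag_in, mag_out)
  d <- array(0i, c(n, n, nt, 3L))
  set.seed(seed)
  for (t in seq_len(nt)) for (k in 1:3)
    d[, , t, k] <- img + rnorm(n * n, sd = noise_sd)
  cine_stack(d, std_params(), pixel_mm = pixel_mm)
}

test_that("thresholding a disk counts its pixels exactly", {
  cine <- disk_stack(radius_px = 10)
  roi <- roi_mm(c(2.45, 2.45), 1.6)
  mag <- Mod(cine$data[, , 1, 1])
  m <- mask_at_threshold(mag, 0.5, roi, 0.1)
  rho <- sqrt(outer(((1:48) - 24.5)^2, ((1:48) - 24.5)^2, `+`))
  expect_equal(sum(m), sum(rho <= 10))
  # tau below everything keeps the whole roi component, above keeps nothing
  disk <- ktqa:::roi_disk(c(48L, 48L), 0.1, c(0, 0), roi)
  expect_equal(sum(mask_at_threshold(mag, 0, roi, 0.1)), sum(disk))
  expect_equal(sum(mask_at_threshold(mag, 1.01, roi, 0.1)), 0)
})

test_that("threshold masks keep only the component anchored at the centre", {
  cine <- disk_stack(radius_px = 6)
  mag <- Mod(cine$data[, , 1, 1])
  mag[40:44, 40:44] <- 1  # bright distractor blob inside the image
  roi <- roi_mm(c(2.45, 2.45), 2.5)  # roi large enough to include both
  m <- mask_at_threshold(mag, 0.5, roi, 0.1)
  expect_true(m[25, 25])
  expect_false(any(m[40:44, 40:44]))
})

test_that("identical encodings have zero cost everywhere", {
  cine <- disk_stack(noise_sd = 0)
  roi <- roi_mm(c(2.45, 2.45), 1.6)
  cost <- variance_cost(cine, seq(0.1, 0.9, by = 0.1), roi)
  expect_equal(cost, rep(0, 9))
})

test_that("the cost is the population variance of the per-encoding counts", {
  # counts per encoding at tau = 0.5 are made to differ by construction:
  # three disks of different radius
  n <- 48L
  d <- array(0i, c(n, n, 1L, 3L))
  radii <- c(8, 9, 10)
  for (k in 1:3) {
    rho <- sqrt(outer(((1:n) - 24.5)^2, ((1:n) - 24.5)^2, `+`))
    d[, , 1, k] <- ifelse(rho <= radii[k], 1, 0)
  }
  cine <- cine_stack(d, std_params(), pixel_mm = 0.1)
  roi <- roi_mm(c(2.45, 2.45), 1.6)
  counts <- vapply(1:3, function(k) {
    rho <- sqrt(outer(((1:n) - 24.5)^2, ((1:n) - 24.5)^2, `+`))
    sum(rho <= radii[k])
  }, numeric(1))
  # anchored normalisation maps the binary levels to the same 0/1 per
  # encoding, so the mid-range cost is the variance of these counts
  cost <- variance_cost(cine, 0.5, roi)
  expect_equal(cost, mean((counts - mean(counts))^2))
})

test_that("suprathreshold counts are non-increasing in the threshold", {
  cine <- disk_stack(noise_sd = 0.05, seed = 3)
  roi <- roi_mm(c(2.45, 2.45), 1.6)
  nm <- ktqa:::normalize_magnitude(cine, roi = roi)
  disk <- ktqa:::roi_disk(dim(nm$mag), 0.1, c(0, 0), roi)
  tau <- seq(0.05, 0.95, length.out = 64)
  counts <- ktqa:::roi_count_curves(nm$mag, disk, tau)
  for (t in 1:dim(counts)[2]) for (k in 1:dim(counts)[3])
    expect_true(all(diff(counts[, t, k]) <= 0))
})

test_that("the grid search arg-min equals an exhaustive brute-force minimum", {
  cine <- disk_stack(radius_px = 8, noise_sd = 0.06, nt = 3L, seed = 9)
  roi <- roi_mm(c(2.45, 2.45), 1.6)
  tau <- seq(0.05, 0.95, length.out = 96)
  lum <- quiet(segment_semiauto(cine, roi, tau = tau, cost_smooth = 1L,
                                tie_range = 0, tie_abs = 0))
  # independent brute force over the same grid and objective
  nm <- ktqa:::normalize_magnitude(cine, roi = roi)
  disk <- ktqa:::roi_disk(dim(nm$mag), 0.1, c(0, 0), roi)
  nroi <- sum(disk)
  cost <- cand <- numeric(length(tau))
  for (i in seq_along(tau)) {
    P <- matrix(0, dim(nm$mag)[3], 3)
    for (t in 1:dim(nm$mag)[3]) for (k in 1:3)
      P[t, k] <- sum(nm$mag[, , t, k][disk] >= tau[i])
    cost[i] <- mean(apply(P, 1, function(p) mean((p - mean(p))^2)))
    cand[i] <- mean(P) <= 0.95 * nroi && !all(P == 0)
  }
  idx <- which(cand == 1)
  # the chosen threshold attains the brute-force minimum over the grid
  i_star <- which.min(abs(tau - lum$tau))
  expect_equal(cost[i_star], min(cost[idx]))
})

test_that("flat costs resolve to the candidate-plateau midpoint", {
  cine <- disk_stack(noise_sd = 0)  # identical encodings, cost identically 0
  roi <- roi_mm(c(2.45, 2.45), 1.6)
  tau <- seq(0.05, 0.95, length.out = 181)
  lum <- quiet(segment_semiauto(cine, roi, tau = tau))
  nm <- ktqa:::normalize_magnitude(cine, roi = roi)
  disk <- ktqa:::roi_disk(dim(nm$mag), 0.1, c(0, 0), roi)
  nroi <- sum(disk)
  counts <- ktqa:::roi_count_curves(nm$mag, disk, tau)
  cand <- which(apply(counts, 1, mean) <= 0.95 * nroi & !apply(counts == 0, 1, all))
  expect_equal(lum$tau, tau[cand[round((1 + length(cand)) / 2)]])
})

test_that("inter-encoding inflow differences give an interior cost minimum", {
  spec <- phantom_spec(inflow_gain = c(0.2, 0.3, 0.4), seed = 4)
  kt <- quiet(encode_kspace(render_cine(spec, std_params())))
  roi <- roi_of(kt)
  crop <- list(center_mm = roi$center_mm, half_width_mm = 1.6 * roi$radius_mm)
  rec <- reconstruct_full(kt, 1024L, crop, apodize = "fermi")
  tau <- seq(0.05, 0.95, length.out = 128)
  cost <- variance_cost(rec, tau, roi, normalize = "encoding")
  sm <- lowpass_area(cost, 21L)
  # among non-saturated thresholds the minimum is interior, rising towards
  # both ends of the candidate range (Fig.-3-like valley)
  nm <- ktqa:::normalize_magnitude(rec, method = "encoding")
  disk <- ktqa:::roi_disk(dim(nm$mag), rec$pixel_mm, rec$origin_mm, roi)
  counts <- ktqa:::roi_count_curves(nm$mag, disk, tau)
  cand <- which(apply(counts, 1, mean) <= 0.95 * sum(disk) &
                  !apply(counts == 0, 1, all))
  imin <- cand[which.min(sm[cand])]
  expect_gt(imin, min(cand))
  expect_lt(imin, max(cand))
  expect_gt(sm[min(cand)], sm[imin])
  expect_gt(sm[max(cand)], sm[imin])
})

test_that("semi-automatic segmentation recovers a noiseless lumen area", {
  kt <- std_kt_clean()
  roi <- roi_of(kt)
  crop <- list(center_mm = roi$center_mm, half_width_mm = 1.6 * roi$radius_mm)
  rec <- reconstruct_full(kt, 1024L, crop, apodize = "fermi")
  lum <- quiet(segment_semiauto(rec, roi))
  tr <- kt$meta$truth
  ring <- 2 * pi * unlist(tr$R_mm) * 22 / 150  # one acquisition-pixel ring
  expect_true(all(abs(lum$area_mm2 - unlist(tr$A_mm2)) < ring))
  expect_true(all(vapply(seq_len(dim(lum$masks)[3]), function(t)
    max(EBImage::bwlabel(lum$masks[, , t, 1])), numeric(1)) == 1))
})

test_that("the area series follows the mean pixel count over encodings", {
  cine <- disk_stack(radius_px = 9, noise_sd = 0.03, nt = 3L)
  roi <- roi_mm(c(2.45, 2.45), 1.6)
  lum <- quiet(segment_semiauto(cine, roi))
  expect_equal(lum$area_mm2, rowMeans(lum$pixel_counts) * 0.1^2)
})

test_that("area low-pass filtering is zero-phase with exact edge handling", {
  expect_equal(lowpass_area(c(3, 1, 4, 1, 5), 1L), c(3, 1, 4, 1, 5))
  expect_equal(lowpass_area(rep(2, 10), 5L), rep(2, 10))
  x <- c(rep(0, 5), 1, rep(0, 5))
  expect_equal(lowpass_area(x, 5L)[4:8], rep(0.2, 5))
  expect_error(lowpass_area(1:3, 5L), "window")
  expect_error(lowpass_area(1:10, 4L), "odd")
})

test_that("manual masks ingest to the expected area series", {
  m <- array(FALSE, c(20, 20, 5))
  expect_equal(load_manual_masks(m, 0.1)$area_mm2, rep(0, 5))
  rho <- sqrt(outer(((1:20) - 10.5)^2, ((1:20) - 10.5)^2, `+`))
  for (t in 1:5) m[, , t] <- rho <= 6
  ls <- load_manual_masks(m, 0.1, n_frames = 5)
  expect_equal(ls$area_mm2, rep(sum(rho <= 6) * 0.01, 5))
  expect_error(load_manual_masks(m, 0.1, n_frames = 7), "frame count")
})
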