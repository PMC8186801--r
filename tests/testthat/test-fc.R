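test_that("the temporal low-pass keeps the passband and kills the stopband", {
  n <- 132; tr <- 2.8
  tt <- (seq_len(n) - 1) * tr
  mk <- function(f) time_series_volume(array(sin(2 * pi * f * tt),
                                             c(1, 1, 1, n)), tr_s = tr)
  amp <- function(ts) stats::sd(ts$values[1, 1, 1, ])
  hi <- lowpass_filter(mk(0.15), 0.08)
  expect_lt(amp(hi) / amp(mk(0.15)), 0.10)
  lo <- lowpass_filter(mk(0.02), 0.08)
  expect_gt(amp(lo) / amp(mk(0.02)), 0.95)
  # constant series pass through unchanged (DC preservation)
  cst <- time_series_volume(array(3.7, c(2, 2, 1, n)), tr_s = tr)
  expect_equal(lowpass_filter(cst, 0.08)$values, cst$values,
               tolerance = 1e-12)
  expect_error(lowpass_filter(cst, 0.2), "Nyquist")
})

test_that("low-pass preserves the voxel mean", {
  set.seed(2)
  ts <- time_series_volume(array(rnorm(4 * 64, mean = 10), c(2, 2, 1, 64)),
                           tr_s = 2.8)
  f <- lowpass_filter(ts, 0.08)
  expect_equal(apply(f$values, 1:3, mean), apply(ts$values, 1:3, mean),
               tolerance = 1e-10)
})

test_that("the in-plane Hamming filter preserves DC and apodizes Nyquist", {
  # spatially constant slice: unchanged
  cst <- voxel_grid(array(2.5, c(8, 8, 2)), c(2, 2, 4))
  expect_equal(inplane_hamming_filter(cst)$values, cst$values,
               tolerance = 1e-10)
  # impulse: spread but total preserved
  imp <- voxel_grid(array(0, c(16, 16, 1)), c(2, 2, 4))
  imp$values[8, 8, 1] <- 1
  fi <- inplane_hamming_filter(imp)
  expect_equal(sum(fi$values[, , 1]), 1, tolerance = 1e-9)
  expect_lt(max(fi$values), 1)                      # energy spread
  # in-plane Nyquist checkerboard: reduced to the window edge value 0.08
  n <- 16
  chk <- outer(0:(n - 1), 0:(n - 1), function(i, j) (-1)^(i + j))
  cb <- voxel_grid(array(chk, c(n, n, 1)), c(2, 2, 4))
  fc <- inplane_hamming_filter(cb)
  expect_equal(fc$values[, , 1] / chk,
               matrix(0.08^2, n, n), tolerance = 1e-9)
})

test_that("the in-plane Gaussian filter preserves the mean and smooths", {
  set.seed(3)
  sl <- voxel_grid(array(rnorm(24 * 24 * 2), c(24, 24, 2)), c(2, 2, 4))
  sm <- inplane_gaussian_filter(sl, fwhm_mm = 4)
  expect_equal(mean(sm$values[, , 1]), mean(sl$values[, , 1]),
               tolerance = 1e-10)
  expect_lt(stats::sd(sm$values[, , 1]), stats::sd(sl$values[, , 1]))
})

test_that("seed_reference averages then removes the least-squares line", {
  n <- 40
  s <- sin(2 * pi * (1:n) / 10) + 0.3 * (1:n)
  arr <- array(0, c(3, 1, 1, n))
  for (i in 1:3) arr[i, 1, 1, ] <- s
  ts <- time_series_volume(arr, tr_s = 2)
  roi <- seed_roi(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  ref <- seed_reference(ts, roi)
  fit <- stats::lm(ref$values ~ seq_len(n))
  expect_lt(abs(coef(fit)[1]), 1e-9 * stats::sd(ref$values))
  expect_lt(abs(coef(fit)[2]), 1e-9 * stats::sd(ref$values))
  # a pure linear ramp detrends to zero
  ramp <- time_series_volume(array(rep(1:n, each = 1), c(1, 1, 1, n)),
                             tr_s = 2)
  expect_equal(max(abs(seed_reference(ramp,
                                      seed_roi(c(0, 0, 0)))$values)), 0,
               tolerance = 1e-9)
  # random multi-voxel seed equals the hand-computed mean-then-detrend
  set.seed(8)
  arr2 <- array(rnorm(5 * n), c(5, 1, 1, n))
  ts2 <- time_series_volume(arr2, tr_s = 2)
  roi5 <- seed_roi(cbind(0:4, 0, 0))
  ref2 <- seed_reference(ts2, roi5)
  m <- colMeans(matrix(arr2, 5, n))
  expect_equal(ref2$values, unname(resid(stats::lm(m ~ seq_len(n)))),
               tolerance = 1e-12)
})

test_that("correlation maps agree with the textbook formula", {
  set.seed(4)
  n <- 30
  arr <- array(rnorm(8 * n), c(2, 2, 2, n))
  ref <- arr[1, 1, 1, ]
  arr[2, 1, 1, ] <- -ref
  ts <- time_series_volume(arr, tr_s = 2)
  cm <- correlation_map(ts, ref, all_ones_mask(c(2, 2, 2)))
  expect_equal(cm$map$values[1, 1, 1], 1)
  expect_equal(cm$map$values[2, 1, 1], -1)
  for (v in list(c(1, 2, 1), c(2, 2, 2))) {
    x <- ts$values[v[1], v[2], v[3], ]
    r_hand <- sum((x - mean(x)) * (ref - mean(ref))) /
      sqrt(sum((x - mean(x))^2) * sum((ref - mean(ref))^2))
    expect_equal(cm$map$values[v[1], v[2], v[3]], r_hand, tolerance = 1e-12)
  }
  # zero-variance voxels are flagged as r = 0; zero-variance refs error
  arr[1, 2, 2, ] <- 7
  ts0 <- time_series_volume(arr, tr_s = 2)
  cm0 <- correlation_map(ts0, ref, all_ones_mask(c(2, 2, 2)))
  expect_equal(cm0$map$values[1, 2, 2], 0)
  expect_identical(cm0$n_flagged, 1L)
  expect_error(correlation_map(ts, rep(1, n), all_ones_mask(c(2, 2, 2))),
               "zero variance")
})

test_that("r-to-t conversion follows the closed form with capped extremes", {
  g <- voxel_grid(array(c(0, 0.5, -0.5, 1, -1, 0.3), c(6, 1, 1)), units = "r")
  cm <- structure(list(map = g, stage = "r", dof = 130L, n_flagged = 0L),
                  class = "connectivity_map")
  tm <- r_to_t(cm, n_effective = 132)
  expect_equal(tm$map$values[1, 1, 1], 0)
  expect_equal(tm$map$values[2, 1, 1], 0.5 * sqrt(130 / 0.75),
               tolerance = 1e-12)                      # ~6.583
  expect_equal(tm$map$values[3, 1, 1], -tm$map$values[2, 1, 1])
  expect_equal(tm$map$values[4, 1, 1], 1e6)
  expect_equal(tm$map$values[5, 1, 1], -1e6)
  expect_identical(tm$dof, 130L)
  expect_error(r_to_t(cm, n_effective = 2), "at least 3")
})

test_that("whole-brain z-normalisation is exact and affine-invariant", {
  vals <- array(c(1, 2, 3, 4, 5), c(5, 1, 1))
  cm <- structure(list(map = voxel_grid(vals, units = "t"), stage = "t",
                       dof = 30L, n_flagged = 0L), class = "connectivity_map")
  zm <- normalize_t_to_z(cm)
  # population-SD convention: sd = sqrt(2), z = (x - 3) / sqrt(2)
  expect_equal(as.numeric(zm$map$values),
               c(-sqrt(2), -sqrt(2) / 2, 0, sqrt(2) / 2, sqrt(2)),
               tolerance = 1e-12)
  z <- zm$map$values
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)
  # affine rescaling of the input leaves the output unchanged
  cm2 <- cm
  cm2$map$values <- 3.7 * vals - 11
  expect_equal(normalize_t_to_z(cm2)$map$values, zm$map$values,
               tolerance = 1e-12)
  # sample-SD convention differs by the expected constant factor
  zs <- normalize_t_to_z(cm, sd_type = "sample")
  expect_equal(zs$map$values * sqrt(5 / 4), zm$map$values, tolerance = 1e-12)
  cmc <- cm; cmc$map$values <- array(2, c(5, 1, 1))
  expect_error(normalize_t_to_z(cmc), "degenerate")
})

test_that("extract_fc averages the target and errors off-mask", {
  z <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  zm <- structure(list(map = voxel_grid(z, units = "z"), stage = "z",
                       dof = 30L), class = "connectivity_map")
  tgt <- seed_roi(rbind(c(0, 0, 0), c(1, 1, 1), c(3, 3, 1)))
  expect_equal(as.numeric(extract_fc(zm, tgt)),
               mean(c(z[1, 1, 1], z[2, 2, 2], z[4, 4, 2])))
  zc <- z; zc[] <- 1.2
  zmc <- zm; zmc$map$values <- zc
  expect_equal(as.numeric(extract_fc(zmc, tgt)), 1.2)
  zm$map$values[1, 1, 1] <- NA
  expect_error(extract_fc(zm, tgt), "outside")
})

test_that("fc over the whole mask is ~0 and the pipeline is deterministic", {
  fx <- make_image_fixtures(dim = c(12, 12, 6), n_volumes = 40, rng_seed = 21)
  res1 <- fc_pathway(fx$rest_series, fx$seed, fx$target, fx$brain_mask)
  res2 <- fc_pathway(fx$rest_series, fx$seed, fx$target, fx$brain_mask)
  expect_identical(res1$fc, res2$fc)
  whole <- mask_to_roi(fx$brain_mask)
  expect_equal(as.numeric(extract_fc(res1$zmap, whole)), 0, tolerance = 1e-9)
})

test_that("null fc values stay inside the 3-sigma target-average bound", {
  # with a unit-variance normalised z map, the mean of n_target independent
  # voxels has SD ~ 1/sqrt(n_target); 3/sqrt(n_target) should hold >= 95%
  set.seed(31)
  n_in <- 0
  nsim <- 200
  dims <- c(10, 10, 3); nvol <- 40
  mask <- all_ones_mask(dims)
  seed <- seed_roi(as.matrix(expand.grid(1:3, 1:3, 1)))
  target <- seed_roi(as.matrix(expand.grid(6:8, 6:8, 1)))
  for (i in seq_len(nsim)) {
    ts <- time_series_volume(array(rnorm(prod(dims) * nvol), c(dims, nvol)),
                             tr_s = 2.8)
    res <- fc_pathway(ts, seed, target, mask, spatial_filter = FALSE)
    if (abs(res$fc) < 3 / sqrt(9)) n_in <- n_in + 1
  }
  expect_gte(n_in / nsim, 0.95)
})
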