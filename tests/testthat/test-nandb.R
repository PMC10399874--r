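dwell <- 50e-6

stack_from_array <- function(a, dwell = 50e-6, fi = 0.1) {
  image_stack(a, pixel_dwell_time = dwell, pixel_size = 0.4,
              frame_interval = fi)
}

test_that("pixel statistics match hand and Poisson oracles", {
  # hand arithmetic: trace [2, 4] -> mean 3, unbiased variance 2
  a <- array(0L, c(2, 1, 2)); a[, 1, 1] <- c(2L, 4L); a[, 1, 2] <- c(3L, 3L)
  ps <- pixel_statistics(stack_from_array(a))
  expect_equal(ps$mean[1, 1], 3); expect_equal(ps$variance[1, 1], 2)
  expect_equal(ps$variance[1, 2], 0)

  # constant stack -> zero variance everywhere
  ps0 <- pixel_statistics(stack_from_array(array(7L, c(5, 3, 3))))
  expect_true(all(ps0$variance == 0))

  # Poisson law: variance/mean -> 1
  set.seed(1)
  ap <- array(rpois(1e5 * 4, 4), c(1e5, 2, 2))
  pp <- pixel_statistics(stack_from_array(ap))
  expect_true(all(abs(pp$variance / pp$mean - 1) < 0.02))

  expect_error(pixel_statistics(stack_from_array(array(1L, c(1, 2, 2)))),
               "2 frames")
})

test_that("brightness and number follow the photon-counting estimators", {
  # direct arithmetic: kbar = 2.5, var = 3.75, dwell 50 us
  mu <- matrix(2.5, 2, 2); v <- matrix(3.75, 2, 2)
  bm <- brightness_number(mu, v, dwell)
  expect_equal(bm$epsilon_per_dwell[1, 1], 0.5)
  expect_equal(bm$epsilon_cps[1, 1], 1e4)
  expect_equal(bm$number[1, 1], 5)

  # shot-noise-only pixel: epsilon 0, invalid for n, never NaN
  bm0 <- brightness_number(matrix(2, 1, 2), matrix(c(2, 0), 1, 2), dwell)
  expect_equal(bm0$epsilon_cps[1, 1], 0)
  expect_false(any(bm0$valid_mask))
  expect_true(all(is.finite(bm0$epsilon_cps)))

  # zero-mean pixel stays finite and invalid
  bmz <- brightness_number(matrix(0, 1, 1), matrix(0, 1, 1), dwell)
  expect_true(is.finite(bmz$epsilon_cps[1, 1]))
  expect_false(bmz$valid_mask[1, 1])
})

test_that("the vectorized N&B path equals a brute-force per-pixel loop", {
  cfg <- sim_config(seed = 12, n_frames = 40, height = 12, width = 15)
  st <- simulate_nb_stack(cfg)
  ps <- pixel_statistics(st)
  bm <- brightness_number(ps$mean, ps$variance, st$pixel_dwell_time)
  bf <- brute_force_nandb(st$counts, st$pixel_dwell_time)
  expect_equal(ps$mean, bf$mean, tolerance = 1e-12)
  expect_equal(ps$variance, bf$variance, tolerance = 1e-12)
  expect_equal(bm$epsilon_cps, bf$epsilon_cps, tolerance = 1e-12)
  expect_equal(bm$number[bm$valid_mask], bf$number[bm$valid_mask],
               tolerance = 1e-12)
})

test_that("saturation masking applies the 1 MHz rule and scales with dwell", {
  a <- array(10L, c(5, 4, 4))
  a[3, 2, 2] <- 60L   # 60 counts / 50 us = 1.2 MHz
  st <- stack_from_array(a, dwell = 50e-6)
  m <- saturation_mask(st)
  expect_true(m[2, 2]); expect_equal(sum(m), 1L)

  # nothing masked when all counts <= 50 at 50 us
  expect_equal(sum(saturation_mask(stack_from_array(array(50L, c(3, 2, 2)),
                                                    dwell = 50e-6))), 0L)

  # 80 counts at 100 us dwell = 0.8 MHz -> unmasked
  a2 <- array(80L, c(3, 2, 2))
  expect_equal(sum(saturation_mask(stack_from_array(a2, dwell = 100e-6))), 0L)

  # monotonicity: lowering max_rate never unmasks
  set.seed(3)
  ar <- array(rpois(10 * 36, 20), c(10, 6, 6))
  str <- stack_from_array(ar)
  prev <- saturation_mask(str, max_rate = 1e6)
  for (r in c(8e5, 6e5, 4e5, 2e5)) {
    cur <- saturation_mask(str, max_rate = r)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("boxcar windows extrapolate brightness to the acquisition start", {
  # identical 8-frame blocks -> equal window values -> exact flat line
  set.seed(7)
  block <- array(rpois(8 * 64, 3), c(8, 8, 8))
  a <- array(0L, c(16, 8, 8)); a[1:8, , ] <- block; a[9:16, , ] <- block
  bb <- boxcar_brightness(stack_from_array(a), window = 8)
  expect_equal(bb$n_windows, 2L)
  expect_equal(bb$window_epsilon[1], bb$window_epsilon[2])
  expect_equal(bb$extrapolated_epsilon, bb$window_epsilon[1],
               tolerance = 1e-12)

  # stationary stack: extrapolation is a no-op within window scatter
  st <- simulate_nb_stack(fx_nb_config(seed = 41))
  bbs <- boxcar_brightness(st)
  whole <- (mean(bbs$map$variance) - mean(bbs$map$mean_counts)) /
    mean(bbs$map$mean_counts)
  expect_lt(abs(bbs$extrapolated_epsilon - whole),
            3 * sd(bbs$window_epsilon))

  expect_error(boxcar_brightness(stack_from_array(array(1L, c(10, 4, 4))),
                                 window = 8), "2 complete")
})

test_that("boxcar extrapolation corrects a 30% bleaching loss", {
  errs <- sapply(1:3, function(s) {
    cfg <- fx_nb_config(seed = 330 + s)
    cfg$bleach_rate <- -log(0.7) / ((cfg$n_frames - 1) * cfg$frame_interval)
    st <- simulate_nb_stack(cfg)
    truth <- expected_stats(cfg)$epsilon_per_dwell / cfg$pixel_dwell_time
    row <- nb_cell_brightness(st)
    c(corr = abs(row$epsilon_cps / truth - 1),
      unc = abs(row$epsilon_cps_uncorrected / truth - 1))
  })
  expect_lt(median(errs["corr", ]), 0.10)
  expect_lt(median(errs["corr", ]), median(errs["unc", ]))
})

test_that("bleached fraction reads the head/tail intensity loss", {
  expect_equal(bleached_fraction(rep(100, 60))$fraction, 0)

  # exponential decay with k * T = ln 2: matches the endpoint-average
  # oracle exactly and sits near 0.5
  n <- 100; k <- log(2) / (n - 1)
  totals <- exp(-k * (seq_len(n) - 1))
  bf <- bleached_fraction(totals)
  oracle <- exponential_bleached_fraction(k, n, 1, bf$n_edge)
  expect_equal(bf$fraction, oracle, tolerance = 1e-12)
  expect_lt(abs(oracle - 0.5), 0.02)

  # monotone increase -> negative fraction, flagged
  up <- bleached_fraction(seq_len(50))
  expect_lt(up$fraction, 0)
  expect_true(up$increased)

  expect_error(bleached_fraction(c(0, rep(1, 30))), "zero initial")
  expect_error(bleached_fraction(rep(1, 10)), ">= 20")
})

test_that("ROI brightness averages valid unmasked pixels only", {
  # uniform map -> the constant
  mu <- matrix(2.5, 4, 4); v <- matrix(3.75, 4, 4)
  bm <- brightness_number(mu, v, dwell)
  rb <- roi_brightness(bm)
  expect_equal(rb$epsilon_cps, 1e4)
  expect_equal(rb$n_pixels, 16L)

  # checkerboard of 0.5c and 1.5c -> c
  ck <- matrix(c(3.125, 4.375), 4, 4)   # excess 0.625 / 1.875 over kbar 2.5
  bmc <- brightness_number(matrix(2.5, 4, 4), ck, dwell)
  expect_equal(roi_brightness(bmc)$epsilon_cps, 1e4)

  # ROI entirely saturated -> error
  expect_error(roi_brightness(bm, sat_mask = matrix(TRUE, 4, 4)),
               "empty ROI")
})
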