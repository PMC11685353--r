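test_that("a noiseless Gaussian zone is integrated to its closed forms", {
  tr <- simulate_trace(trace_sim_config(peaks = list(c(1000, 0.1, 10)),
                                        noise_sd = 0))
  pk <- detect_peaks(tr, min_height = 0.01)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_pixel, 1000L)
  expect_equal(pk$height, 0.1, tolerance = 1e-4)
  expect_equal(pk$area, 0.1 * 10 * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(pk$width_half_height, 2 * sqrt(2 * log(2)) * 10, tolerance = 0.01)
})

test_that("flat and all-zero traces yield empty peak tables", {
  zero <- electropherogram(1:500, rep(0, 500))
  expect_equal(nrow(detect_peaks(zero, 0.01)), 0L)
  flat <- electropherogram(1:500, rep(0.3, 500))
  expect_equal(nrow(detect_peaks(flat, 0.01)), 0L)
})

test_that("peaks are labelled through identity windows", {
  tr <- simulate_trace(trace_sim_config(
    peaks = list(c(700, 0.2, 12), c(1500, 0.34, 12)), noise_sd = 0))
  pk <- detect_peaks(tr, 0.05,
                     identity_windows = list(`Rp5-C` = c(650, 750),
                                             `pI 7.05` = c(1450, 1550)))
  expect_equal(pk$identity, c("Rp5-C", "pI 7.05"))
})

test_that("resolution follows the half-height formula and is symmetric", {
  a <- list(apex_pixel = 1000, width_half_height = 10)
  b <- list(apex_pixel = 1118, width_half_height = 10)
  expect_equal(resolution(a, b), 1.18 * 118 / 20)
  expect_equal(resolution(a, b), 6.962)
  expect_equal(resolution(b, a), resolution(a, b))
  expect_equal(resolution(a, a), 0)
  expect_error(resolution(a, list(apex_pixel = 1, width_half_height = 0)),
               "width")
  # doubling the separation doubles the resolution at fixed widths
  c2 <- list(apex_pixel = 1236, width_half_height = 10)
  expect_equal(resolution(a, c2), 2 * resolution(a, b))
})

test_that("detected Gaussian pairs match the sigma-based resolution form", {
  sigma <- 12
  delta <- 300
  tr <- simulate_trace(trace_sim_config(
    peaks = list(c(800, 0.1, sigma), c(800 + delta, 0.12, sigma)),
    noise_sd = 0))
  pk <- detect_peaks(tr, 0.01)
  expect_equal(nrow(pk), 2L)
  rs <- resolution(pk[1L, ], pk[2L, ])
  expect_equal(rs, delta / (2 * (2 * sqrt(2 * log(2))) / 1.18 * sigma),
               tolerance = 0.01)
})

test_that("pixel-to-pI interpolation matches the two-anchor line", {
  map <- gradient_map(c(500, 5.12), c(1900, 7.05))
  expect_equal(as.numeric(pixel_to_pi(map, 500)), 5.12)
  expect_equal(as.numeric(pixel_to_pi(map, 1900)), 7.05)
  expect_equal(as.numeric(pixel_to_pi(map, 1200)), 6.085)
  out <- pixel_to_pi(map, 300)
  expect_equal(as.numeric(out), 5.12 - 200 * (7.05 - 5.12) / 1400,
               tolerance = 1e-12)
  expect_equal(round(as.numeric(out), 3), 4.844)
  expect_true(attr(out, "extrapolated"))
  expect_false(attr(pixel_to_pi(map, 1200), "extrapolated"))
  # strict monotonicity across the cartridge
  vals <- as.numeric(pixel_to_pi(map, 1:2048))
  expect_true(all(diff(vals) > 0))
  expect_error(gradient_map(c(1900, 5.12), c(500, 7.05)), "exceed")
})

test_that("apparent pI averages day means with a t-based interval", {
  same <- apparent_pi(rep(5.99, 5))
  expect_equal(same$mean, 5.99)
  expect_equal(same$ci_half_width, 0)

  days <- c(6.46, 6.47, 6.48, 6.47, 6.47)
  ap <- apparent_pi(days)
  expect_equal(ap$mean, 6.47)
  expect_equal(ap$ci_half_width, qt(0.975, 4) * sd(days) / sqrt(5))
  expect_equal(ap$ci_half_width, 0.0088, tolerance = 0.01)

  two <- apparent_pi(c(6.0, 6.1))
  expect_equal(two$ci_half_width, qt(0.975, 1) * sd(c(6.0, 6.1)) / sqrt(2))
  expect_error(apparent_pi(6.0), "two day means")
})

test_that("precision summaries define CV as 100 SD / mean", {
  ps <- precision_summary(c(9, 10, 11))
  expect_equal(ps$cv, 10)
  expect_equal(ps$n, 3L)
  expect_equal(precision_summary(rep(4.2, 6))$cv, 0)
  # scale invariance
  x <- c(3.1, 3.3, 3.0, 3.2)
  expect_equal(precision_summary(7 * x)$cv, precision_summary(x)$cv)
  expect_error(precision_summary(5), "two replicates")
  expect_error(precision_summary(c(-1, 1)), "zero")
})

test_that("simulated repeatability CVs concentrate on the nominal value", {
  # peak-height replicates with noise_sd / height = 2% nominal CV
  cvs <- vapply(1:300, function(s) {
    set.seed(s + 900)
    precision_summary(0.5 + rnorm(6, 0, 0.01))$cv
  }, numeric(1))
  expect_equal(mean(cvs), 2, tolerance = 0.1)
})
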