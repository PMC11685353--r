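test_that("Mandel's test resolves exact lines and parabolas degenerately", {
  x <- rep(seq(5, 30, 5), 3)
  line <- calibration_series(x, 2 + 0.5 * x)
  res_line <- mandel_test(line)
  expect_true(res_line$linear)
  expect_true(res_line$degenerate)
  parab <- calibration_series(x, 1 + 0.1 * x + 0.02 * x^2)
  res_par <- mandel_test(parab)
  expect_false(res_par$linear)
  expect_true(res_par$degenerate)
  expect_equal(res_par$p, 0)
  expect_error(mandel_test(calibration_series(rep(1:4, 3), rnorm(12))),
               "five calibration levels")
})

test_that("Mandel's F equals the nested-model ANOVA oracle", {
  for (s in 1:10) {
    ser <- std_series(seed = 200 + s, curvature = 0.002)
    got <- mandel_test(ser)
    df <- as.data.frame(ser)
    a <- anova(lm(response ~ concentration, df),
               lm(response ~ concentration + I(concentration^2), df))
    expect_equal(got$F, a$F[2], tolerance = 1e-9)
    expect_equal(got$p, a$`Pr(>F)`[2], tolerance = 1e-9)
  }
})

test_that("lack-of-fit decomposition is exact and matches a one-way ANOVA oracle", {
  for (s in 1:10) {
    ser <- std_series(seed = 300 + s, curvature = 0.001)
    got <- lof_test(ser)
    scale <- sum(ser$response^2)
    expect_lt(abs(got$ss_lack + got$ss_pure - fit_ols(ser)$SSE), 1e-9 * scale)
    # oracle: pure error from the level-means model, lack of fit by difference
    df <- as.data.frame(ser)
    sse_lin <- sum(residuals(lm(response ~ concentration, df))^2)
    ss_pure <- sum(residuals(lm(response ~ factor(concentration), df))^2)
    k <- length(unique(df$concentration))
    n <- nrow(df)
    F_or <- ((sse_lin - ss_pure) / (k - 2)) / (ss_pure / (n - k))
    expect_equal(got$F, F_or, tolerance = 1e-9)
    expect_equal(got$p, pf(F_or, k - 2, n - k, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("replicate means on the fitted line give zero lack of fit", {
  x <- rep(c(1, 2, 3), each = 3)
  means <- 1 + 2 * c(1, 2, 3)
  y <- rep(means, each = 3) + rep(c(-0.2, 0, 0.2), 3)
  res <- lof_test(calibration_series(x, y))
  expect_equal(res$F, 0, tolerance = 1e-9)
  expect_true(res$linear)
  expect_error(lof_test(calibration_series(rep(1:3, 2), rnorm(6))),
               "three replicates")
})

test_that("stepwise elimination keeps clean ranges and trims saturated tops", {
  clean <- std_series(seed = 17L)
  res <- stepwise_linearity(clean, "MFT")
  expect_equal(res$removed_levels, 0L)
  expect_false(res$no_linear_range)

  hits <- 0L
  for (s in 1:200) {
    sat <- saturate_top_level(std_series(seed = s), deficit = 3)
    sw <- stepwise_linearity(sat, "MFT")
    hits <- hits + (sw$removed_levels == 1L && !sw$no_linear_range)
  }
  expect_gte(hits / 200, 0.9)
})

test_that("globally quadratic data exhaust the elimination floor", {
  ser <- std_series(seed = 23L, curvature = 0.05)
  res <- stepwise_linearity(ser, "MFT")
  expect_true(res$no_linear_range)
  expect_false(res$linear)
  # LOF can trim further (floor at three levels) but also fails here
  res_lof <- stepwise_linearity(ser, "LOF")
  expect_true(res_lof$removed_levels <= 3L)
})

test_that("LOF is more sensitive than MFT to non-parabolic saturation", {
  mft_rej <- 0L
  lof_rej <- 0L
  for (s in 1:200) {
    sat <- saturate_top_level(std_series(seed = 700 + s), deficit = 1.2)
    mft_rej <- mft_rej + (mandel_test(sat)$p < 0.01)
    lof_rej <- lof_rej + (lof_test(sat)$p < 0.01)
  }
  expect_gt(lof_rej, mft_rej)
})

test_that("the variance F-test is symmetric with exact scaled fixtures", {
  ser <- std_series(seed = 61L)
  f <- fit_ols(ser)
  # doubling the residuals around the fitted line scales s2_yx by exactly 4
  scaled <- calibration_series(ser$concentration, f$fitted + 2 * f$residuals,
                               ser$injection_order, ser$cycle, ser$level_index)
  f4 <- fit_ols(scaled)
  expect_equal(f4$s2_yx / f$s2_yx, 4, tolerance = 1e-9)
  ft <- variance_f_test(f, f4)
  expect_equal(ft$F, 4, tolerance = 1e-9)
  expect_equal(ft$p, 2 * pf(4, 16, 16, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(variance_f_test(f4, f)$p, ft$p)
  same <- variance_f_test(f, f)
  expect_equal(same$F, 1)
  expect_equal(same$p, 1)
})

test_that("slope comparison collapses to the pooled test under equal designs", {
  ser <- std_series(seed = 71L)
  f_a <- fit_ols(ser)
  # same design, same residuals, different line: equal s2_yx and Sxx
  shifted <- calibration_series(ser$concentration,
                                3 + 0.8 * ser$concentration + f_a$residuals,
                                ser$injection_order, ser$cycle, ser$level_index)
  f_b <- fit_ols(shifted)
  expect_equal(f_b$s2_yx, f_a$s2_yx, tolerance = 1e-12)
  cmp <- compare_slopes(f_a, f_b)
  expect_equal(cmp$welch$df, 32)
  expect_equal(cmp$pooled$df, 32)
  expect_equal(cmp$welch$p, cmp$pooled$p, tolerance = 1e-12)

  ident <- compare_slopes(f_a, f_a)
  expect_equal(ident$welch$t, 0)
  expect_equal(ident$welch$p, 1)
  expect_equal(ident$pooled$p, 1)
})

test_that("Welch uses Aspin-Welch fractional degrees of freedom", {
  a <- fit_ols(std_series(seed = 81L))
  b <- fit_ols(simulate_calibration(calib_sim_config(noise_sd = 1.2, seed = 82L)))
  cmp <- compare_slopes(a, b)
  va <- a$s2_yx / sum((a$x - mean(a$x))^2)
  vb <- b$s2_yx / sum((b$x - mean(b$x))^2)
  nu <- (va + vb)^2 / (va^2 / 16 + vb^2 / 16)
  expect_equal(cmp$welch$df, nu, tolerance = 1e-12)
  expect_lte(cmp$welch$df, cmp$pooled$df + 1e-9)
  expect_equal(cmp$welch$t, (a$coefficients[["b1"]] - b$coefficients[["b1"]]) /
                 sqrt(va + vb), tolerance = 1e-12)
})
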