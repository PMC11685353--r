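test_that("moment SEs reproduce the published interval half-widths", {
  se18 <- moment_se(18L)
  expect_equal(round(se18$se_skewness * t_critical(0.05, 17), 3), 1.131)
  expect_equal(round(se18$se_excess_kurtosis * t_critical(0.05, 17), 3), 2.190)
  se17 <- moment_se(17L)
  # 1.166 as usually printed comes from a 3-d.p.-rounded SE (0.550 * 2.120);
  # the exact value is 1.1653
  expect_equal(se17$se_skewness * t_critical(0.05, 16), 1.166, tolerance = 1e-3)
  expect_equal(round(se17$se_excess_kurtosis * t_critical(0.05, 16), 3), 2.254)
  expect_error(moment_se(3L), "at least 4")
  expect_true(is.na(moment_se(5L)$se_excess_kurtosis))
})

test_that("moment SE formulas match brute-force normal-sampling SDs", {
  set.seed(99)
  n <- 18L
  X <- matrix(rnorm(n * 1e5), n)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = n)
  m2 <- colMeans(Xc^2)
  G1 <- (colMeans(Xc^3) / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * (colMeans(Xc^4) / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  se <- moment_se(n)
  expect_equal(sd(G1), se$se_skewness, tolerance = 0.02)
  expect_equal(sd(G2), se$se_excess_kurtosis, tolerance = 0.02)
})

test_that("skewness and kurtosis estimators behave on signed shapes", {
  sym <- c(-3, -2, -1, 1, 2, 3)
  expect_equal(sample_skewness(sym), 0, tolerance = 1e-12)
  expect_gt(sample_skewness(c(1, 2, 3, 4, 100)), 0)
  expect_lt(sample_skewness(-c(1, 2, 3, 4, 100)), 0)
  # heavy-tailed samples carry positive excess kurtosis
  expect_gt(sample_excess_kurtosis(c(rep(0, 10), -8, 8)), 0)
})

test_that("BCa intervals are seeded, degenerate-safe and percentile-like in the limit", {
  x <- c(-2.1, -1.4, -0.7, -0.2, 0.1, 0.4, 0.9, 1.3, 1.8, 2.2, -0.9, 0.6)
  a <- bca_ci(x, mean, seed = 7L)
  b <- bca_ci(x, mean, seed = 7L)
  expect_identical(a, b)
  expect_lt(a$lower, mean(x))
  expect_gt(a$upper, mean(x))

  cst <- bca_ci(rep(1, 10), mean, seed = 1L)
  expect_true(cst$degenerate)
  expect_equal(c(cst$lower, cst$upper), c(1, 1))

  # large symmetric sample: z0 and a vanish, endpoints near the percentile CI
  set.seed(123)
  big <- rnorm(400)
  bca <- bca_ci(big, mean, n_boot = 2000L, seed = 5L)
  perc <- local({
    set.seed(5L)
    boots <- replicate(2000, mean(sample(big, replace = TRUE)))
    quantile(boots, c(0.025, 0.975), names = FALSE, type = 6)
  })
  width <- perc[2] - perc[1]
  expect_lt(abs(bca$lower - perc[1]), 0.1 * width)
  expect_lt(abs(bca$upper - perc[2]), 0.1 * width)
})

test_that("BCa endpoints agree with the reference bootstrap implementation", {
  skip_if_not_installed("boot")
  set.seed(50012)
  x <- rnorm(18)
  ours <- bca_ci(x, sample_skewness, n_boot = 6000L, seed = 3L)
  ref <- boot::boot.ci(
    boot::boot(x, function(d, i) sample_skewness(d[i]), R = 6000),
    type = "bca")$bca[4:5]
  spread <- ours$upper - ours$lower
  expect_lt(abs(ours$lower - ref[1]), 0.1 * spread)
  expect_lt(abs(ours$upper - ref[2]), 0.1 * spread)
})

test_that("BCa skewness coverage at n = 18 sits in the small-sample band", {
  # known small-sample undercoverage: nominal 95% BCa intervals for
  # skewness cover the true value in roughly 9 cases out of 10 at n = 18
  cov <- 0L
  for (s in 1:400) {
    set.seed(s + 50000)
    x <- rnorm(18)
    ci <- bca_ci(x, sample_skewness, n_boot = 1000L, seed = s)
    cov <- cov + (ci$lower <= 0 && ci$upper >= 0)
  }
  expect_gte(cov / 400, 0.86)
  expect_lte(cov / 400, 0.96)
})

test_that("the normality suite reports consistent moments, tests and verdicts", {
  ser <- std_series(seed = 41L)
  rep_ <- normality_suite(fit_ols(ser)$residuals, seed = 11L)
  expect_false(rep_$degenerate)
  expect_true(rep_$skewness_ci[1] <= rep_$skewness &&
                rep_$skewness <= rep_$skewness_ci[2])
  expect_true(rep_$excess_kurtosis_ci[1] <= rep_$excess_kurtosis &&
                rep_$excess_kurtosis <= rep_$excess_kurtosis_ci[2])
  expect_gte(rep_$shapiro_p, 0)
  expect_lte(rep_$shapiro_p, 1)
  expect_gte(rep_$lilliefors_p, 0)
  expect_lte(rep_$lilliefors_p, 1)
  expect_identical(rep_$verdicts$shapiro, rep_$shapiro_p >= 0.05)
  degen <- normality_suite(rep(0.5, 10))
  expect_true(degen$degenerate)
})

test_that("Shapiro-Wilk attains its nominal type-I error", {
  rej <- 0L
  for (s in 1:1000) {
    set.seed(s)
    rej <- rej + (shapiro.test(rnorm(200))$p.value < 0.05)
  }
  expect_equal(rej / 1000, 0.05, tolerance = 0.3) # 5% +/- 1.5%
  expect_lte(abs(rej / 1000 - 0.05), 0.015)
})

test_that("Breusch-Pagan matches the hand-solved auxiliary regression", {
  # residuals [1, -2, 3] on x = [1, 2, 3]: R^2 = 48/49, n R^2 = 2.9388
  fake <- structure(list(residuals = c(1, -2, 3), x = c(1, 2, 3), n = 3L),
                    class = "regression_fit")
  bp <- breusch_pagan(fake)
  expect_equal(bp$koenker_statistic, 3 * 48 / 49, tolerance = 1e-9)
  expect_equal(bp$koenker_p, pchisq(3 * 48 / 49, 1, lower.tail = FALSE))
  expect_equal(round(bp$koenker_p, 4), 0.0865)
})

test_that("both Breusch-Pagan forms agree with the lmtest reference", {
  skip_if_not_installed("lmtest")
  ser <- std_series(seed = 77L)
  f <- fit_ols(ser)
  bp <- breusch_pagan(f)
  lmfit <- lm(response ~ concentration, data = as.data.frame(ser))
  expect_equal(bp$koenker_statistic,
               unname(lmtest::bptest(lmfit, studentize = TRUE)$statistic),
               tolerance = 1e-9)
  expect_equal(bp$lm_statistic,
               unname(lmtest::bptest(lmfit, studentize = FALSE)$statistic),
               tolerance = 1e-9)
  expect_error(breusch_pagan(structure(list(residuals = rep(0, 8),
                                            x = 1:8, n = 8L),
                                       class = "regression_fit")),
               "zero-variance")
})

test_that("constant-magnitude residuals cannot look heteroscedastic", {
  fake <- structure(list(residuals = c(1, -1, 1, -1, 1, -1),
                         x = c(1, 2, 3, 4, 5, 6), n = 6L),
                    class = "regression_fit")
  bp <- breusch_pagan(fake)
  expect_equal(bp$koenker_statistic, 0, tolerance = 1e-12)
  expect_equal(bp$p, 1)
})

test_that("heteroscedastic responses are detected more than half the time", {
  rej <- 0L
  for (s in 1:1000) {
    ser <- simulate_calibration(calib_sim_config(noise_sd = 1.5,
                                                 hetero_exponent = 1, seed = s))
    rej <- rej + (breusch_pagan(fit_ols(ser))$p < 0.05)
  }
  expect_gt(rej / 1000, 0.5)
})

test_that("Durbin-Watson arithmetic and zones follow the bound logic", {
  expect_equal(durbin_watson_check(rep(1, 8))$dw, 0)
  alt <- rep(c(1, -1), 4)
  expect_equal(durbin_watson_check(alt)$dw, sum(diff(alt)^2) / sum(alt^2))
  expect_equal(durbin_watson_check(alt)$dw, 3.5)
  expect_error(durbin_watson_check(rep(0, 10)), "zero residual")

  # published bound values and zone assignments
  b <- dw_bounds(18L, 1L, 0.05)
  expect_equal(round(b$d_L, 3), 1.158)
  expect_equal(round(b$d_U, 3), 1.391)
  expect_equal(round(4 - b$d_U, 3), 2.609)
  b17 <- dw_bounds(17L, 1L, 0.05)
  expect_equal(round(b17$d_L, 3), 1.133)
  expect_equal(round(b17$d_U, 3), 1.381)

  zone_of <- function(dw, n) {
    bb <- dw_bounds(n, 1L, 0.05)
    if (dw < bb$d_L) "positive-autocorrelation"
    else if (dw < bb$d_U) "inconclusive"
    else if (dw <= 4 - bb$d_U) "no-autocorrelation"
    else if (dw <= 4 - bb$d_L) "inconclusive-negative"
    else "negative-autocorrelation"
  }
  expect_equal(zone_of(1.164, 18L), "inconclusive")
  expect_equal(zone_of(2.256, 17L), "no-autocorrelation")
  expect_equal(zone_of(1.969, 18L), "no-autocorrelation")
  expect_equal(zone_of(0.9, 18L), "positive-autocorrelation")
  expect_equal(zone_of(3.2, 18L), "negative-autocorrelation")
})

test_that("the DW statistic matches lmtest and stays in [0, 4] with mean near 2", {
  skip_if_not_installed("lmtest")
  ser <- std_series(seed = 55L)
  f <- fit_ols(ser)
  ref <- unname(lmtest::dwtest(lm(response ~ concentration,
                                  data = as.data.frame(ser)))$statistic)
  expect_equal(durbin_watson_check(f)$dw, ref, tolerance = 1e-9)

  dws <- vapply(1:1000, function(s) {
    durbin_watson_check(fit_ols(std_series(seed = s + 3000)))$dw
  }, numeric(1))
  expect_true(all(dws >= 0 & dws <= 4))
  expect_lt(abs(mean(dws) - 2), 0.1)
})

test_that("Imhof bound quantiles match direct simulation of the bounding laws", {
  # d_L's null law: weighted chi-square ratio over the n - m - 1 smallest
  # eigenvalues of the differencing matrix; simulate it directly
  n <- 12L
  m <- 1L
  lam <- 4 * sin(pi * seq_len(n - 1L) / (2 * n))^2
  set.seed(77)
  sim_q <- function(ev) {
    z2 <- matrix(rnorm(length(ev) * 2e5)^2, nrow = length(ev))
    quantile(colSums(z2 * ev) / colSums(z2), 0.05, names = FALSE)
  }
  b <- dw_bounds(n, m, 0.05)
  expect_equal(b$d_L, sim_q(lam[seq_len(n - m - 1L)]), tolerance = 0.01)
  expect_equal(b$d_U, sim_q(lam[seq.int(m + 1L, n - 1L)]), tolerance = 0.01)
  expect_lt(b$d_L, b$d_U)
})

test_that("Q-Q plot data pairs ordered residuals with normal quantiles", {
  e <- c(0.3, -1.2, 0.8, -0.1)
  qq <- qq_data(e)
  expect_equal(qq$sample, sort(e))
  expect_equal(qq$theoretical, qnorm(ppoints(4)))
})
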