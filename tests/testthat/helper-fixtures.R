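# Shared fixtures: all synthetic, generated at test time.

# Standard six-level, three-cycle calibration series (the usual 18-point
# design), homoscedastic, linear truth.
std_series <- function(seed = 1L, noise_sd = 0.4, ...) {
  simulate_calibration(calib_sim_config(noise_sd = noise_sd, seed = seed, ...))
}

# Replace the response at the highest level by a saturated (depressed)
# value: a flat deficit applied to every replicate of the top level.
saturate_top_level <- function(series, deficit = 3) {
  r <- series$response
  top <- series$concentration == max(series$concentration)
  r[top] <- r[top] - deficit
  calibration_series(series$concentration, r, series$injection_order,
                     series$cycle, series$level_index,
                     analyte = attr(series, "analyte"), day = attr(series, "day"))
}

# Brute-force leave-one-out influence oracle: refits literally without
# observation i and rebuilds SDR, Cook's D, DFFITS and DFBETAS from the
# textbook definitions. Independent of the package's influence_table(),
# which delegates to the closed-form stats:: accessors.
loo_influence_oracle <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  fit_full <- lm(y ~ x)
  yhat_full <- fitted(fit_full)
  b_full <- coef(fit_full)
  s2_full <- sum(residuals(fit_full)^2) / (n - 2)
  XtXinv <- solve(crossprod(X))
  out <- data.frame(sdr = numeric(n), cooks_d = numeric(n),
                    dffits = numeric(n), dfbetas_intercept = numeric(n),
                    dfbetas_slope = numeric(n))
  for (i in seq_len(n)) {
    fit_i <- lm(y[-i] ~ x[-i])
    b_i <- coef(fit_i)
    s2_i <- sum(residuals(fit_i)^2) / (n - 3)
    xi <- c(1, x[i])
    XtXinv_i <- solve(crossprod(X[-i, , drop = FALSE]))
    pred_i <- sum(b_i * xi)
    # externally studentized residual: prediction error over its SE
    out$sdr[i] <- (y[i] - pred_i) /
      sqrt(s2_i * (1 + drop(t(xi) %*% XtXinv_i %*% xi)))
    yhat_i_all <- drop(cbind(1, x) %*% b_i)
    out$cooks_d[i] <- sum((yhat_full - yhat_i_all)^2) / (2 * s2_full)
    h_i <- drop(t(xi) %*% XtXinv %*% xi)
    out$dffits[i] <- (yhat_full[i] - pred_i) / sqrt(s2_i * h_i)
    out$dfbetas_intercept[i] <- (b_full[1] - b_i[1]) / sqrt(s2_i * XtXinv[1, 1])
    out$dfbetas_slope[i] <- (b_full[2] - b_i[2]) / sqrt(s2_i * XtXinv[2, 2])
  }
  out
}
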