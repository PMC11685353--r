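#' Per-observation influence and outlier diagnostics
#'
#' Leverage, studentized deleted residuals (SDR), Cook's distance, DFFITS,
#' and per-coefficient DFBETAS for a calibration fit. All quantities use
#' the standard leave-one-out definitions: the SDR is the externally
#' studentized residual (leave-one-out variance estimate), DFFITS is
#' `SDR * sqrt(h / (1 - h))`, Cook's D is `e^2 h / (p s2_yx (1 - h)^2)`,
#' and DFBETAS is the coefficient change on deletion scaled by the
#' deleted-fit SE. An exact-interpolation point (leverage 1) is flagged and
#' its deletion measures reported as `NA`.
#'
#' @param fit A [fit_ols()] result with at least `order + 3` observations.
#' @return A data frame of class `influence_table`, rows in injection
#'   order: `injection_order`, `concentration`, `leverage`, `sdr`,
#'   `cooks_d`, `dffits`, `dfbetas_intercept`, `dfbetas_slope`
#'   (`dfbetas_quadratic` for order-2 fits), `undefined`.
#' @export
influence_table <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  p <- fit$order + 1L
  if (fit$n < p + 2L) stop("too few observations for deletion diagnostics", call. = FALSE)
  lmfit <- fit$lm
  h <- unname(stats::hatvalues(lmfit))
  bad <- h >= 1 - 1e-12
  sdr <- unname(stats::rstudent(lmfit))
  cd <- unname(stats::cooks.distance(lmfit))
  dff <- unname(stats::dffits(lmfit))
  dfb <- unname(stats::dfbetas(lmfit))
  sdr[bad] <- NA_real_
  dff[bad] <- NA_real_
  out <- data.frame(injection_order = seq_len(fit$n),
                    concentration = fit$x,
                    leverage = h, sdr = sdr, cooks_d = cd, dffits = dff,
                    dfbetas_intercept = dfb[, 1L],
                    dfbetas_slope = dfb[, 2L])
  if (fit$order == 2L) out$dfbetas_quadratic <- dfb[, 3L]
  out$undefined <- bad
  structure(out, class = c("influence_table", "data.frame"))
}

#' Outlier decision thresholds
#'
#' Fixed conventions for the all-thresholds outlier rule: |SDR| > 3.0
#' (alpha = 0.01), Cook's D above the median of the F(p, n - p)
#' distribution (0.724 for n = 18, p = 2), |DFFITS| > 1.0 and
#' max |DFBETAS| > 1.0. Leverage cut-offs are advisory only (evenly spaced
#' calibration levels make x-outliers uninformative); both the `2p/n` and
#' `4/n` conventions are reported. The t-quantile behind the SDR rule is
#' included for transparency.
#'
#' @param n Number of observations.
#' @param p Number of regression coefficients (2 for a straight line).
#' @param sdr_alpha Significance level associated with the SDR threshold.
#' @return A list of class `outlier_thresholds`.
#' @examples
#' outlier_thresholds(18, 2)$cooks_crit # 0.724
#' @export
outlier_thresholds <- function(n, p = 2L, sdr_alpha = 0.01) {
  if (n <= p) stop("`n` must exceed the number of coefficients", call. = FALSE)
  structure(
    list(sdr_crit = 3.0,
         sdr_t_quantile = stats::qt(1 - sdr_alpha / 2, n - p - 1L),
         cooks_crit = stats::qf(0.5, p, n - p),
         dffits_crit = 1.0,
         dfbetas_crit = 1.0,
         leverage_crit = 2 * p / n,
         leverage_crit_4n = 4 / n,
         n = n, p = p),
    class = "outlier_thresholds"
  )
}

#' Apply the all-thresholds outlier rule
#'
#' An observation is an outlier only if it exceeds *all* of the SDR,
#' Cook's D, DFFITS and (maximum absolute) DFBETAS thresholds
#' simultaneously; observations exceeding some but not all are reported as
#' suspects with the exceeded measures listed. Leverage is advisory and
#' never triggers a verdict on its own.
#'
#' @param table An [influence_table()].
#' @param thresholds An [outlier_thresholds()] for the same fit.
#' @return The table with added columns `exceeded` (comma-separated list of
#'   exceeded measures) and `verdict` (`"ok"`, `"suspect"`, `"outlier"`).
#' @export
flag_outliers <- function(table, thresholds) {
  stopifnot(inherits(table, "influence_table"),
            inherits(thresholds, "outlier_thresholds"))
  dfb_cols <- grep("^dfbetas_", names(table), value = TRUE)
  max_dfb <- do.call(pmax, c(lapply(table[dfb_cols], abs), list(na.rm = TRUE)))
  exc <- cbind(
    SDR = abs(table$sdr) > thresholds$sdr_crit,
    cooks_d = table$cooks_d > thresholds$cooks_crit,
    DFFITS = abs(table$dffits) > thresholds$dffits_crit,
    DFBETAS = max_dfb > thresholds$dfbetas_crit
  )
  exc[is.na(exc)] <- FALSE
  out <- table
  out$max_abs_dfbetas <- max_dfb
  out$exceeded <- apply(exc, 1L, function(r) paste(colnames(exc)[r], collapse = ","))
  out$verdict <- ifelse(rowSums(exc) == ncol(exc), "outlier",
                        ifelse(rowSums(exc) > 0, "suspect", "ok"))
  out
}
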