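#' Calibration series container
#'
#' Per-injection calibration data for one analyte on one day: concentration
#' (µmol/L), response (peak area by convention, peak height for the
#' detection-limit slope approach), and the injection chronology needed for
#' the autocorrelation check. Rows are kept in injection order.
#'
#' @param concentration Numeric concentrations (µmol/L).
#' @param response Numeric responses.
#' @param injection_order Integer chronology of the injections.
#' @param cycle Integer cycle index per observation.
#' @param level_index Integer concentration-level index per observation.
#' @param analyte,day Labels.
#' @return A data frame of class `calibration_series` with attributes
#'   `analyte` and `day`.
#' @export
calibration_series <- function(concentration, response,
                               injection_order = seq_along(concentration),
                               cycle = rep(1L, length(concentration)),
                               level_index = match(concentration, sort(unique(concentration))),
                               analyte = "analyte", day = "day 1") {
  n <- length(concentration)
  if (length(response) != n || length(injection_order) != n ||
      length(cycle) != n || length(level_index) != n) {
    stop("all per-observation columns must have equal length", call. = FALSE)
  }
  if (anyDuplicated(injection_order)) {
    stop("`injection_order` must be unique", call. = FALSE)
  }
  df <- data.frame(level_index = as.integer(level_index),
                   cycle = as.integer(cycle),
                   injection_order = as.integer(injection_order),
                   concentration = as.numeric(concentration),
                   response = as.numeric(response))
  df <- df[order(df$injection_order), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, analyte = analyte, day = day,
            class = c("calibration_series", "data.frame"))
}

#' @export
print.calibration_series <- function(x, ...) {
  cat(sprintf("<calibration series: %s, %s; %d observations, %d levels>\n",
              attr(x, "analyte"), attr(x, "day"), nrow(x),
              length(unique(x$level_index))))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read / write calibration series as CSV
#'
#' Columns: `analyte, level_index, cycle, injection_order,
#' concentration_umol_L, response` (the format written by the synthetic
#' generator). A file may hold several analytes/days; `read_calibration_csv`
#' returns one series per `(analyte, day)` combination.
#'
#' @param path File path.
#' @return A list of [calibration_series] objects (length one for a
#'   single-analyte file).
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("analyte", "level_index", "cycle", "injection_order",
            "concentration_umol_L", "response")
  if (!all(need %in% names(df))) {
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"day" %in% names(df)) df$day <- "day 1"
  split_keys <- interaction(df$analyte, df$day, drop = TRUE)
  lapply(split(df, split_keys), function(d) {
    calibration_series(d$concentration_umol_L, d$response, d$injection_order,
                       d$cycle, d$level_index,
                       analyte = d$analyte[1L], day = d$day[1L])
  })
}

#' @rdname read_calibration_csv
#' @param series A [calibration_series].
#' @export
write_calibration_csv <- function(series, path) {
  df <- data.frame(analyte = attr(series, "analyte"),
                   day = attr(series, "day"),
                   level_index = series$level_index,
                   cycle = series$cycle,
                   injection_order = series$injection_order,
                   concentration_umol_L = series$concentration,
                   response = series$response)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit a first- or second-order calibration model by OLS
#'
#' Ordinary least squares, never forced through the origin:
#' `y = b0 + b1 x` (order 1) or `y = b0 + b1 x + b2 x^2` (order 2).
#' Residuals are kept in injection order so the Durbin-Watson statistic can
#' be computed against the chronology of injections. The residual variance
#' `s2_yx = SSE / (n - order - 1)` is the quantity used by the linearity
#' tests and the inter-day slope comparison.
#'
#' @param series A [calibration_series] (or data frame with columns
#'   `concentration` and `response`).
#' @param order 1 (straight line) or 2 (quadratic).
#' @return A list of class `regression_fit` with elements `order`,
#'   `coefficients` (`b0`, `b1`, and `b2` for order 2), `se`, `residuals`
#'   (injection order), `fitted`, `SSE`, `s2_yx`, `n`, `df`, `x`, `y`,
#'   and the underlying `lm` object.
#' @examples
#' s <- calibration_series(c(0, 1, 2), c(1, 3, 4))
#' fit <- fit_ols(s)
#' fit$coefficients # b0 = 7/6, b1 = 1.5
#' @export
fit_ols <- function(series, order = 1L) {
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2", call. = FALSE)
  x <- series$concentration
  y <- series$response
  n <- length(x)
  if (n <= order + 1L) stop("need more observations than coefficients", call. = FALSE)
  if (length(unique(x)) < order + 1L) {
    stop("rank-deficient design: too few distinct concentrations", call. = FALSE)
  }
  lmfit <- if (order == 1L) {
    stats::lm(y ~ x)
  } else {
    stats::lm(y ~ x + I(x^2))
  }
  cf <- stats::coef(lmfit)
  names(cf) <- c("b0", "b1", "b2")[seq_len(order + 1L)]
  res <- stats::residuals(lmfit)
  sse <- sum(res^2)
  df <- n - order - 1L
  s2 <- sse / df
  se <- sqrt(diag(s2 * chol2inv(qr.R(lmfit$qr))))
  names(se) <- names(cf)
  structure(
    list(order = order, coefficients = cf, se = se,
         residuals = unname(res), fitted = unname(stats::fitted(lmfit)),
         SSE = sse, s2_yx = s2, n = n, df = df,
         x = x, y = y, lm = lmfit,
         analyte = attr(series, "analyte"), day = attr(series, "day")),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  eq <- if (x$order == 1L) {
    sprintf("y = %.6g + %.6g x", x$coefficients["b0"], x$coefficients["b1"])
  } else {
    sprintf("y = %.6g + %.6g x + %.6g x^2",
            x$coefficients["b0"], x$coefficients["b1"], x$coefficients["b2"])
  }
  cat(sprintf("<OLS calibration fit (order %d): %s; n = %d, s2_yx = %.4g>\n",
              x$order, eq, x$n, x$s2_yx))
  invisible(x)
}

#' Per-coefficient t-tests and confidence intervals
#'
#' Each coefficient divided by its standard error gives a t-statistic with
#' the fit's residual degrees of freedom; two-sided p-values and
#' `estimate +/- t * SE` confidence limits are reported. A zero SE (perfect
#' fit) is flagged as degenerate with p reported as 0. Optionally reports
#' HC3 heteroscedasticity-consistent standard errors alongside (first-order
#' fits), as a remedy when homoscedasticity fails.
#'
#' @param fit A [fit_ols()] result.
#' @param alpha Two-sided significance level (default 0.05).
#' @param hc3 If `TRUE`, add HC3 standard errors and the t/p recomputed
#'   from them.
#' @return Data frame with one row per coefficient: `estimate`, `se`, `t`,
#'   `p`, `ci_lower`, `ci_upper`, `significant`, `degenerate` (plus
#'   `se_hc3`, `t_hc3`, `p_hc3` when requested).
#' @export
coefficient_tests <- function(fit, alpha = 0.05, hc3 = FALSE) {
  stopifnot(inherits(fit, "regression_fit"))
  if (fit$df < 1L) stop("at least one residual degree of freedom required", call. = FALSE)
  est <- fit$coefficients
  se <- fit$se
  # a numerically exact fit leaves only rounding noise in the SSE
  degen <- se == 0 | fit$SSE <= 1e-20 * max(1, sum(fit$y^2))
  tval <- ifelse(degen, Inf * sign(est), est / se)
  p <- ifelse(degen, 0, 2 * stats::pt(-abs(tval), fit$df))
  tcrit <- t_critical(alpha, fit$df)
  out <- data.frame(coefficient = names(est), estimate = unname(est),
                    se = unname(se), t = unname(tval), p = unname(p),
                    ci_lower = unname(est - tcrit * se),
                    ci_upper = unname(est + tcrit * se),
                    significant = unname(p < alpha),
                    degenerate = unname(degen))
  if (hc3) {
    X <- stats::model.matrix(fit$lm)
    h <- stats::hatvalues(fit$lm)
    e <- fit$residuals
    XtXinv <- chol2inv(qr.R(fit$lm$qr))
    meat <- t(X) %*% (X * (e^2 / (1 - h)^2))
    vc <- XtXinv %*% meat %*% XtXinv
    se3 <- sqrt(diag(vc))
    out$se_hc3 <- se3
    out$t_hc3 <- out$estimate / se3
    out$p_hc3 <- 2 * stats::pt(-abs(out$t_hc3), fit$df)
  }
  out
}

#' Two-sided Student-t critical value
#'
#' Upper `1 - alpha/2` quantile of the t distribution, e.g.
#' `t_critical(0.05, 17)` is 2.11 — the multiplier used for 95% confidence
#' intervals on skewness and kurtosis at n = 18.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return The quantile.
#' @export
t_critical <- function(alpha, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(df) || df < 1) stop("`df` must be at least 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}
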