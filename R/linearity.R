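#' Mandel fitting test for calibration linearity
#'
#' Genuine (extra-sum-of-squares) form: the first-order fit is compared to
#' the nested quadratic alternative through
#' `F = (SSE_linear - SSE_quadratic) / (SSE_quadratic / (n - 3))`
#' against `F(1, n - 3)`. A significant statistic means the quadratic term
#' improves the fit, i.e. the calibration is non-linear over the tested
#' range. A perfect quadratic fit (SSE = 0) is reported with p = 0 and a
#' degenerate flag; a perfect linear fit is linear with a degenerate flag.
#'
#' @param series A [calibration_series] with at least five concentration
#'   levels.
#' @param alpha Test level (default 0.01).
#' @return A list of class `linearity_result`: `test`, `F`, `p`, `alpha`,
#'   `linear` (verdict at `alpha`), `n`, `levels`, `degenerate`,
#'   `removed_levels`, `retained_range`.
#' @export
mandel_test <- function(series, alpha = 0.01) {
  n_levels <- length(unique(series$concentration))
  if (n_levels < 5L) {
    stop("Mandel fitting test requires at least five calibration levels", call. = FALSE)
  }
  fit1 <- fit_ols(series, 1L)
  fit2 <- fit_ols(series, 2L)
  n <- fit1$n
  noise_floor <- 1e-20 * max(1, sum(series$response^2))
  if (fit1$SSE <= noise_floor) {
    # exact line: both models perfect
    degen <- TRUE
    res <- list(F = 0, p = 1, linear = TRUE)
  } else if (fit2$SSE <= noise_floor || fit2$SSE < 1e-12 * fit1$SSE) {
    degen <- TRUE
    res <- list(F = Inf, p = 0, linear = FALSE)
  } else {
    degen <- FALSE
    Fval <- (fit1$SSE - fit2$SSE) / (fit2$SSE / (n - 3L))
    p <- stats::pf(Fval, 1L, n - 3L, lower.tail = FALSE)
    res <- list(F = Fval, p = p, linear = p >= alpha)
  }
  structure(
    list(test = "MFT", F = res$F, p = res$p, alpha = alpha,
         linear = res$linear, n = n, levels = n_levels, degenerate = degen,
         removed_levels = 0L,
         retained_range = range(series$concentration)),
    class = "linearity_result"
  )
}

#' Lack-of-fit test for calibration linearity
#'
#' Classic ANOVA decomposition of the first-order residual sum of squares
#' into lack-of-fit (`sum n_j (ybar_j - yhat_j)^2`, df `k - 2`) and pure
#' error (`sum (y_ij - ybar_j)^2`, df `n - k`), with
#' `F = MS_lack / MS_pure` against `F(k - 2, n - k)`. Requires at least
#' three replicates per level so the pure-error estimate is meaningful.
#'
#' @param series A [calibration_series] with >= 3 levels and >= 3
#'   replicates per level.
#' @param alpha Test level (default 0.01).
#' @return A `linearity_result` (see [mandel_test()]) with additional
#'   fields `ss_lack`, `ss_pure`, `df_lack`, `df_pure`.
#' @export
lof_test <- function(series, alpha = 0.01) {
  conc <- series$concentration
  k <- length(unique(conc))
  if (k < 3L) stop("lack-of-fit test requires at least three levels", call. = FALSE)
  reps <- table(conc)
  if (any(reps < 3L)) {
    stop("lack-of-fit test requires at least three replicates per level", call. = FALSE)
  }
  fit <- fit_ols(series, 1L)
  n <- fit$n
  level_means <- tapply(series$response, conc, mean)
  ybar <- level_means[as.character(conc)]
  ss_pure <- sum((series$response - ybar)^2)
  ss_lack <- fit$SSE - ss_pure
  df_lack <- k - 2L
  df_pure <- n - k
  if (ss_pure <= 1e-12 * max(1, sum(series$response^2))) {
    degen <- TRUE
    Fval <- if (ss_lack <= 1e-12 * max(1, sum(series$response^2))) 0 else Inf
    p <- if (is.infinite(Fval)) 0 else 1
  } else {
    degen <- FALSE
    Fval <- (ss_lack / df_lack) / (ss_pure / df_pure)
    Fval <- max(Fval, 0)
    p <- stats::pf(Fval, df_lack, df_pure, lower.tail = FALSE)
  }
  structure(
    list(test = "LOF", F = Fval, p = p, alpha = alpha,
         linear = p >= alpha, n = n, levels = k, degenerate = degen,
         ss_lack = ss_lack, ss_pure = ss_pure,
         df_lack = df_lack, df_pure = df_pure,
         removed_levels = 0L, retained_range = range(conc)),
    class = "linearity_result"
  )
}

#' @export
print.linearity_result <- function(x, ...) {
  verdict <- if (isTRUE(x$no_linear_range)) {
    "no linear range found"
  } else if (x$linear) "linear" else "non-linear"
  cat(sprintf("%s: F = %.4g, p = %.4g (alpha = %g) -> %s", x$test, x$F, x$p,
              x$alpha, verdict))
  if (x$removed_levels > 0L) {
    cat(sprintf("; %d highest level(s) removed, retained [%g, %g]",
                x$removed_levels, x$retained_range[1L], x$retained_range[2L]))
  }
  cat("\n")
  invisible(x)
}

#' Stepwise elimination of the highest calibration level
#'
#' When the chosen linearity test is significant, the highest remaining
#' concentration level is deleted and the test repeated on the reduced
#' design (pure error re-estimated on the reduced design for the LOF test)
#' until the quadratic departure becomes insignificant or the design falls
#' below the test's minimum (five levels for the Mandel test, three for
#' lack-of-fit). Failure to ever reach linearity is reported as such
#' rather than continuing below the floor.
#'
#' @param series A [calibration_series].
#' @param test `"MFT"` or `"LOF"`.
#' @param alpha Test level (default 0.01).
#' @return The final `linearity_result` with `removed_levels`,
#'   `retained_range`, `no_linear_range` and a `history` list of the
#'   per-step results.
#' @export
stepwise_linearity <- function(series, test = c("MFT", "LOF"), alpha = 0.01) {
  test <- match.arg(test)
  run <- if (test == "MFT") mandel_test else lof_test
  floor_levels <- if (test == "MFT") 5L else 3L
  cur <- series
  removed <- 0L
  history <- list()
  full_range <- range(series$concentration)
  repeat {
    res <- run(cur, alpha = alpha)
    res$removed_levels <- removed
    res$retained_range <- range(cur$concentration)
    history[[length(history) + 1L]] <- res
    if (res$linear) {
      res$no_linear_range <- FALSE
      res$history <- history
      return(res)
    }
    n_levels <- length(unique(cur$concentration))
    if (n_levels - 1L < floor_levels) {
      res$no_linear_range <- TRUE
      res$linear <- FALSE
      res$history <- history
      return(res)
    }
    top <- max(cur$concentration)
    keep <- cur$concentration < top
    cur <- calibration_series(cur$concentration[keep], cur$response[keep],
                              cur$injection_order[keep], cur$cycle[keep],
                              cur$level_index[keep],
                              analyte = attr(series, "analyte"),
                              day = attr(series, "day"))
    removed <- removed + 1L
  }
}

#' F-test for equality of two residual variances
#'
#' Fisher-Snedecor test on the regression-model variances `s2_yx` of two
#' calibration fits (larger over smaller), two-sided p-value. This is the
#' homogeneity gate before choosing between the pooled and Welch slope
#' comparisons.
#'
#' @param fit_a,fit_b [fit_ols()] results.
#' @param alpha Test level (default 0.01).
#' @return List with `F`, `df_num`, `df_den`, `p`, `equal_variances`.
#' @export
variance_f_test <- function(fit_a, fit_b, alpha = 0.01) {
  stopifnot(inherits(fit_a, "regression_fit"), inherits(fit_b, "regression_fit"))
  if (fit_a$df < 1L || fit_b$df < 1L) stop("both fits need df >= 1", call. = FALSE)
  s2 <- c(fit_a$s2_yx, fit_b$s2_yx)
  df <- c(fit_a$df, fit_b$df)
  if (any(s2 == 0)) stop("zero residual variance", call. = FALSE)
  big <- which.max(s2)
  small <- 3L - big
  Fval <- s2[big] / s2[small]
  p <- min(1, 2 * stats::pf(Fval, df[big], df[small], lower.tail = FALSE))
  list(F = Fval, df_num = df[big], df_den = df[small], p = p,
       alpha = alpha, equal_variances = p >= alpha)
}

#' Compare two calibration slopes (pooled and Welch t-tests)
#'
#' Tests equality of the slopes of two independent first-order calibration
#' fits. Both tests use the regression-model variance `s2_yx` (not the
#' slope variance): the slope-difference variance per fit is
#' `v = s2_yx / Sxx`. Welch's statistic is
#' `t = (b1_a - b1_b) / sqrt(v_a + v_b)` with fractional Aspin-Welch
#' degrees of freedom
#' `nu = (v_a + v_b)^2 / (v_a^2/(n_a - 2) + v_b^2/(n_b - 2))`; the pooled
#' test replaces both `s2_yx` by their df-weighted pool on
#' `n_a + n_b - 4` degrees of freedom. The variance homogeneity F-test is
#' run alongside at `f_alpha`.
#'
#' @param fit_a,fit_b First-order [fit_ols()] results with >= 4
#'   observations each.
#' @param alpha Slope-test level (default 0.05).
#' @param f_alpha Level of the variance homogeneity gate (default 0.01).
#' @return A list of class `slope_comparison` with elements
#'   `f_variances`, `welch` (`t`, `df`, `p`, `equal_slopes`), `pooled`
#'   (likewise), `slope_a`, `slope_b`.
#' @export
compare_slopes <- function(fit_a, fit_b, alpha = 0.05, f_alpha = 0.01) {
  stopifnot(inherits(fit_a, "regression_fit"), inherits(fit_b, "regression_fit"))
  if (fit_a$order != 1L || fit_b$order != 1L) {
    stop("slope comparison is defined for first-order fits", call. = FALSE)
  }
  if (fit_a$n < 4L || fit_b$n < 4L) {
    stop("both fits need at least 4 observations", call. = FALSE)
  }
  sxx_a <- sum((fit_a$x - mean(fit_a$x))^2)
  sxx_b <- sum((fit_b$x - mean(fit_b$x))^2)
  if (sxx_a == 0 || sxx_b == 0) stop("zero Sxx in a design", call. = FALSE)
  b1a <- fit_a$coefficients[["b1"]]
  b1b <- fit_b$coefficients[["b1"]]
  va <- fit_a$s2_yx / sxx_a
  vb <- fit_b$s2_yx / sxx_b

  t_w <- (b1a - b1b) / sqrt(va + vb)
  df_w <- (va + vb)^2 / (va^2 / (fit_a$n - 2L) + vb^2 / (fit_b$n - 2L))
  p_w <- 2 * stats::pt(-abs(t_w), df_w)

  df_p <- fit_a$n + fit_b$n - 4L
  s2_pool <- (fit_a$SSE + fit_b$SSE) / df_p
  t_p <- (b1a - b1b) / sqrt(s2_pool / sxx_a + s2_pool / sxx_b)
  p_p <- 2 * stats::pt(-abs(t_p), df_p)

  structure(
    list(f_variances = variance_f_test(fit_a, fit_b, alpha = f_alpha),
         welch = list(t = t_w, df = df_w, p = p_w, equal_slopes = p_w >= alpha),
         pooled = list(t = t_p, df = df_p, p = p_p, equal_slopes = p_p >= alpha),
         slope_a = b1a, slope_b = b1b, alpha = alpha),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slopes %.6g vs %.6g\n", x$slope_a, x$slope_b))
  cat(sprintf("  variance F = %.4g, p = %.4g (%s at alpha = %g)\n",
              x$f_variances$F, x$f_variances$p,
              if (x$f_variances$equal_variances) "homogeneous" else "heterogeneous",
              x$f_variances$alpha))
  cat(sprintf("  Welch  t = %.4g, df = %.2f, p = %.4g\n",
              x$welch$t, x$welch$df, x$welch$p))
  cat(sprintf("  pooled t = %.4g, df = %d, p = %.4g\n",
              x$pooled$t, x$pooled$df, x$pooled$p))
  invisible(x)
}
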