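#' System-suitability acceptance criteria
#'
#' The acceptance windows checked before a run is used quantitatively:
#' minimum electrophoretic resolution of the critical pair, apex-pixel
#' windows per marker, absolute peak-height window for the reference
#' marker, optional height-ratio windows relative to that reference, and
#' the profile-scan intensity window of the imaging cartridge. Defaults
#' follow the validated method (resolution > 6.50; apex windows 370-400
#' and 1880-2000 pixels for the flanking markers; reference height
#' 0.315-0.365 AU; profile scan 8000-15550 intensity units).
#'
#' @param rs_min Minimum resolution of the critical pair.
#' @param apex_windows Named list of `c(pixel_lo, pixel_hi)` windows.
#' @param height_windows Named list of `c(AU_lo, AU_hi)` windows.
#' @param height_ratio_windows Named list of `c(lo, hi)` windows for
#'   heights relative to `reference_analyte` (no defaults shipped).
#' @param reference_analyte Name of the height-ratio reference.
#' @param profile_scan_window `c(lo, hi)` intensity window.
#' @return An object of class `suitability_criteria`.
#' @export
suitability_criteria <- function(rs_min = 6.50,
                                 apex_windows = list(`pI 4.65` = c(370, 400),
                                                     `pI 7.05` = c(1880, 2000)),
                                 height_windows = list(`pI 7.05` = c(0.315, 0.365)),
                                 height_ratio_windows = list(),
                                 reference_analyte = "pI 7.05",
                                 profile_scan_window = c(8000, 15550)) {
  check_win <- function(w, what) {
    for (nm in names(w)) {
      if (length(w[[nm]]) != 2L || w[[nm]][1L] > w[[nm]][2L]) {
        stop(sprintf("%s window for %s must be c(lo, hi) with lo <= hi", what, nm),
             call. = FALSE)
      }
    }
  }
  check_win(apex_windows, "apex")
  check_win(height_windows, "height")
  check_win(height_ratio_windows, "height-ratio")
  structure(list(rs_min = rs_min, apex_windows = apex_windows,
                 height_windows = height_windows,
                 height_ratio_windows = height_ratio_windows,
                 reference_analyte = reference_analyte,
                 profile_scan_window = profile_scan_window),
            class = "suitability_criteria")
}

#' Evaluate suitability criteria
#'
#' Checks measured run characteristics against a [suitability_criteria()]
#' object. Every supplied measurement is evaluated; the overall verdict is
#' a pass only if all individual checks pass. A criterion referencing an
#' analyte without a measurement raises an error.
#'
#' @param measured List with any of: `rs` (resolution of the critical
#'   pair), `apex_pixels` (named), `heights` (named AU), `profile_scan`
#'   (vector of intensity values or its range).
#' @param criteria A [suitability_criteria()].
#' @return List of class `suitability_result`: `pass`, `checks` (data
#'   frame with `check`, `value`, `lo`, `hi`, `pass`).
#' @export
suitability_check <- function(measured, criteria = suitability_criteria()) {
  stopifnot(inherits(criteria, "suitability_criteria"))
  rows <- list()
  add <- function(check, value, lo, hi) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, lo = lo, hi = hi,
      pass = is.finite(value) && value >= lo && value <= hi
    )
  }
  if (!is.null(measured$rs)) add("resolution", measured$rs, criteria$rs_min, Inf)
  for (nm in names(criteria$apex_windows)) {
    if (is.null(measured$apex_pixels) || !nm %in% names(measured$apex_pixels)) {
      stop("missing apex-pixel measurement for ", nm, call. = FALSE)
    }
    w <- criteria$apex_windows[[nm]]
    add(paste0("apex: ", nm), measured$apex_pixels[[nm]], w[1L], w[2L])
  }
  for (nm in names(criteria$height_windows)) {
    if (is.null(measured$heights) || !nm %in% names(measured$heights)) {
      stop("missing height measurement for ", nm, call. = FALSE)
    }
    w <- criteria$height_windows[[nm]]
    add(paste0("height: ", nm), measured$heights[[nm]], w[1L], w[2L])
  }
  if (length(criteria$height_ratio_windows) > 0L) {
    ref <- measured$heights[[criteria$reference_analyte]]
    if (is.null(ref)) {
      stop("missing reference height for ", criteria$reference_analyte, call. = FALSE)
    }
    for (nm in names(criteria$height_ratio_windows)) {
      if (!nm %in% names(measured$heights)) {
        stop("missing height measurement for ", nm, call. = FALSE)
      }
      w <- criteria$height_ratio_windows[[nm]]
      add(paste0("height ratio: ", nm), measured$heights[[nm]] / ref, w[1L], w[2L])
    }
  }
  if (!is.null(measured$profile_scan)) {
    w <- criteria$profile_scan_window
    add("profile scan min", min(measured$profile_scan), w[1L], w[2L])
    add("profile scan max", max(measured$profile_scan), w[1L], w[2L])
  }
  checks <- do.call(rbind, rows)
  structure(list(pass = all(checks$pass), checks = checks),
            class = "suitability_result")
}

#' @export
print.suitability_result <- function(x, ...) {
  cat(sprintf("suitability: %s\n", if (x$pass) "PASS" else "FAIL"))
  print.data.frame(x$checks, row.names = FALSE)
  invisible(x)
}

#' Full assumption battery and linearity workup for one calibration series
#'
#' Runs the validation stages in their canonical order on one series:
#' first-order OLS fit, influence screening with the all-thresholds
#' outlier rule (optional removal and refit — removals are logged, never
#' silent), coefficient t-tests, normality suite, Breusch-Pagan,
#' Durbin-Watson against the injection chronology, and stepwise linearity
#' by both the Mandel fitting test and the lack-of-fit test.
#'
#' @param series A [calibration_series].
#' @param remove_outliers If `TRUE`, observations with verdict
#'   `"outlier"` are removed and the battery re-run on the reduced series
#'   (a single pass); the default flags without removing.
#' @param alpha Named list of significance levels
#'   (`outliers`, `normality`, `heteroscedasticity`, `autocorrelation`,
#'   `linearity`).
#' @param seed Seed for the bootstrap stages.
#' @return A list of class `series_validation` with the per-stage results
#'   and an `audit` data frame of removal decisions.
#' @export
validate_series <- function(series, remove_outliers = FALSE,
                            alpha = list(outliers = 0.01, normality = 0.05,
                                         heteroscedasticity = 0.05,
                                         autocorrelation = 0.05,
                                         linearity = 0.01),
                            seed = 1L) {
  fit <- fit_ols(series, 1L)
  thr <- outlier_thresholds(fit$n, fit$order + 1L, sdr_alpha = alpha$outliers)
  flags <- flag_outliers(influence_table(fit), thr)
  audit <- data.frame(injection_order = integer(), concentration = numeric(),
                      response = numeric(), reason = character())
  removed_series <- NULL
  if (remove_outliers && any(flags$verdict == "outlier")) {
    drop <- which(flags$verdict == "outlier")
    audit <- data.frame(
      injection_order = series$injection_order[drop],
      concentration = series$concentration[drop],
      response = series$response[drop],
      reason = sprintf("all-thresholds outlier (SDR %.3f, D %.3f, DFFITS %.3f, max|DFBETAS| %.3f)",
                       flags$sdr[drop], flags$cooks_d[drop], flags$dffits[drop],
                       flags$max_abs_dfbetas[drop])
    )
    keep <- setdiff(seq_len(nrow(series)), drop)
    removed_series <- calibration_series(
      series$concentration[keep], series$response[keep],
      series$injection_order[keep], series$cycle[keep], series$level_index[keep],
      analyte = attr(series, "analyte"), day = attr(series, "day"))
    fit <- fit_ols(removed_series, 1L)
    thr <- outlier_thresholds(fit$n, fit$order + 1L, sdr_alpha = alpha$outliers)
    flags <- flag_outliers(influence_table(fit), thr)
  }
  working <- if (is.null(removed_series)) series else removed_series
  lof <- tryCatch(stepwise_linearity(working, "LOF", alpha = alpha$linearity),
                  error = function(e) NULL)
  structure(
    list(analyte = attr(series, "analyte"), day = attr(series, "day"),
         fit = fit,
         coefficients = coefficient_tests(fit, alpha = 0.05),
         influence = flags, thresholds = thr, audit = audit,
         outliers_removed = nrow(audit),
         normality = normality_suite(fit$residuals, seed = seed),
         heteroscedasticity = breusch_pagan(fit, alpha = alpha$heteroscedasticity),
         autocorrelation = durbin_watson_check(fit, alpha = alpha$autocorrelation),
         linearity_mft = stepwise_linearity(working, "MFT", alpha = alpha$linearity),
         linearity_lof = lof),
    class = "series_validation"
  )
}

#' Run the full validation workflow from a configuration
#'
#' Orchestrates the whole pipeline from a config (a YAML file path or an
#' equivalent nested list): each analyte lists one series per day, given
#' either as a simulation spec (fields of [calib_sim_config()]) or a
#' calibration CSV path. Every series gets the full assumption battery
#' ([validate_series()]); analytes with exactly two days additionally get
#' the inter-day variance F-test and slope comparison. The report records
#' seeds and a config fingerprint so it is reproducible from config +
#' seed alone.
#'
#' @param config Path to a YAML config or a list. Top-level fields:
#'   `seed`, `remove_outliers`, `alpha` (optional overrides), `analytes`
#'   (list; each has `name` and `days`, each day a list with `day` plus
#'   either `simulate:` fields or `csv:` path).
#' @return A list of class `validation_report`.
#' @export
run_validation <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  remove_outliers <- isTRUE(config$remove_outliers)
  alpha <- utils::modifyList(
    list(outliers = 0.01, normality = 0.05, heteroscedasticity = 0.05,
         autocorrelation = 0.05, linearity = 0.01, slopes = 0.05,
         variance = 0.01),
    if (is.null(config$alpha)) list() else config$alpha
  )
  analytes <- list()
  for (an in config$analytes) {
    days <- list()
    for (d in an$days) {
      series <- if (!is.null(d$simulate)) {
        sim <- d$simulate
        sim$seed <- if (is.null(sim$seed)) seed else sim$seed
        if (!is.null(sim$levels)) sim$levels <- as.numeric(sim$levels)
        cfg <- do.call(calib_sim_config, sim)
        simulate_calibration(cfg, analyte = an$name, day = d$day)
      } else if (!is.null(d$csv)) {
        read_calibration_csv(d$csv)[[1L]]
      } else {
        stop("each day needs either `simulate` or `csv`", call. = FALSE)
      }
      days[[as.character(d$day)]] <- validate_series(
        series, remove_outliers = remove_outliers,
        alpha = alpha[c("outliers", "normality", "heteroscedasticity",
                        "autocorrelation", "linearity")],
        seed = seed)
    }
    comparison <- if (length(days) == 2L) {
      compare_slopes(days[[1L]]$fit, days[[2L]]$fit,
                     alpha = alpha$slopes, f_alpha = alpha$variance)
    } else {
      NULL
    }
    analytes[[an$name]] <- list(days = days, slope_comparison = comparison)
  }
  structure(
    list(seed = seed, remove_outliers = remove_outliers, alpha = alpha,
         config_hash = string_fingerprint(jsonlite::toJSON(config, auto_unbox = TRUE)),
         package_version = as.character(utils::packageVersion("iciefval")),
         note = paste("analytes tested independently at the per-test alpha;",
                      "no multiplicity correction"),
         analytes = analytes),
    class = "validation_report"
  )
}

# Strip non-serializable members (lm objects, closures) for JSON export.
.report_serializable <- function(x) {
  if (inherits(x, "regression_fit")) {
    x$lm <- NULL
    x <- unclass(x)
  }
  if (is.list(x)) {
    x <- lapply(x, .report_serializable)
  }
  x
}

#' Serialize a validation report to JSON
#'
#' Writes a machine-readable report; identical configs and seeds produce
#' byte-identical files.
#'
#' @param report A [run_validation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  json <- jsonlite::toJSON(.report_serializable(unclass(report)),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE, force = TRUE)
  writeLines(json, path)
  invisible(path)
}
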