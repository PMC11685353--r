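#' Electropherogram container
#'
#' A whole-column-imaged trace: strictly increasing 1-based pixel positions
#' with one absorbance value (AU) per pixel, plus free-form metadata (run
#' id, day, replicate, anchor markers).
#'
#' @param pixel Integer vector of strictly increasing pixel positions.
#' @param absorbance Numeric vector of the same length (AU).
#' @param metadata Named list of run-level metadata.
#' @return A data frame of class `electropherogram` with columns `pixel`
#'   and `absorbance` and a `metadata` attribute.
#' @export
electropherogram <- function(pixel, absorbance, metadata = list()) {
  if (length(pixel) != length(absorbance)) {
    stop("`pixel` and `absorbance` must have equal length", call. = FALSE)
  }
  if (length(pixel) == 0L) stop("trace must be non-empty", call. = FALSE)
  if (is.unsorted(pixel, strictly = TRUE)) {
    stop("`pixel` must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(pixel = as.integer(pixel), absorbance = as.numeric(absorbance)),
    metadata = metadata,
    class = c("electropherogram", "data.frame")
  )
}

#' @export
print.electropherogram <- function(x, ...) {
  cat(sprintf("<electropherogram: %d pixels, absorbance range [%.4g, %.4g] AU>\n",
              nrow(x), min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Read / write traces as two-column CSV
#'
#' The on-disk format is a plain CSV with columns `pixel` and `absorbance`.
#'
#' @param path File path.
#' @param metadata Metadata list attached on read.
#' @return `read_trace_csv()` returns an [electropherogram];
#'   `write_trace_csv()` invisibly returns `path`.
#' @export
read_trace_csv <- function(path, metadata = list()) {
  df <- utils::read.csv(path)
  if (!all(c("pixel", "absorbance") %in% names(df))) {
    stop("trace CSV must have columns `pixel` and `absorbance`", call. = FALSE)
  }
  electropherogram(df$pixel, df$absorbance, metadata = metadata)
}

#' @rdname read_trace_csv
#' @param trace An [electropherogram].
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("pixel", "absorbance")], path, row.names = FALSE)
  invisible(path)
}

#' Detect and integrate peaks in a trace
#'
#' The local baseline is a rolling median over `baseline_window` pixels
#' (odd; default 201). Apexes are strict local maxima of the
#' baseline-corrected signal exceeding `min_height`. For each apex the peak
#' region extends to the nearest baseline crossings (corrected signal <= 0)
#' on either side; area is the trapezoidal integral of the corrected signal
#' over that region, and the width is measured at 50% of the corrected
#' height with linear interpolation between pixels. A flat trace yields an
#' empty table.
#'
#' @param trace An [electropherogram].
#' @param min_height Minimum baseline-corrected apex height (AU) for a
#'   local maximum to count as a peak.
#' @param baseline_window Rolling-median window in pixels.
#' @param identity_windows Optional named list of `c(pixel_lo, pixel_hi)`
#'   windows used to label peaks whose apex falls inside.
#' @return A data frame of class `peak_table` with columns `apex_pixel`,
#'   `height`, `area`, `width_half_height`, `identity`.
#' @export
detect_peaks <- function(trace, min_height = 0.01, baseline_window = 201L,
                         identity_windows = NULL) {
  stopifnot(inherits(trace, "electropherogram"))
  if (min_height <= 0) stop("`min_height` must be positive", call. = FALSE)
  y <- trace$absorbance
  n <- length(y)
  k <- min(baseline_window, n)
  if (k %% 2L == 0L) k <- k - 1L
  k <- max(k, 1L)
  baseline <- if (k >= 3L) stats::runmed(y, k, endrule = "median") else y * 0
  s <- y - baseline

  empty <- data.frame(apex_pixel = integer(), height = numeric(),
                      area = numeric(), width_half_height = numeric(),
                      identity = character())
  if (n < 3L) return(structure(empty, class = c("peak_table", "data.frame")))

  d <- diff(s)
  apex <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  apex <- apex[s[apex] > min_height]
  if (length(apex) == 0L) return(structure(empty, class = c("peak_table", "data.frame")))

  rows <- lapply(apex, function(a) {
    h <- s[a]
    lo <- a
    while (lo > 1L && s[lo - 1L] > 0) lo <- lo - 1L
    hi <- a
    while (hi < n && s[hi + 1L] > 0) hi <- hi + 1L
    seg <- lo:hi
    area <- sum((s[seg[-length(seg)]] + s[seg[-1L]]) / 2)
    half <- h / 2
    # left crossing of the half-height level, interpolated
    il <- a
    while (il > lo && s[il - 1L] > half) il <- il - 1L
    xl <- if (il == lo && s[il] > half) il else {
      (il - 1L) + (half - s[il - 1L]) / (s[il] - s[il - 1L])
    }
    ir <- a
    while (ir < hi && s[ir + 1L] > half) ir <- ir + 1L
    xr <- if (ir == hi && s[ir] > half) ir else {
      ir + (s[ir] - half) / (s[ir] - s[ir + 1L])
    }
    data.frame(apex_pixel = trace$pixel[a], height = h, area = area,
               width_half_height = xr - xl, identity = NA_character_,
               region_lo = lo)
  })
  pk <- do.call(rbind, rows)
  # noise can raise several local maxima within one baseline-to-baseline
  # region; they are the same peak — keep the tallest apex per region
  pk <- pk[order(pk$region_lo, -pk$height), , drop = FALSE]
  pk <- pk[!duplicated(pk$region_lo), , drop = FALSE]
  pk <- pk[order(pk$apex_pixel), setdiff(names(pk), "region_lo"), drop = FALSE]
  rownames(pk) <- NULL
  if (!is.null(identity_windows)) {
    for (nm in names(identity_windows)) {
      w <- identity_windows[[nm]]
      inside <- pk$apex_pixel >= w[1L] & pk$apex_pixel <= w[2L]
      pk$identity[inside] <- nm
    }
  }
  structure(pk, class = c("peak_table", "data.frame"))
}

#' Electrophoretic resolution of two focused zones
#'
#' European-Pharmacopoeia half-height form:
#' `R_S = 1.18 * |apex_b - apex_a| / (w_a + w_b)` with widths measured at
#' 50% of peak height. Symmetric in its arguments.
#'
#' @param peak_a,peak_b Single rows of a [detect_peaks()] table (or any
#'   list-likes with `apex_pixel` and `width_half_height`).
#' @return Unitless resolution.
#' @examples
#' a <- list(apex_pixel = 1000, width_half_height = 10)
#' b <- list(apex_pixel = 1118, width_half_height = 10)
#' resolution(a, b) # 6.962
#' @export
resolution <- function(peak_a, peak_b) {
  wa <- peak_a$width_half_height
  wb <- peak_b$width_half_height
  if (is.null(wa) || is.null(wb) || wa <= 0 || wb <= 0) {
    stop("both peaks need positive half-height widths", call. = FALSE)
  }
  1.18 * abs(peak_b$apex_pixel - peak_a$apex_pixel) / (wa + wb)
}

#' Two-anchor pixel-to-pI mapping
#'
#' The acquisition software accepts exactly two reference markers, so the
#' map is the straight line through the two anchors; positions outside the
#' anchor interval are extrapolated on the same line but flagged, which is
#' why a third marker's focusing position can deviate slightly from its
#' nominal pI.
#'
#' @param anchor_low,anchor_high `c(pixel, pI)` pairs with
#'   `anchor_high` strictly above `anchor_low` in both coordinates.
#' @return An object of class `gradient_map`.
#' @export
gradient_map <- function(anchor_low, anchor_high) {
  if (length(anchor_low) != 2L || length(anchor_high) != 2L) {
    stop("anchors must be c(pixel, pI) pairs", call. = FALSE)
  }
  if (anchor_high[1L] <= anchor_low[1L] || anchor_high[2L] <= anchor_low[2L]) {
    stop("high anchor must exceed low anchor in both pixel and pI", call. = FALSE)
  }
  structure(list(anchor_low = anchor_low, anchor_high = anchor_high),
            class = "gradient_map")
}

#' Convert pixel positions to apparent pI
#'
#' Linear interpolation between the two anchors of a [gradient_map()];
#' extrapolation beyond the anchors is permitted and marked in the
#' `extrapolated` attribute of the result.
#'
#' @param map A `gradient_map`.
#' @param pixel Numeric vector of pixel positions.
#' @return Numeric vector of pI values with a logical `extrapolated`
#'   attribute of the same length.
#' @export
pixel_to_pi <- function(map, pixel) {
  stopifnot(inherits(map, "gradient_map"))
  slope <- (map$anchor_high[2L] - map$anchor_low[2L]) /
    (map$anchor_high[1L] - map$anchor_low[1L])
  pi_val <- map$anchor_low[2L] + slope * (pixel - map$anchor_low[1L])
  structure(pi_val,
            extrapolated = pixel < map$anchor_low[1L] | pixel > map$anchor_high[1L])
}

#' Apparent pI with a day-level 95% confidence interval
#'
#' Respects the nested design (several injection replicates on each of
#' several days): the estimate is the grand mean of the per-day mean pIs and
#' the half-width is `t(0.975, n_days - 1) * SD(day means) / sqrt(n_days)`.
#'
#' @param day_values Numeric vector of per-day mean pI values (length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `mean`, `ci_half_width`, `n_days`.
#' @export
apparent_pi <- function(day_values, conf_level = 0.95) {
  n <- length(day_values)
  if (n < 2L) stop("at least two day means are required", call. = FALSE)
  m <- mean(day_values)
  hw <- stats::qt(1 - (1 - conf_level) / 2, n - 1L) * stats::sd(day_values) / sqrt(n)
  list(mean = m, ci_half_width = hw, n_days = n)
}

#' Precision summary (repeatability or intermediate precision)
#'
#' Coefficient of variation `CV = 100 * SD / mean` with the sample SD
#' (n - 1 denominator). `scope` records whether the replicates are
#' within-day (repeatability) or across days (intermediate precision).
#'
#' @param values Numeric replicate measurements (length >= 2, nonzero mean).
#' @param scope One of `"repeatability"`, `"intermediate_precision"`.
#' @return List of class `precision_summary` with `mean`, `sd`, `cv`
#'   (percent), `n`, `scope`.
#' @export
precision_summary <- function(values,
                              scope = c("repeatability", "intermediate_precision")) {
  scope <- match.arg(scope)
  n <- length(values)
  if (n < 2L) stop("at least two replicates are required", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero; CV undefined", call. = FALSE)
  s <- stats::sd(values)
  structure(list(mean = m, sd = s, cv = 100 * s / m, n = n, scope = scope),
            class = "precision_summary")
}

#' @export
print.precision_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.5g, SD %.3g, CV %.2f%% (n = %d)\n",
              gsub("_", " ", x$scope), x$mean, x$sd, x$cv, x$n))
  invisible(x)
}
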