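#' Baseline noise by the core-noise convention
#'
#' Noise is assessed on a blank trace within +/- `half_window` pixels of
#' the analyte's average focusing position. After linear detrending of the
#' window, the core-noise range is the central 95% span of the detrended
#' values (2.5th to 97.5th percentile), which for Gaussian noise
#' approximates four standard deviations while clipping extreme
#' excursions. The baseline noise `N` is the positive half of that range
#' (about two SDs), the quantity entering signal-to-noise ratios.
#'
#' @param blank An [electropherogram] of a blank run.
#' @param apex_pixel Average pixel position of the analyte's focused zone.
#' @param half_window Half-width of the baseline window in pixels
#'   (default 100, at least five half-height peak widths for typical
#'   zones).
#' @return A list of class `noise_estimate`: `window`, `core_noise_range`,
#'   `N`, `n_pixels_used`.
#' @export
estimate_noise <- function(blank, apex_pixel, half_window = 100L) {
  stopifnot(inherits(blank, "electropherogram"))
  lo <- apex_pixel - half_window
  hi <- apex_pixel + half_window
  if (lo < min(blank$pixel) || hi > max(blank$pixel)) {
    stop("noise window exceeds trace bounds", call. = FALSE)
  }
  sel <- blank$pixel >= lo & blank$pixel <= hi
  px <- blank$pixel[sel]
  y <- blank$absorbance[sel]
  detr <- stats::residuals(stats::lm(y ~ px))
  qs <- stats::quantile(detr, c(0.025, 0.975), names = FALSE)
  core <- qs[2L] - qs[1L]
  structure(list(window = c(lo, hi), core_noise_range = core, N = core / 2,
                 n_pixels_used = length(y)),
            class = "noise_estimate")
}

#' LOD and LOQ by the signal-to-noise approach
#'
#' From replicate peak heights of a sample near the quantification limit:
#' the mean signal-to-noise ratio is `mean(heights) / N`, and the limits
#' follow from the 3:1 and 10:1 conventions assuming local
#' proportionality of response and concentration:
#' `LOD = 3 c / (S/N)`, `LOQ = 10 c / (S/N)` (so `LOQ / LOD = 10/3`).
#'
#' @param heights Replicate peak heights (AU), >= 2 values.
#' @param conc Concentration of the measured sample (µmol/L).
#' @param noise A [estimate_noise()] result (or a positive number taken as
#'   `N` directly).
#' @return List with `lod`, `loq` (µmol/L), `mean_sn`, `n_replicates`.
#' @export
lod_loq_sn <- function(heights, conc, noise) {
  if (length(heights) < 2L) stop("need at least two replicate heights", call. = FALSE)
  N <- if (inherits(noise, "noise_estimate")) noise$N else noise
  if (!is.numeric(N) || N <= 0) stop("baseline noise must be positive", call. = FALSE)
  sn <- mean(heights) / N
  list(lod = 3 * conc / sn, loq = 10 * conc / sn,
       mean_sn = sn, n_replicates = length(heights))
}

#' LOD and LOQ by the calibration-slope approach
#'
#' `LOD = 3.3 * SD_signal / slope` and `LOQ = 10 * SD_signal / slope`,
#' where `SD_signal` is the standard deviation of replicate peak heights
#' close to the estimated LOQ and the slope comes from a height-based
#' calibration restricted to its linear range. When per-day values are
#' supplied (vectors of equal length), limits are computed for the
#' individual days and then averaged.
#'
#' @param sd_signal Signal SD (AU), one value or one per day.
#' @param slope Calibration slope (AU per µmol/L), same length.
#' @return List with `lod`, `loq` (averaged over days) and `per_day`
#'   (data frame of the per-day values).
#' @export
lod_loq_slope <- function(sd_signal, slope) {
  if (length(sd_signal) != length(slope)) {
    stop("`sd_signal` and `slope` must have the same length", call. = FALSE)
  }
  if (any(slope <= 0)) stop("slope must be positive", call. = FALSE)
  if (any(sd_signal < 0)) stop("`sd_signal` must be non-negative", call. = FALSE)
  lod_day <- 3.3 * sd_signal / slope
  loq_day <- 10 * sd_signal / slope
  list(lod = mean(lod_day), loq = mean(loq_day),
       per_day = data.frame(sd_signal = sd_signal, slope = slope,
                            lod = lod_day, loq = loq_day))
}
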