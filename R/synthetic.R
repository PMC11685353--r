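#' Configuration for a synthetic iCIEF trace
#'
#' Describes a whole-column-imaged electropherogram to be generated by
#' [simulate_trace()]: Gaussian analyte zones focused on a piecewise-linear
#' pH gradient, iid Gaussian detector noise, and optional localized baseline
#' irregularities (broad Gaussian bumps) of the kind carrier-ampholyte
#' mixtures produce in the acidic part of the cartridge.
#'
#' @param n_pixels Number of detector pixels (default 2048, the full
#'   cartridge separation length).
#' @param anchor_markers List of `c(pixel, pI)` pairs for the pI markers that
#'   anchor the pixel-to-pI mapping; pixels and pI values must be strictly
#'   increasing.
#' @param peaks List of `c(apex_pixel, height, sigma_pixels)` triples, one
#'   per focused zone; heights in absorbance units (AU).
#' @param noise_sd Standard deviation of the per-pixel Gaussian baseline
#'   noise (AU); 0 gives a noiseless trace.
#' @param baseline_bumps List of `c(center_pixel, amplitude, width)` triples
#'   for localized baseline irregularities.
#' @param seed Integer seed; identical configs with identical seeds generate
#'   identical traces.
#' @return An object of class `trace_sim_config`.
#' @seealso [simulate_trace()]
#' @export
trace_sim_config <- function(n_pixels = 2048,
                             anchor_markers = list(c(500, 5.12), c(1900, 7.05)),
                             peaks = list(),
                             noise_sd = 0,
                             baseline_bumps = list(),
                             seed = 1L) {
  stop_if_not_scalar_number(n_pixels, "n_pixels")
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (n_pixels < 2) stop("`n_pixels` must be at least 2", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  anchors <- do.call(rbind, lapply(anchor_markers, function(a) {
    if (length(a) != 2L) stop("each anchor marker must be c(pixel, pI)", call. = FALSE)
    a
  }))
  if (!is.null(anchors)) {
    if (anyDuplicated(anchors[, 1L])) {
      stop("anchor pixels must not overlap", call. = FALSE)
    }
    if (is.unsorted(anchors[, 1L], strictly = TRUE) ||
        is.unsorted(anchors[, 2L], strictly = TRUE)) {
      stop("anchor pixels and pI values must be strictly increasing", call. = FALSE)
    }
  }
  for (p in peaks) {
    if (length(p) != 3L) stop("each peak must be c(apex_pixel, height, sigma_pixels)", call. = FALSE)
    if (p[3L] <= 0) stop("peak `sigma_pixels` must be positive", call. = FALSE)
  }
  structure(
    list(n_pixels = as.integer(n_pixels), anchor_markers = anchor_markers,
         peaks = peaks, noise_sd = noise_sd, baseline_bumps = baseline_bumps,
         seed = as.integer(seed)),
    class = "trace_sim_config"
  )
}

#' Simulate an iCIEF electropherogram
#'
#' Generates a pixel-indexed absorbance trace as the sum of Gaussian peaks,
#' Gaussian baseline bumps, and iid Gaussian noise, per the supplied
#' [trace_sim_config()]. Deterministic for a fixed config and seed.
#'
#' @param config A `trace_sim_config` object.
#' @param metadata Optional named list (run id, day, replicate) attached to
#'   the returned trace.
#' @return An [electropherogram] object.
#' @examples
#' cfg <- trace_sim_config(peaks = list(c(1000, 0.1, 10)), noise_sd = 0)
#' tr <- simulate_trace(cfg)
#' max(tr$absorbance) # 0.1 at pixel 1000
#' @export
simulate_trace <- function(config, metadata = list()) {
  stopifnot(inherits(config, "trace_sim_config"))
  px <- seq_len(config$n_pixels)
  y <- numeric(config$n_pixels)
  for (p in config$peaks) {
    y <- y + p[2L] * exp(-(px - p[1L])^2 / (2 * p[3L]^2))
  }
  for (b in config$baseline_bumps) {
    y <- y + b[2L] * exp(-(px - b[1L])^2 / (2 * b[3L]^2))
  }
  if (config$noise_sd > 0) {
    y <- y + with_seed(config$seed, stats::rnorm(config$n_pixels, 0, config$noise_sd))
  }
  metadata$anchor_markers <- config$anchor_markers
  electropherogram(px, y, metadata = metadata)
}

#' Configuration for a synthetic calibration series
#'
#' Describes a calibration experiment generated by [simulate_calibration()]:
#' evenly spaced concentration levels injected in order of increasing
#' concentration over several cycles (so time-dependent drifts are not
#' mistaken for non-linearity), with a known straight-line truth and
#' injectable pathologies — curvature, heteroscedastic noise, AR(1) drift
#' along the injection sequence, and a single gross outlier.
#'
#' @param levels Numeric vector of calibration concentrations (µmol/L). At
#'   least five distinct levels are required to emulate a standard run.
#' @param cycles Number of injection cycles (default 3); each cycle runs the
#'   levels in increasing order, giving `cycles` replicates per level.
#' @param slope,intercept True first-order coefficients (response units per
#'   µmol/L, response units). Response is a peak area by convention.
#' @param noise_sd Response noise SD at the highest level.
#' @param hetero_exponent With exponent `g`, the noise SD at concentration
#'   `c` is `noise_sd * (c / max(c))^g`; 0 (default) is homoscedastic.
#' @param curvature True second-order coefficient (0 for a straight line).
#' @param ar1_phi AR(1) coefficient in (-1, 1) applied to the error sequence
#'   in injection order; 0 gives independent errors.
#' @param outlier Optional `c(level_index, cycle_index, offset)`: adds
#'   `offset` response units to that single observation.
#' @param seed Integer seed.
#' @return An object of class `calib_sim_config`.
#' @export
calib_sim_config <- function(levels = seq(5, 30, by = 5),
                             cycles = 3L,
                             slope = 1,
                             intercept = 0.5,
                             noise_sd = 0.4,
                             hetero_exponent = 0,
                             curvature = 0,
                             ar1_phi = 0,
                             outlier = NULL,
                             seed = 1L) {
  if (length(levels) < 2L || anyDuplicated(levels) || is.unsorted(levels, strictly = TRUE)) {
    stop("`levels` must be strictly increasing distinct concentrations", call. = FALSE)
  }
  if (cycles < 1L) stop("`cycles` must be at least 1", call. = FALSE)
  if (abs(ar1_phi) > 1) stop("`ar1_phi` must lie in [-1, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (!is.null(outlier)) {
    if (length(outlier) != 3L) {
      stop("`outlier` must be c(level_index, cycle_index, offset)", call. = FALSE)
    }
    if (outlier[1L] < 1 || outlier[1L] > length(levels) ||
        outlier[2L] < 1 || outlier[2L] > cycles) {
      stop("`outlier` indices out of range", call. = FALSE)
    }
  }
  structure(
    list(levels = as.numeric(levels), cycles = as.integer(cycles),
         slope = slope, intercept = intercept, noise_sd = noise_sd,
         hetero_exponent = hetero_exponent, curvature = curvature,
         ar1_phi = ar1_phi, outlier = outlier, seed = as.integer(seed)),
    class = "calib_sim_config"
  )
}

#' Simulate a calibration series
#'
#' Generates per-injection responses
#' `intercept + slope * c + curvature * c^2 + error (+ outlier offset)`,
#' where the error sequence follows the injection order: independent
#' heteroscedastic Gaussian innovations passed through an AR(1) recursion
#' with coefficient `ar1_phi` (stationary start). Injection order enumerates
#' the levels in increasing concentration within each cycle.
#'
#' @param config A `calib_sim_config` object.
#' @param analyte,day Labels carried into the returned series.
#' @return A [calibration_series] object.
#' @export
simulate_calibration <- function(config, analyte = "analyte", day = "day 1") {
  stopifnot(inherits(config, "calib_sim_config"))
  L <- length(config$levels)
  n <- L * config$cycles
  level_index <- rep(seq_len(L), times = config$cycles)
  cycle <- rep(seq_len(config$cycles), each = L)
  conc <- config$levels[level_index]
  cmax <- max(config$levels)
  sd_i <- if (config$noise_sd > 0) {
    config$noise_sd * (conc / cmax)^config$hetero_exponent
  } else {
    rep(0, n)
  }
  err <- with_seed(config$seed, {
    innov <- stats::rnorm(n, 0, sd_i)
    if (config$ar1_phi != 0) {
      e <- numeric(n)
      # stationary scaling of the first error when |phi| < 1
      e[1L] <- if (abs(config$ar1_phi) < 1) {
        innov[1L] / sqrt(1 - config$ar1_phi^2)
      } else {
        innov[1L]
      }
      for (t in seq_len(n)[-1L]) e[t] <- config$ar1_phi * e[t - 1L] + innov[t]
      e
    } else {
      innov
    }
  })
  resp <- config$intercept + config$slope * conc + config$curvature * conc^2 + err
  if (!is.null(config$outlier)) {
    hit <- which(level_index == config$outlier[1L] & cycle == config$outlier[2L])
    resp[hit] <- resp[hit] + config$outlier[3L]
  }
  calibration_series(
    concentration = conc, response = resp, injection_order = seq_len(n),
    cycle = cycle, level_index = level_index, analyte = analyte, day = day
  )
}
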