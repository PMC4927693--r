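#' Exponentially modified Gaussian (EMG) peak profile
#'
#' Evaluates the EMG closed form: a Gaussian of standard deviation `sigma`
#' and apex height `amplitude` centred at `tr_center`, convolved with a
#' normalised exponential decay of time constant `tau`. The EMG is the
#' standard model for tailing chromatographic peaks: `tau = 0` recovers the
#' pure Gaussian, and increasing `tau/sigma` increases the trailing/leading
#' asymmetry (b/a) monotonically. The profile integrates to
#' `amplitude * sigma * sqrt(2*pi)` for any `tau` (convolution with a unit
#' kernel preserves area).
#'
#' @param t Numeric vector of times (seconds).
#' @param tr_center Centre of the underlying Gaussian (seconds). Note the
#'   observed apex elutes later than `tr_center` when `tau > 0`.
#' @param sigma Gaussian standard deviation (seconds), > 0.
#' @param tau Exponential tail time constant (seconds), >= 0.
#' @param amplitude Apex height of the underlying Gaussian (intensity units).
#' @return Numeric vector of intensities, same length as `t`.
#' @examples
#' tt <- seq(0, 200, by = 0.05)
#' y <- emg_profile(tt, tr_center = 100, sigma = 2, tau = 4, amplitude = 1000)
#' @export
emg_profile <- function(t, tr_center, sigma, tau, amplitude) {
  stopifnot(is.numeric(t), length(t) >= 1)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0)
    stop("tau must be a single non-negative number")
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    stop("amplitude must be a single non-negative number")

  # tau below ~1e-4 sigma is numerically indistinguishable from a Gaussian
  if (tau < 1e-4 * sigma) {
    return(amplitude * exp(-((t - tr_center)^2) / (2 * sigma^2)))
  }
  z <- (sigma / tau - (t - tr_center) / sigma) / sqrt(2)
  pref <- amplitude * (sigma / tau) * sqrt(pi / 2)
  y <- numeric(length(t))
  pos <- z >= 0
  # stable branch: exp(-x^2/2s^2) * erfcx(z) avoids overflow of exp(s^2/2tau^2)
  if (any(pos)) {
    y[pos] <- pref * exp(-((t[pos] - tr_center)^2) / (2 * sigma^2)) *
      erfcx_safe(z[pos])
  }
  if (any(!pos)) {
    # deep tail: exponent is provably negative here, erfc(z) in (1, 2)
    y[!pos] <- pref * exp(sigma^2 / (2 * tau^2) - (t[!pos] - tr_center) / tau) *
      pracma::erfc(z[!pos])
  }
  y
}

# Scaled complementary error function, safe for large positive arguments
# (pracma::erfcx returns NaN above ~z = 26); 4-term asymptotic expansion,
# relative error < 1e-8 for z >= 20.
erfcx_safe <- function(z) {
  out <- numeric(length(z))
  small <- z < 20
  if (any(small)) out[small] <- pracma::erfcx(z[small])
  if (any(!small)) {
    x <- z[!small]
    x2 <- 1 / x^2
    out[!small] <- (1 - 0.5 * x2 + 0.75 * x2^2 - 1.875 * x2^3) /
      (x * sqrt(pi))
  }
  out
}

#' Specify one EMG peak
#'
#' @param analyte_id Analyte label.
#' @param tr_center Gaussian centre (seconds).
#' @param sigma Gaussian width (seconds), > 0.
#' @param tau Exponential tail constant (seconds), >= 0.
#' @param amplitude Gaussian apex height (intensity units), >= 0.
#' @return An object of class `emg_peak_spec`.
#' @export
emg_peak_spec <- function(analyte_id, tr_center, sigma, tau = 0, amplitude = 1000) {
  if (!is.character(analyte_id) || length(analyte_id) != 1)
    stop("analyte_id must be a single string")
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(
    list(analyte_id = analyte_id, tr_center = tr_center, sigma = sigma,
         tau = tau, amplitude = amplitude),
    class = "emg_peak_spec"
  )
}

#' Baseline noise model for simulated chromatograms
#'
#' White Gaussian baseline noise plus an optional linear drift.
#'
#' @param baseline_sd Standard deviation of the additive baseline noise
#'   (intensity units), >= 0.
#' @param drift_slope Linear baseline drift (intensity units per second).
#' @param seed Integer seed; required so every simulated trace is
#'   reproducible. A noise model without a seed is rejected.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_sd = 0, drift_slope = 0, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a noise model requires an explicit integer seed")
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  structure(
    list(baseline_sd = baseline_sd, drift_slope = drift_slope,
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Evaluate one EMG peak on a uniform time grid
#'
#' @param spec An [emg_peak_spec()].
#' @param grid Strictly increasing, uniformly spaced time grid (seconds).
#' @return Intensity trace (numeric vector, >= 0 everywhere).
#' @export
make_emg_trace <- function(spec, grid) {
  stopifnot(inherits(spec, "emg_peak_spec"))
  check_uniform_grid(grid)
  emg_profile(grid, spec$tr_center, spec$sigma, spec$tau, spec$amplitude)
}

check_uniform_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2)
    stop("grid must be a numeric vector with at least 2 samples")
  d <- diff(grid)
  if (any(d <= 0)) stop("grid must be strictly increasing")
  step <- d[1]
  if (any(abs(d - step) > 1e-9 * max(abs(step), 1)))
    stop("grid must be uniformly spaced (non-uniform step detected)")
  invisible(step)
}

#' Simulate a chromatogram from EMG peaks plus baseline noise
#'
#' The trace is the sum of the EMG contributions of all peaks, plus white
#' Gaussian baseline noise and a linear drift. Simulation is fully
#' reproducible: the noise model carries its own seed and the RNG state of
#' the session is restored on exit.
#'
#' Peaks whose `tr_center +/- 6 * (sigma + tau)` support extends beyond the
#' run window are kept but flagged as truncated (with a warning), mirroring
#' peaks cut off by the end of a gradient.
#'
#' @param peaks List of [emg_peak_spec()] objects.
#' @param noise A [noise_model()].
#' @param run_length Run length (seconds).
#' @param step Sampling interval (seconds); 0.05 s by default.
#' @param channel Detection channel, `"MS"` or `"UV"`.
#' @param condition_id Condition label carried in the chromatogram header.
#' @return A [chromatogram()] object; truncated peak ids (if any) are in
#'   `attr(, "truncated")`.
#' @export
simulate_chromatogram <- function(peaks, noise, run_length, step = 0.05,
                                  channel = c("MS", "UV"),
                                  condition_id = "sim") {
  channel <- match.arg(channel)
  stopifnot(inherits(noise, "noise_model"), run_length > 0, step > 0)
  if (!is.list(peaks) || (length(peaks) > 0 &&
      !all(vapply(peaks, inherits, logical(1), "emg_peak_spec"))))
    stop("peaks must be a list of emg_peak_spec objects")

  grid <- seq(0, run_length, by = step)
  intensity <- numeric(length(grid))
  truncated <- character(0)
  for (p in peaks) {
    half <- 6 * (p$sigma + p$tau)
    if (p$tr_center - half < 0 || p$tr_center + half > run_length) {
      warning(sprintf("peak '%s' extends outside the run window; truncated",
                      p$analyte_id))
      truncated <- c(truncated, p$analyte_id)
    }
    intensity <- intensity + make_emg_trace(p, grid)
  }
  intensity <- intensity + noise$drift_slope * grid
  if (noise$baseline_sd > 0) {
    intensity <- intensity + with_seed(noise$seed, {
      stats::rnorm(length(grid), sd = noise$baseline_sd)
    })
  }
  chrom <- chromatogram(grid, intensity, channel = channel,
                        condition_id = condition_id)
  attr(chrom, "seed") <- noise$seed
  attr(chrom, "truncated") <- truncated
  chrom
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
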