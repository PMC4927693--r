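#' Gradient method description
#'
#' @param t_g Gradient length (seconds), > 0. The default 441 s corresponds
#'   to the 7.35 min gradient used throughout the screen.
#' @param t0 Column dead time (seconds), > 0; default 30 s (an unretained
#'   marker such as toluene).
#' @param program Optional data frame `(time, pct_co2)` with non-decreasing
#'   times describing the solvent program.
#' @return An object of class `gradient_method`.
#' @export
gradient_method <- function(t_g = 441, t0 = 30, program = NULL) {
  if (t_g <= 0) stop("t_g must be > 0")
  if (t0 <= 0) stop("t0 must be > 0")
  if (!is.null(program)) {
    stopifnot(is.data.frame(program), all(c("time", "pct_co2") %in% names(program)))
    if (is.unsorted(program$time)) stop("program times must be non-decreasing")
  }
  structure(list(t_g = t_g, t0 = t0, program = program),
            class = "gradient_method")
}

#' Retention factor from retention and dead time
#'
#' `k = (tr - t0) / t0`, the standard dimensionless retention factor.
#'
#' @param tr Retention time (seconds), >= `t0`.
#' @param t0 Dead time (seconds), > 0.
#' @return Retention factor(s) `k`.
#' @examples
#' retention_factor(90, 30)  # k = 2
#' @export
retention_factor <- function(tr, t0) {
  if (any(t0 <= 0)) stop("t0 must be > 0")
  if (any(tr < t0)) stop("peak elutes before dead time (tr < t0)")
  (tr - t0) / t0
}

#' Estimate baseline noise in a peak-free window
#'
#' Returns the sample standard deviation of the linearly detrended
#' intensities in the window, an estimate of the detector baseline noise
#' used by the S/N convention `snr = height / (2 * noise_sd)`.
#'
#' @param chrom A [chromatogram()].
#' @param window Length-2 numeric, `(start, end)` in seconds. Must contain
#'   at least 50 samples and no detected peak.
#' @param peak_check_height Detrended excursions above this intensity raise
#'   a window-overlaps-peak error; by default 8x a robust noise scale
#'   (sd of successive differences / sqrt(2)), which white noise exceeds
#'   with negligible probability while even modest peaks trip it.
#' @return Noise standard deviation (intensity units).
#' @export
estimate_baseline_noise <- function(chrom, window, peak_check_height = NULL) {
  stopifnot(inherits(chrom, "chromatogram"), length(window) == 2)
  sel <- chrom$time >= window[1] & chrom$time <= window[2]
  n <- sum(sel)
  if (n < 50) stop(sprintf("window too short: %d samples (need >= 50)", n))
  y <- chrom$intensity[sel]
  t <- chrom$time[sel]
  resid <- stats::resid(stats::lm(y ~ t))
  s <- stats::sd(resid)
  robust <- stats::sd(diff(y)) / sqrt(2)  # insensitive to smooth structure
  thr <- if (is.null(peak_check_height)) 8 * robust else peak_check_height
  if (s > 0 && max(abs(resid)) > thr)
    stop("window overlaps a peak: detrended excursion exceeds threshold")
  s
}

# Topographic prominence of local maxima: height above the higher of the two
# key saddles separating the maximum from taller terrain.
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

peak_prominence <- function(y, apexes) {
  vapply(apexes, function(i) {
    h <- y[i]
    # walk left until terrain exceeds h; key saddle = min along the way
    lmin <- h
    j <- i - 1L
    while (j >= 1 && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1L }
    left <- if (j >= 1) lmin else min(lmin, min(y[1:i]))
    rmin <- h
    j <- i + 1L
    while (j <= length(y) && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1L }
    right <- if (j <= length(y)) rmin else min(rmin, min(y[i:length(y)]))
    h - max(left, right)
  }, numeric(1))
}

#' Detect peak apexes in a chromatogram
#'
#' Local maxima filtered by a minimum height and a minimum topographic
#' prominence (height above the key saddle to taller terrain). Co-eluting
#' shoulders are reported separately only if both exceed the prominence
#' threshold; otherwise they merge into one apex.
#'
#' @param chrom A [chromatogram()].
#' @param min_height Minimum apex intensity, > 0.
#' @param min_prominence Minimum prominence, > 0; defaults to `min_height/2`.
#' @return Sorted numeric vector of apex times (seconds), possibly empty.
#' @export
detect_peaks <- function(chrom, min_height, min_prominence = min_height / 2) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (min_height <= 0 || min_prominence <= 0)
    stop("thresholds must be > 0")
  y <- chrom$intensity
  cand <- local_maxima(y)
  cand <- cand[y[cand] >= min_height]
  if (length(cand) == 0) return(numeric(0))
  prom <- peak_prominence(y, cand)
  keep <- cand[prom >= min_prominence]
  sort(chrom$time[keep])
}

# Walk outward from the apex to the peak boundaries: stop at the first
# sample below `frac` of apex height, or at the valley before a genuine
# rise (more than `rise_tol` above the running minimum — a neighbouring
# peak). The boundary is the running-minimum position, so noise-scale
# wiggles below `rise_tol` never terminate the walk early.
peak_bounds <- function(y, i_apex, frac = 0.005, rise_tol = 0) {
  h <- y[i_apex]
  floor_h <- frac * h
  rise_tol <- max(1e-12 * h, rise_tol)
  walk <- function(dir) {
    i <- i_apex
    i_min <- i_apex
    repeat {
      nxt <- i + dir
      if (nxt < 1 || nxt > length(y)) break
      if (y[nxt] <= floor_h) { i_min <- nxt; break }
      if (y[nxt] > y[i_min] + rise_tol) break
      i <- nxt
      if (y[i] < y[i_min]) i_min <- i
    }
    i_min
  }
  c(walk(-1L), walk(1L))
}

#' Measure per-peak descriptors at a detected apex
#'
#' Computes the descriptor set used throughout the evaluation:
#' \itemize{
#'   \item `width_s` — base width by the tangent method: tangents through
#'     the leading and trailing inflection points (fitted by least squares
#'     over the 45–75% height band of each flank),
#'     intersected with the local straight-line baseline; equals `4*sigma`
#'     for a Gaussian.
#'   \item `asym` — asymmetry b/a, trailing over leading half-width at 10%
#'     of baseline-corrected height.
#'   \item `snr` — `height / (2 * noise_sd)`.
#'   \item `area` — trapezoidal integral above the baseline between the
#'     detected peak boundaries.
#'   \item `k` — retention factor `(tr - t0)/t0` from the gradient's dead
#'     time.
#' }
#' The local baseline is the straight line joining the peak boundaries
#' (first samples below 0.5% of apex height, or the valley to an adjacent
#' peak).
#'
#' @param chrom A [chromatogram()].
#' @param apex Apex time (seconds), as returned by [detect_peaks()].
#' @param noise_sd Baseline noise sd from [estimate_baseline_noise()]; use 0
#'   for noise-free traces (S/N is then `Inf`).
#' @param gradient A [gradient_method()] supplying `t0`; pass `NULL` to skip
#'   the retention factor.
#' @param analyte_id Optional analyte label for the descriptor row.
#' @return One-row data frame with columns `analyte`, `tr_s`, `area`,
#'   `height`, `width_s`, `asym`, `snr`, `k`.
#' @export
measure_peak <- function(chrom, apex, noise_sd = 0, gradient = NULL,
                         analyte_id = "unknown") {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$time; y <- chrom$intensity
  step <- t[2] - t[1]
  # on noisy traces, measure shape on a Savitzky-Golay smoothed copy so the
  # boundary walk, tangents and 10%-height crossings see the peak envelope
  if (noise_sd > 0) y <- as.numeric(signal::sgolayfilt(y, p = 3, n = 11))
  i_apex <- which.min(abs(t - apex))
  if (noise_sd > 0) {
    # re-centre on the smoothed trace's local maximum near the raw apex
    win <- max(1, i_apex - 10):min(length(y), i_apex + 10)
    i_apex <- win[which.max(y[win])]
  }
  if (i_apex <= 2 || i_apex >= length(t) - 1)
    stop("truncated peak: apex at trace boundary")
  b <- peak_bounds(y, i_apex, rise_tol = 5 * noise_sd)
  i_l <- b[1]; i_r <- b[2]
  if (i_l <= 1 || i_r >= length(t))
    stop("truncated peak: peak extends to trace boundary")

  # straight-line baseline between the boundaries
  base_at <- function(idx) {
    y[i_l] + (y[i_r] - y[i_l]) * (t[idx] - t[i_l]) / (t[i_r] - t[i_l])
  }
  yc <- y[i_l:i_r] - base_at(i_l:i_r)
  tt <- t[i_l:i_r]
  ia <- i_apex - i_l + 1L
  height <- yc[ia]
  if (height <= 0) stop("apex below local baseline")

  # tangent-at-inflection base width: the tangent on each flank is fitted by
  # least squares over the samples between 45% and 75% of apex height (the
  # flank is nearly linear around its inflection point there), which keeps
  # the slope estimate stable when the per-sample slope is comparable to the
  # residual noise on broad, low peaks
  flank_tangent <- function(side) {
    idx <- if (side == "l") seq_len(ia - 1L) else (ia + 1L):length(yc)
    if (length(idx) == 0 || ia <= 1L || ia >= length(yc))
      stop("truncated peak: no flank samples")
    sel <- idx[yc[idx] >= 0.45 * height & yc[idx] <= 0.75 * height]
    if (length(sel) >= 3) {
      co <- stats::lm.fit(cbind(1, tt[sel]), yc[sel])$coefficients
    } else {
      # too few band samples (very narrow peak at this sampling rate):
      # fall back to the single steepest inter-sample slope on the flank
      dyf <- diff(yc)[if (side == "l") idx else idx - 1L] / step
      j <- if (side == "l") idx[which.max(dyf)] else (idx - 1L)[which.min(dyf)]
      s_ <- (yc[j + 1L] - yc[j]) / step
      co <- c((yc[j] + yc[j + 1L]) / 2 - s_ * (tt[j] + tt[j + 1L]) / 2, s_)
    }
    co
  }
  cl <- flank_tangent("l"); cr <- flank_tangent("r")
  if (cl[2] <= 0 || cr[2] >= 0) stop("cannot place tangents: degenerate flanks")
  x_left <- -cl[1] / cl[2]                  # tangent hits baseline (yc = 0)
  x_right <- -cr[1] / cr[2]
  width <- x_right - x_left
  if (width <= 0) stop("non-positive tangent base width")

  # asymmetry b/a at 10% of height
  thr <- 0.10 * height
  cross_left <- {
    j <- ia
    while (j > 1 && yc[j] > thr) j <- j - 1L
    if (yc[j] > thr) tt[1] else
      tt[j] + (thr - yc[j]) / (yc[j + 1] - yc[j]) * step
  }
  cross_right <- {
    j <- ia
    while (j < length(yc) && yc[j] > thr) j <- j + 1L
    if (yc[j] > thr) tt[length(tt)] else
      tt[j] - (thr - yc[j]) / (yc[j - 1] - yc[j]) * step
  }
  a_half <- tt[ia] - cross_left
  b_half <- cross_right - tt[ia]
  asym <- b_half / a_half

  area <- sum((yc[-1] + yc[-length(yc)]) / 2) * step
  snr <- if (noise_sd > 0) height / (2 * noise_sd) else Inf
  k <- if (!is.null(gradient)) retention_factor(tt[ia], gradient$t0) else NA_real_

  data.frame(analyte = analyte_id, tr_s = tt[ia], area = area,
             height = height, width_s = width, asym = asym, snr = snr,
             k = k, stringsAsFactors = FALSE)
}

#' Build a peak table from a chromatogram
#'
#' Convenience wrapper: detect apexes, measure each, and assign analyte
#' labels by nearest expected retention time within a tolerance.
#'
#' @param chrom A [chromatogram()].
#' @param min_height,min_prominence Detection thresholds, see
#'   [detect_peaks()].
#' @param noise_sd Baseline noise sd.
#' @param gradient A [gradient_method()].
#' @param expected_tr Optional named numeric vector of expected retention
#'   times (seconds) per analyte; unmatched peaks are labelled `"unknown"`.
#' @param match_tol Matching tolerance (seconds), default 5.
#' @return A [peak_table()].
#' @export
extract_peak_table <- function(chrom, min_height, min_prominence = min_height / 2,
                               noise_sd = 0, gradient = gradient_method(),
                               expected_tr = NULL, match_tol = 5) {
  apexes <- detect_peaks(chrom, min_height, min_prominence)
  rows <- lapply(apexes, function(a)
    measure_peak(chrom, a, noise_sd = noise_sd, gradient = gradient))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analyte = character(0), tr_s = numeric(0), area = numeric(0),
               height = numeric(0), width_s = numeric(0), asym = numeric(0),
               snr = numeric(0), k = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(expected_tr) && nrow(df) > 0) {
    used <- character(0)
    for (i in seq_len(nrow(df))) {
      d <- abs(expected_tr - df$tr_s[i])
      d[names(expected_tr) %in% used] <- Inf
      j <- which.min(d)
      if (d[j] <= match_tol) {
        df$analyte[i] <- names(expected_tr)[j]
        used <- c(used, names(expected_tr)[j])
      } else df$analyte[i] <- sprintf("unknown_%d", i)
    }
  } else if (nrow(df) > 0) {
    df$analyte <- sprintf("unknown_%d", seq_len(nrow(df)))
  }
  peak_table(df, condition_id = chrom$condition_id, gradient = gradient)
}
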