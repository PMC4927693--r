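# Peak detection and descriptor extraction

gaussian_chrom <- function(centers, sigmas, amps, run_length = 600,
                           noise_sd = 0, seed = 1, step = 0.05) {
  peaks <- mapply(function(c, s, a, i)
    emg_peak_spec(sprintf("p%d", i), c, s, 0, a),
    centers, sigmas, amps, seq_along(centers), SIMPLIFY = FALSE)
  suppressWarnings(simulate_chromatogram(
    peaks, noise_model(baseline_sd = noise_sd, seed = seed),
    run_length = run_length, step = step))
}

test_that("baseline noise estimate recovers the generating sd", {
  ch <- gaussian_chrom(500, 2, 1000, run_length = 600, noise_sd = 5, seed = 42)
  est <- estimate_baseline_noise(ch, c(0, 50))  # 1000 samples, no peak
  expect_equal(est, 5, tolerance = 0.10 * 5)
})

test_that("noise estimation edge cases behave as specified", {
  ch <- chromatogram(seq(0, 100, 0.5), rep(0, 201))
  expect_equal(estimate_baseline_noise(ch, c(0, 100)), 0)
  expect_error(estimate_baseline_noise(ch, c(0, 4)), "too short")
  chp <- gaussian_chrom(50, 2, 1000, run_length = 100, noise_sd = 2, seed = 7)
  expect_error(estimate_baseline_noise(chp, c(30, 70)), "overlaps a peak")
})

test_that("well-separated peaks are each detected within one grid step", {
  centers <- c(80, 160, 240, 320, 400)
  ch <- gaussian_chrom(centers, rep(2, 5), seq(400, 1200, length.out = 5))
  apexes <- detect_peaks(ch, min_height = 100)
  expect_length(apexes, 5)
  expect_true(all(abs(apexes - centers) <= 0.051))
})

test_that("flat traces yield no peaks and thresholds are validated", {
  ch <- chromatogram(seq(0, 100, 0.05), rep(0, 2001))
  expect_length(detect_peaks(ch, min_height = 10), 0)
  expect_error(detect_peaks(ch, min_height = 0), "> 0")
})

test_that("shoulders merge below the prominence threshold and split above", {
  # 0.5 sigma apart: sum is unimodal, always one apex
  ch1 <- gaussian_chrom(c(100, 101), c(2, 2), c(1000, 1000), run_length = 200)
  expect_length(detect_peaks(ch1, min_height = 100, min_prominence = 1), 1)
  # 3 sigma apart: bimodal; split with low prominence, merged with high
  ch2 <- gaussian_chrom(c(100, 106), c(2, 2), c(1000, 800), run_length = 200)
  expect_length(detect_peaks(ch2, min_height = 100, min_prominence = 10), 2)
  expect_length(detect_peaks(ch2, min_height = 100, min_prominence = 700), 1)
})

test_that("tangent base width recovers 4 sigma across a sigma grid", {
  for (s in c(1, 2, 4, 8)) {
    ch <- gaussian_chrom(300, s, 1000)
    d <- measure_peak(ch, 300, noise_sd = 0)
    expect_gt(d$width_s / s, 3.8)
    expect_lt(d$width_s / s, 4.2)
  }
})

test_that("symmetric Gaussians measure asymmetry 1 and exact S/N", {
  ch <- gaussian_chrom(300, 3, 600)
  d <- measure_peak(ch, 300, noise_sd = 10)
  expect_equal(d$asym, 1.0, tolerance = 0.02)
  # direct convention check: snr = height / (2 * noise_sd)
  expect_equal(d$snr, d$height / 20)
  expect_equal(d$snr, 600 / 20, tolerance = 0.02)
})

test_that("asymmetry b/a increases monotonically with tau/sigma", {
  taus <- c(0.5, 1, 2, 4, 8)
  asyms <- vapply(taus, function(tau) {
    ch <- suppressWarnings(simulate_chromatogram(
      list(emg_peak_spec("p", 200, 2, tau, 1000)),
      noise_model(seed = 1), run_length = 600))
    measure_peak(ch, ch$time[which.max(ch$intensity)], noise_sd = 0)$asym
  }, numeric(1))
  expect_true(all(diff(asyms) > 0))
  expect_true(all(asyms > 1))
})

test_that("measured area matches trace quadrature for clean peaks", {
  for (s in c(2, 5)) {
    ch <- gaussian_chrom(300, s, 1000)
    d <- measure_peak(ch, 300, noise_sd = 0)
    expect_equal(d$area, 1000 * s * sqrt(2 * pi), tolerance = 0.02)
  }
})

test_that("descriptor extraction recovers generator ground truth", {
  centers <- c(100, 200, 300)
  ch <- gaussian_chrom(centers, c(2, 3, 4), c(800, 1000, 600))
  tab <- extract_peak_table(ch, min_height = 100, noise_sd = 0,
                            gradient = gradient_method(t0 = 30),
                            expected_tr = c(first = 100, second = 200,
                                            third = 300))
  expect_equal(nrow(tab), 3)
  expect_true(all(abs(tab$tr_s - centers) <= 0.051))
  expect_equal(tab$analyte, c("first", "second", "third"))
  expect_equal(tab$k, (centers - 30) / 30, tolerance = 0.01)
})

test_that("descriptors stay accurate on noisy traces (broad, low peaks included)", {
  # broad low-amplitude peaks have near-zero slope at the apex, so the
  # boundary search must not terminate on noise-scale wiggles
  ch <- gaussian_chrom(230, 6.5, 400, run_length = 441, noise_sd = 5,
                       seed = 20260)
  apex <- detect_peaks(ch, min_height = 100)
  expect_length(apex, 1)
  d <- measure_peak(ch, apex, noise_sd = 5)
  expect_equal(d$width_s, 4 * 6.5, tolerance = 0.10)
  expect_equal(d$height, 400, tolerance = 0.05)
  expect_equal(d$area, 400 * 6.5 * sqrt(2 * pi), tolerance = 0.05)
  expect_equal(d$asym, 1, tolerance = 0.10)
})

test_that("apexes at the trace boundary are rejected as truncated", {
  ch <- chromatogram(seq(0, 10, 0.05), c(seq(0, 100, length.out = 100),
                                         seq(100, 0, length.out = 101)))
  expect_error(measure_peak(ch, 0), "truncated")
})

test_that("retention factor follows its definition and guards", {
  expect_equal(retention_factor(60, 30), 1)
  expect_equal(retention_factor(30, 30), 0)
  expect_equal(retention_factor(90, 30), 2)
  expect_error(retention_factor(20, 30), "before dead time")
  expect_error(retention_factor(20, 0), "t0")
})

test_that("gradient method validates its program", {
  expect_error(gradient_method(t_g = -1), "t_g")
  expect_error(gradient_method(t0 = 0), "t0")
  expect_error(gradient_method(program = data.frame(time = c(2, 1),
                                                    pct_co2 = c(98, 50))),
               "non-decreasing")
})
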