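# EMG peak simulation and the synthetic screen generator

test_that("EMG reduces to a Gaussian as tau -> 0", {
  grid <- seq(0, 200, by = 0.05)
  spec <- emg_peak_spec("g", tr_center = 100, sigma = 2, tau = 1e-6,
                        amplitude = 1000)
  y <- make_emg_trace(spec, grid)
  expect_equal(max(y), 1000, tolerance = 1e-6)
  expect_equal(grid[which.max(y)], 100, tolerance = 0.05)
  # FWHM within 1% of 2.355 sigma
  above <- grid[y >= 500]
  expect_equal(max(above) - min(above), 2.3548 * 2, tolerance = 0.01)
  expect_true(all(y >= 0))
})

test_that("zero-amplitude peak gives an all-zero trace", {
  grid <- seq(0, 200, by = 0.05)
  y <- make_emg_trace(emg_peak_spec("z", 100, 2, 1, 0), grid)
  expect_true(all(y == 0))
})

test_that("tailing EMG matches an independent Gaussian*exponential convolution", {
  step <- 0.05
  grid <- seq(0, 300, by = step)
  y <- emg_profile(grid, 100, 2, 4, 1000)
  # oracle: discrete convolution of the Gaussian with a normalised
  # exponential kernel (independent of the closed form)
  gau <- 1000 * exp(-(grid - 100)^2 / (2 * 2^2))
  ker <- exp(-seq(0, 80, by = step) / 4)
  ker <- ker / sum(ker)
  conv <- stats::filter(c(gau, numeric(length(ker))), ker, sides = 1)
  conv <- as.numeric(conv[seq_along(grid)])
  ok <- grid > 85 & !is.na(conv)  # skip the convolution warm-up region
  expect_equal(grid[which.max(y)], grid[which.max(replace(conv, is.na(conv), 0))],
               tolerance = 0.051)
  # the discrete-convolution oracle carries rectangle-rule error ~ O(step)
  expect_lt(max(abs(y - conv)[ok]), 1e-2 * max(y))
  # apex later and lower than the parent Gaussian
  expect_gt(grid[which.max(y)], 100)
  expect_lt(max(y), 1000)
})

test_that("noise-free simulated peak conserves area to amplitude*sigma*sqrt(2pi)", {
  nm <- noise_model(baseline_sd = 0, seed = 1)
  ch <- simulate_chromatogram(list(emg_peak_spec("p", 100, 2, 0, 1000)),
                              nm, run_length = 200)
  area <- sum((ch$intensity[-1] + ch$intensity[-length(ch$intensity)]) / 2) * 0.05
  expect_equal(area, 1000 * 2 * sqrt(2 * pi), tolerance = 0.001)
})

test_that("baseline noise has the requested sd and traces are seed-reproducible", {
  nm <- noise_model(baseline_sd = 5, seed = 77)
  ch1 <- simulate_chromatogram(list(), nm, run_length = 500, step = 0.05)
  expect_gt(length(ch1$time), 10000 - 1)
  expect_equal(sd(ch1$intensity), 5, tolerance = 0.10 * 5)
  ch2 <- simulate_chromatogram(list(), nm, run_length = 500, step = 0.05)
  expect_identical(ch1$intensity, ch2$intensity)
})

test_that("peaks outside the run window are flagged truncated", {
  nm <- noise_model(seed = 1)
  expect_warning(
    ch <- simulate_chromatogram(list(emg_peak_spec("edge", 195, 3, 2, 100)),
                                nm, run_length = 200),
    "truncated")
  expect_identical(attr(ch, "truncated"), "edge")
})

test_that("non-uniform grids are rejected", {
  expect_error(make_emg_trace(emg_peak_spec("p", 5, 1, 0, 1),
                              c(0, 1, 2, 3.5, 4)), "uniform")
  expect_error(make_emg_trace(emg_peak_spec("p", 5, 1, 0, 1),
                              c(0, 1, 1, 2)), "increasing")
})

test_that("peak spec and noise model invariants are enforced", {
  expect_error(emg_peak_spec("p", 100, sigma = 0, tau = 1), "sigma")
  expect_error(emg_peak_spec("p", 100, sigma = 1, tau = -1), "tau")
  expect_error(emg_peak_spec("p", 100, 1, 0, amplitude = -5), "amplitude")
  expect_error(noise_model(baseline_sd = 5), "seed")
  expect_error(noise_model(baseline_sd = -1, seed = 1), "baseline_sd")
})

test_that("the method-development design enumerates 264 unique conditions", {
  d <- sfc_method_development_design()
  expect_equal(nrow(d), 264)
  expect_equal(anyDuplicated(d$condition_id), 0)
  # alkylamine conditions are UV-only; Torus-only at 55 degC
  alk <- d$additive %in% ALKYLAMINE_ADDITIVES
  expect_true(all(d$detection[alk] == "UV"))
  expect_true(all(d$column[d$temperature == 55] %in% TORUS_COLUMNS))
})

test_that("screen generation is deterministic in its seed", {
  des <- small_design(additives = c("water", "formic acid"))
  pan <- default_test_panel()
  d1 <- generate_screen(des, pan, seed = 11)
  d2 <- generate_screen(des, pan, seed = 11)
  expect_identical(d1$tables, d2$tables)
  expect_identical(d1$is_replicates, d2$is_replicates)
  d3 <- generate_screen(des, pan, seed = 12)
  expect_false(identical(d1$tables, d3$tables))
  expect_error(generate_screen(des, pan), "seed")
})

test_that("a compound with elution probability 0 never appears", {
  des <- small_design(additives = c("water", "ammonium formate"),
                      columns = c("Diol", "BEH"))
  eff <- effect_model(elution_overrides = data.frame(
    analyte = "adenine", prob = 0, stringsAsFactors = FALSE))
  ds <- generate_screen(des, default_test_panel(), eff, seed = 5)
  found <- unlist(lapply(ds$tables, function(t) t$analyte))
  expect_false("adenine" %in% found)
})

test_that("elution frequency is calibrated to the Bernoulli probability", {
  # 50 conditions x 20 compounds = 1000 elution draws at p = 0.75
  des <- screen_design(list(design_block(
    setdiff(SFC_COLUMNS, c("BEH Phenyl", "HSS Cyano")),
    c("water", "ammonium formate", "formic acid", "acetic acid",
      "ammonium acetate"),
    40)))
  stopifnot(nrow(des) == 50)
  eff <- effect_model(elution_prob = 0.75)
  ds <- generate_screen(des, make_panel(20), eff, seed = 314)
  frac <- sum(vapply(ds$tables, nrow, integer(1))) / (50 * 20)
  expect_gte(frac, 0.72)
  expect_lte(frac, 0.78)
})

test_that("UV-only conditions observe only UV-active analytes", {
  des <- small_design(additives = "isopropylamine", columns = "BEH 2-EP")
  ds <- generate_screen(des, default_test_panel(), seed = 3)
  pan <- default_test_panel()
  uv_ids <- vapply(pan, `[[`, character(1), "analyte_id")[
    vapply(pan, `[[`, logical(1), "uv_active")]
  expect_true(all(ds$tables[[1]]$analyte %in% uv_ids))
  expect_length(uv_ids, 7)
})

test_that("internal-standard replicates are generated per condition", {
  des <- small_design()
  ds <- generate_screen(des, default_test_panel(), seed = 9)
  reps <- ds$is_replicates
  expect_equal(nrow(reps), 4)
  expect_true(all(reps$area > 0))
  expect_error(generate_screen(des, default_test_panel(), seed = 9,
                               n_is_replicates = 2), ">= 4")
})
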