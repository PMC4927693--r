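# Condition aggregation, repeatability, ranking, end-to-end pipeline

test_that("Tukey five-number summary uses interpolated quartiles and fenced whiskers", {
  s <- tukey_five_number(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, 25.75)
  expect_equal(s$q3, 75.25)
  expect_equal(s$iqr, 49.5)
  # constant input collapses all fields
  sc <- tukey_five_number(rep(7, 5))
  expect_equal(sc$q1, 7); expect_equal(sc$q3, 7); expect_equal(sc$iqr, 0)
  expect_equal(sc$whisker_low, 7); expect_equal(sc$whisker_high, 7)
  # outlier beyond 1.5 IQR excluded from the whisker
  so <- tukey_five_number(c(1, 2, 3, 4, 100))
  expect_equal(so$whisker_high, 4)
  expect_equal(so$whisker_low, 1)
  expect_error(tukey_five_number(numeric(0)), "no values")
})

test_that("Tukey quartiles agree with a brute-force interpolation oracle", {
  # oracle: sort, then linearly interpolate position 1 + p (n - 1)
  brute_q <- function(x, p) {
    x <- sort(x)
    h <- 1 + p * (length(x) - 1)
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  withr::with_seed(60, {
    for (i in 1:25) {
      x <- runif(sample(3:40, 1), 0, 100)
      s <- tukey_five_number(x)
      expect_equal(s$q1, brute_q(x, 0.25))
      expect_equal(s$median, brute_q(x, 0.5))
      expect_equal(s$q3, brute_q(x, 0.75))
    }
  })
})

test_that("factor aggregation recovers a planted width effect", {
  withr::with_seed(14, {
    records <- rbind(
      data.frame(additive = "A", column = "x", temperature = 40,
                 width_s = rlnorm(30, log(10), 0.1)),
      data.frame(additive = "B", column = "x", temperature = 40,
                 width_s = rlnorm(30, log(20), 0.1)))
  })
  agg <- aggregate_by_factor(records, "additive", "width_s")
  medA <- agg$median[agg$level == "A"]
  medB <- agg$median[agg$level == "B"]
  expect_lt(medA, medB)
  expect_equal(medB / medA, 2, tolerance = 0.10)
  expect_equal(agg$n, c(30, 30))
})

test_that("aggregation of a single condition equals its own statistics", {
  rec <- data.frame(additive = "A", column = "x", temperature = 40,
                    width_s = c(10, 12, 14))
  agg <- aggregate_by_factor(rec, "additive", "width_s")
  expect_equal(agg$median, 12)
  expect_equal(agg$n, 3)
})

test_that("restriction and exclusion filter bookkeeping is correct", {
  rec <- expand.grid(additive = c("water", "ammonium formate", "formic acid"),
                     column = c("Diol", "2-PIC", "DEA", "1-AA", "BEH"),
                     temperature = c(35, 55), stringsAsFactors = FALSE)
  rec$width_s <- seq_len(nrow(rec))
  torus <- aggregate_by_factor(
    rec, "column", "width_s",
    restrict = function(d) d$column %in% TORUS_COLUMNS)
  expect_setequal(torus$level, TORUS_COLUMNS)
  expect_true(all(torus$n == 6))
  # excluding one level leaves every other level's statistics unchanged
  full <- aggregate_by_factor(rec, "column", "width_s")
  excl <- aggregate_by_factor(rec, "column", "width_s",
                              exclude_levels = "BEH")
  for (l in setdiff(full$level, "BEH"))
    expect_equal(excl[excl$level == l, -1], full[full$level == l, -1])
  expect_false("BEH" %in% excl$level)
  expect_error(aggregate_by_factor(rec, "column", "nope"), "metric")
})

test_that("repeatability RSDs follow their definition", {
  r <- repeatability(data.frame(tr_s = c(60, 60, 60), area = c(90, 100, 110)))
  expect_equal(r$rsd_area, 10)
  expect_equal(r$rsd_tr, 0)
  expect_equal(r$n_replicates, 3)
  expect_error(repeatability(data.frame(tr_s = 60, area = 100)), ">= 2")
  expect_error(repeatability(data.frame(tr_s = c(1, -1), area = c(1, 1))),
               "zero mean")
  # scale invariance of the area RSD
  x <- data.frame(tr_s = c(59, 60, 61), area = c(80, 100, 120))
  x2 <- x; x2$area <- x2$area * 7
  expect_equal(repeatability(x)$rsd_area, repeatability(x2)$rsd_area)
})

test_that("planted internal-standard area CV is recovered from replicates", {
  eff <- effect_model(is_area_cv_additive = c("water" = 16),
                      is_area_cv_column = c("Diol" = 1))
  ds <- generate_screen(small_design(), make_panel(5), eff, seed = 88,
                        n_is_replicates = 30)
  r <- repeatability(ds$is_replicates)
  expect_gte(r$rsd_area, 12)
  expect_lte(r$rsd_area, 20)
})

test_that("condition ranking is lexicographic, deterministic and complete", {
  s <- data.frame(condition_id = c("c", "a", "b"),
                  median_width = c(10, 10, 8),
                  sum_rs = c(5, 7, 2), nrp = c(0.5, 0.5, 0.9),
                  stringsAsFactors = FALSE)
  r <- rank_conditions(s)
  expect_equal(r$condition_id, c("b", "a", "c"))  # width first, then sum_rs
  expect_equal(r$rank, 1:3)
  # single condition ranks itself
  expect_equal(rank_conditions(s[1, ])$condition_id, "c")
  # permutation of input, stable under shuffling
  withr::with_seed(4, {
    shuf <- s[sample(1:3), ]
  })
  expect_equal(rank_conditions(shuf)$condition_id, r$condition_id)
  # ties fall back to condition_id
  tie <- data.frame(condition_id = c("z", "y"), median_width = 1,
                    sum_rs = 1, nrp = 1, stringsAsFactors = FALSE)
  expect_equal(rank_conditions(tie)$condition_id, c("y", "z"))
  expect_error(rank_conditions(s, objective = c(bogus = "min")), "columns")
})

test_that("a dominating condition block ranks first", {
  des <- screen_design(list(design_block(c("Diol", "BEH"),
                                         c("water", "formic acid"), 40)))
  eff <- effect_model(
    additive_width = c("water" = 1, "formic acid" = 1),
    column_width = c("Diol" = 0.4, "BEH" = 1.5),
    additive_shift = c("water" = 0), column_shift = c("Diol" = 0),
    additive_asym = c("water" = 1), column_asym = c("Diol" = 1),
    elution_prob = 1)
  ds <- generate_screen(des, make_panel(15), eff, seed = 21)
  rep <- run_screen_evaluation(ds, subset = NULL)
  top_cols <- rep$ranking$column[1:2]
  expect_true(all(top_cols == "Diol"))
})

test_that("the pipeline report is reproducible and covers every condition", {
  des <- screen_design(list(design_block(
    c("Diol", "2-PIC"), c("water", "ammonium formate"), c(35, 40))))
  ds <- generate_screen(des, default_test_panel(), seed = 7)
  r1 <- run_screen_evaluation(ds)
  r2 <- run_screen_evaluation(ds)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$ranking, r2$ranking)
  expect_equal(nrow(r1$summaries), nrow(des))
  expect_equal(nrow(r1$repeatability), nrow(des))
  expect_setequal(r1$summaries$condition_id, des$condition_id)
  # digest renders
  f <- withr::local_tempfile(fileext = ".txt")
  write_report_digest(r1, f)
  expect_gt(length(readLines(f)), 10)
})

test_that("identical effects everywhere tie and fall back to condition_id order", {
  des <- screen_design(list(design_block(c("Diol", "DEA"), "water", 40)))
  eff <- effect_model(additive_width = c(water = 1), column_width = c(Diol = 1),
                      additive_shift = c(water = 0), column_shift = c(Diol = 0),
                      additive_asym = c(water = 1), column_asym = c(Diol = 1),
                      elution_prob = 1, tr_jitter_rsd = 0,
                      width_noise_sdlog = 0)
  ds <- generate_screen(des, make_panel(8), eff, seed = 30)
  # with zero retention/width noise the ranking metrics are identical
  # across conditions -> ranking must resolve by id
  expect_identical(ds$tables[[1]]$tr_s, ds$tables[[2]]$tr_s)
  expect_identical(ds$tables[[1]]$width_s, ds$tables[[2]]$width_s)
  r <- run_screen_evaluation(ds, subset = NULL)
  expect_equal(r$ranking$condition_id, sort(des$condition_id))
})
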