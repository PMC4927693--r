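#' Comparability subset of analytes
#'
#' The ten analytes that eluted with reasonable peak shapes and retention
#' factors in every evaluated condition; width boxplots across factors are
#' restricted to these so that conditions with different total peak counts
#' are compared on the same peaks.
#'
#' @export
COMPARABILITY_SUBSET <- c("2-aminobutyric acid", "adenine", "adenosine",
                          "creatinine", "cytosine", "hippuric acid",
                          "leucine", "proline", "uracil", "xylitol")

#' Tukey five-number summary (boxplot statistics, no outliers)
#'
#' Quartiles by linear interpolation (`stats::quantile` type 7); whiskers at
#' the most extreme data point within 1.5 x IQR of the respective quartile.
#'
#' @param values Numeric vector, `n >= 1`, finite.
#' @return One-row data frame: `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `mean`, `n`.
#' @examples
#' tukey_five_number(1:100)
#' @export
tukey_five_number <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values supplied")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  data.frame(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
             whisker_low = min(values[values >= lo_fence]),
             whisker_high = max(values[values <= hi_fence]),
             mean = mean(values), n = length(values))
}

#' Aggregate a descriptor or merit metric by a design factor
#'
#' Pools records across the other factors and returns one Tukey summary per
#' level of `factor` (additive, column or temperature), with per-level `n`
#' bookkeeping — the structure behind the factor-comparison boxplots.
#'
#' @param records Data frame holding one row per observation with at least
#'   the columns `additive`, `column`, `temperature` and the metric.
#' @param factor One of `"additive"`, `"column"`, `"temperature"`.
#' @param metric Name of the metric column (e.g. `"width_s"`, `"sum_rs"`).
#' @param restrict Optional predicate (function of the data frame returning
#'   a logical vector) or logical vector filtering records first, e.g. to a
#'   modifier set or column block.
#' @param exclude_levels Levels of `factor` dropped from the output (e.g. a
#'   column excluded from performance evaluation); other levels' statistics
#'   are unaffected.
#' @return Data frame, one row per level: `level`, then the
#'   [tukey_five_number()] columns.
#' @export
aggregate_by_factor <- function(records, factor = c("additive", "column",
                                                    "temperature"),
                                metric = "width_s", restrict = NULL,
                                exclude_levels = NULL) {
  factor <- match.arg(factor)
  if (!factor %in% names(records))
    stop("unknown factor: records lack a '", factor, "' column")
  if (!metric %in% names(records))
    stop("records lack metric column '", metric, "'")
  if (!is.null(restrict)) {
    keep <- if (is.function(restrict)) restrict(records) else restrict
    records <- records[keep, , drop = FALSE]
  }
  if (!is.null(exclude_levels))
    records <- records[!records[[factor]] %in% exclude_levels, , drop = FALSE]
  if (nrow(records) == 0) stop("no records left to aggregate")
  levs <- unique(records[[factor]])
  out <- do.call(rbind, lapply(levs, function(l) {
    vals <- records[[metric]][records[[factor]] == l]
    cbind(data.frame(level = l, stringsAsFactors = FALSE),
          tukey_five_number(vals))
  }))
  rownames(out) <- NULL
  out[order(out$median), , drop = FALSE]
}

#' Repeatability of the internal standard
#'
#' Percent relative standard deviations of retention time and peak area over
#' replicate injections of the internal standard.
#'
#' @param standard_peaks Data frame of replicate descriptors with columns
#'   `tr_s` and `area`; `n >= 2` rows.
#' @return One-row data frame: `rsd_tr`, `rsd_area` (percent),
#'   `n_replicates`.
#' @examples
#' repeatability(data.frame(tr_s = c(60, 60, 60), area = c(90, 100, 110)))
#' @export
repeatability <- function(standard_peaks) {
  stopifnot(is.data.frame(standard_peaks),
            all(c("tr_s", "area") %in% names(standard_peaks)))
  n <- nrow(standard_peaks)
  if (n < 2) stop("need >= 2 replicates")
  rsd <- function(x) {
    m <- mean(x)
    if (m == 0) stop("zero mean: RSD undefined")
    100 * stats::sd(x) / m
  }
  data.frame(rsd_tr = rsd(standard_peaks$tr_s),
             rsd_area = rsd(standard_peaks$area), n_replicates = n)
}

#' Rank screening conditions by a lexicographic objective
#'
#' Orders condition summaries by the stated criteria in sequence, each
#' either minimised or maximised; remaining ties break on `condition_id` so
#' the ranking is deterministic. The default objective prefers narrower
#' peaks, then higher total resolution, then more even peak distribution.
#'
#' @param summaries Data frame of per-condition merit summaries (rows from
#'   [summarize_condition()]).
#' @param objective Named character vector: names are summary columns,
#'   values `"min"` or `"max"`, in priority order.
#' @return `summaries` reordered best-first, with a `rank` column prepended.
#' @export
rank_conditions <- function(summaries,
                            objective = c(median_width = "min",
                                          sum_rs = "max", nrp = "max")) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  if (!all(names(objective) %in% names(summaries)))
    stop("objective names must be summary columns")
  if (!all(objective %in% c("min", "max")))
    stop("objective directions must be 'min' or 'max'")
  keys <- lapply(names(objective), function(col) {
    v <- summaries[[col]]
    v[is.na(v)] <- if (objective[[col]] == "min") Inf else -Inf
    if (objective[[col]] == "max") -v else v
  })
  keys <- c(keys, list(summaries$condition_id))
  ord <- do.call(order, keys)
  out <- summaries[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Run the full screen evaluation pipeline
#'
#' For every condition of a [generate_screen()] dataset: figures of merit
#' (with width statistics over the comparability subset), internal-standard
#' repeatability, per-peak hit verdicts; then factor-level aggregations of
#' base width and sum of resolution, per-condition hit rates, and the
#' condition ranking. Deterministic: identical inputs give identical
#' reports.
#'
#' @param dataset A `screen_dataset` from [generate_screen()].
#' @param criteria A [hit_criteria()].
#' @param subset Comparability subset for width statistics; `NULL` uses all
#'   peaks.
#' @param objective Ranking objective, see [rank_conditions()].
#' @param exclude_columns Columns excluded from the column-factor
#'   aggregation (poor-shape phases are dropped from column comparisons but
#'   still evaluated per condition).
#' @return A list of class `screen_report` with elements `summaries`,
#'   `repeatability`, `hit_rates`, `peak_records`, `by_additive`,
#'   `by_column`, `by_temperature`, `ranking`, `design`, `seed`.
#' @export
run_screen_evaluation <- function(dataset, criteria = hit_criteria(),
                                  subset = COMPARABILITY_SUBSET,
                                  objective = c(median_width = "min",
                                                sum_rs = "max", nrp = "max"),
                                  exclude_columns = "BEH Phenyl") {
  stopifnot(inherits(dataset, "screen_dataset"))
  design <- dataset$design

  summaries <- do.call(rbind, lapply(design$condition_id, function(cid) {
    tab <- dataset$tables[[cid]]
    if (nrow(tab) == 0)
      return(data.frame(condition_id = cid, n_peaks = 0L, n_subset = 0L,
                        median_width = NA_real_, mean_width = NA_real_,
                        sum_rs = NA_real_, mean_rs = NA_real_, nrp = NA_real_,
                        pc_width = NA_real_, pc_rs = NA_real_,
                        comparable = FALSE, stringsAsFactors = FALSE))
    suppressWarnings(
      summarize_condition(tab, subset = subset, gradient = dataset$gradient))
  }))
  summaries <- merge(design, summaries, by = "condition_id", sort = FALSE)

  rep_sum <- do.call(rbind, lapply(design$condition_id, function(cid) {
    reps <- dataset$is_replicates[dataset$is_replicates$condition_id == cid, ]
    cbind(condition_id = cid, repeatability(reps))
  }))
  rep_sum <- merge(design, rep_sum, by = "condition_id", sort = FALSE)

  peak_records <- do.call(rbind, lapply(design$condition_id, function(cid) {
    tab <- as.data.frame(dataset$tables[[cid]])
    if (nrow(tab) == 0) return(NULL)
    d <- design[design$condition_id == cid, ]
    cbind(tab, d[rep(1, nrow(tab)), c("condition_id", "column", "additive",
                                      "temperature", "detection")],
          row.names = NULL)
  }))

  hit_rates <- do.call(rbind, lapply(design$condition_id, function(cid) {
    tab <- dataset$tables[[cid]]
    d <- design[design$condition_id == cid, ]
    panel_n <- attr(dataset$tables, "panel_size")
    verdicts <- if (nrow(tab) == 0) logical(0) else
      vapply(seq_len(nrow(tab)), function(i)
        evaluate_hit(tab[i, ], criteria)$hit, logical(1))
    data.frame(condition_id = cid, n_observed = nrow(tab),
               n_hits = sum(verdicts), stringsAsFactors = FALSE)
  }))
  hit_rates <- merge(design, hit_rates, by = "condition_id", sort = FALSE)

  sub_records <- if (is.null(subset)) peak_records else
    peak_records[peak_records$analyte %in% subset, , drop = FALSE]
  by_additive <- aggregate_by_factor(sub_records, "additive", "width_s")
  by_column <- aggregate_by_factor(sub_records, "column", "width_s",
                                   exclude_levels = exclude_columns)
  by_temperature <- aggregate_by_factor(sub_records, "temperature", "width_s")

  ranking <- rank_conditions(summaries, objective = objective)

  structure(list(summaries = summaries, repeatability = rep_sum,
                 hit_rates = hit_rates, peak_records = peak_records,
                 by_additive = by_additive, by_column = by_column,
                 by_temperature = by_temperature, ranking = ranking,
                 design = design, seed = dataset$seed),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d conditions (seed %d)\n",
              nrow(x$design), x$seed))
  cat("Top 5 conditions (median width / sum Rs / NRP):\n")
  top <- utils::head(x$ranking, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %d. %-35s w = %5.1f s  sumRs = %5.2f  r = %4.2f\n",
                top$rank[i], top$condition_id[i], top$median_width[i],
                top$sum_rs[i],
                ifelse(is.na(top$nrp[i]), NA, top$nrp[i])))
  invisible(x)
}

#' Write a human-readable digest of a screen report
#'
#' @param report A `screen_report`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_report_digest <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("SFC screen evaluation digest (seed %d)", report$seed)
  w("Conditions evaluated: %d", nrow(report$design))
  w("")
  w("Median base width by additive (comparability subset):")
  for (i in seq_len(nrow(report$by_additive)))
    w("  %-20s median %5.1f s  (mean %5.1f, n = %d)",
      report$by_additive$level[i], report$by_additive$median[i],
      report$by_additive$mean[i], report$by_additive$n[i])
  w("")
  w("Median base width by column:")
  for (i in seq_len(nrow(report$by_column)))
    w("  %-12s median %5.1f s  (mean %5.1f, n = %d)",
      report$by_column$level[i], report$by_column$median[i],
      report$by_column$mean[i], report$by_column$n[i])
  w("")
  w("Top 10 ranked conditions:")
  top <- utils::head(report$ranking, 10)
  for (i in seq_len(nrow(top)))
    w("  %2d. %-35s width %5.1f s  sumRs %5.2f  NRP %s",
      top$rank[i], top$condition_id[i], top$median_width[i], top$sum_rs[i],
      ifelse(is.na(top$nrp[i]), "NA", sprintf("%4.2f", top$nrp[i])))
  invisible(path)
}
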