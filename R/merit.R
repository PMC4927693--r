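#' Resolution between two peaks
#'
#' `Rs = 2 |tr1 - tr2| / (w1 + w2)`, using base widths. The magnitude of the
#' retention-time difference is used, so the result is symmetric in its
#' arguments and invariant under a common retention-time shift.
#'
#' @param tr1,tr2 Retention times (seconds).
#' @param w1,w2 Base widths (seconds), > 0.
#' @return Resolution (unitless, >= 0).
#' @examples
#' resolution(100, 120, 10, 10)  # 2.0
#' @export
resolution <- function(tr1, tr2, w1, w2) {
  if (any(w1 <= 0) || any(w2 <= 0)) stop("peak widths must be > 0")
  if (any(w1 + w2 == 0)) stop("zero total width")
  2 * abs(tr1 - tr2) / (w1 + w2)
}

adjacent_resolutions <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  n <- nrow(table)
  if (n < 2) return(numeric(0))
  resolution(table$tr_s[-n], table$tr_s[-1], table$width_s[-n], table$width_s[-1])
}

#' Sum of resolution across a chromatogram
#'
#' Sum of the pairwise resolutions of adjacent peaks in elution order; 0 for
#' a single peak.
#'
#' @param table A [peak_table()] (sorted by retention time).
#' @return Sum of resolutions (unitless).
#' @export
sum_resolution <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  if (nrow(table) == 0) stop("empty peak table")
  sum(adjacent_resolutions(table))
}

#' Width-based peak capacity
#'
#' `Pc = 1 + t_g / mean(w)`: peaks of average base width `mean(w)` packed at
#' unit resolution into a gradient of length `t_g`.
#'
#' @param gradient A [gradient_method()] (supplies `t_g`).
#' @param widths Base widths (seconds), all > 0, at least one.
#' @return Peak capacity (unitless).
#' @examples
#' peak_capacity_width(gradient_method(t_g = 240), rep(10, 4))  # 25
#' @export
peak_capacity_width <- function(gradient, widths) {
  stopifnot(inherits(gradient, "gradient_method"))
  if (length(widths) == 0) stop("no widths supplied")
  if (any(widths <= 0)) stop("widths must be > 0")
  1 + gradient$t_g / mean(widths)
}

#' Resolution-based peak capacity
#'
#' `Pc = 1 + sum(Rs)` over adjacent peak pairs.
#'
#' @param sum_rs Sum of resolution, >= 0.
#' @return Peak capacity (unitless).
#' @export
peak_capacity_resolution <- function(sum_rs) {
  if (any(sum_rs < 0)) stop("sum of resolution must be >= 0")
  1 + sum_rs
}

#' Normalised resolution product
#'
#' `r = prod(Rs_i / mean(Rs))` over the adjacent-pair resolutions of the
#' table. Equals 1 when every adjacent resolution is equal (evenly
#' distributed peaks) and is < 1 otherwise (AM-GM inequality); values much
#' below 1 indicate uneven use of the separation window. Undefined (returns
#' `NA`) for fewer than 2 adjacent resolutions (< 3 peaks); a zero adjacent
#' resolution (full co-elution) yields 0 with a warning.
#'
#' @param table A [peak_table()].
#' @return The normalised resolution product in `[0, 1]`, or `NA_real_`.
#' @export
normalized_resolution_product <- function(table) {
  rs <- adjacent_resolutions(table)
  if (length(rs) < 2) return(NA_real_)
  if (any(rs == 0)) {
    warning("co-eluting adjacent peaks (Rs = 0); normalised resolution product is 0")
    return(0)
  }
  prod(rs / mean(rs))
}

#' Per-condition figures of merit
#'
#' Summarises one condition's peak tables into the evaluation metrics:
#' peak count, median/mean base width (over the comparability subset when
#' one is given), sum of resolution and normalised resolution product (over
#' all observed peaks), and both peak-capacity estimates.
#'
#' Width statistics may be restricted to a named analyte subset so that
#' conditions with different total peak counts can be compared on the peaks
#' they share; the resolution-based metrics always use all observed peaks,
#' since resolution is a property of the whole chromatogram.
#'
#' @param tables A [peak_table()] or list of peak tables for one condition.
#' @param subset Optional character vector of analyte ids restricting the
#'   width statistics. If no peak matches, the summary is flagged
#'   `comparable = FALSE` and width statistics are `NA`.
#' @param gradient A [gradient_method()]; defaults to the table attribute.
#' @return One-row data frame of class `merit_summary`: `condition_id`,
#'   `n_peaks`, `n_subset`, `median_width`, `mean_width`, `sum_rs`,
#'   `mean_rs`, `nrp`, `pc_width`, `pc_rs`, `comparable`.
#' @export
summarize_condition <- function(tables, subset = NULL, gradient = NULL) {
  if (inherits(tables, "peak_table")) tables <- list(tables)
  if (length(tables) == 0) stop("no peak tables supplied")
  stopifnot(all(vapply(tables, inherits, logical(1), "peak_table")))
  condition_id <- attr(tables[[1]], "condition_id")
  if (is.null(gradient)) gradient <- attr(tables[[1]], "gradient")
  if (is.null(gradient)) gradient <- gradient_method()

  all_peaks <- do.call(rbind, lapply(tables, as.data.frame))
  n_peaks <- nrow(all_peaks)
  sub_peaks <- if (is.null(subset)) all_peaks
               else all_peaks[all_peaks$analyte %in% subset, , drop = FALSE]
  comparable <- nrow(sub_peaks) > 0
  if (!comparable && n_peaks > 0)
    warning(sprintf("condition '%s': no peaks in comparability subset",
                    condition_id))

  rs_all <- unlist(lapply(tables, adjacent_resolutions))
  sum_rs <- if (n_peaks == 0) NA_real_ else sum(rs_all)
  mean_rs <- if (length(rs_all) > 0) mean(rs_all) else NA_real_
  nrp <- if (length(rs_all) < 2) NA_real_
         else if (any(rs_all == 0)) 0
         else prod(rs_all / mean(rs_all))

  med_w <- if (comparable) stats::median(sub_peaks$width_s) else NA_real_
  mean_w <- if (comparable) mean(sub_peaks$width_s) else NA_real_
  out <- data.frame(
    condition_id = condition_id, n_peaks = n_peaks,
    n_subset = nrow(sub_peaks),
    median_width = med_w, mean_width = mean_w,
    sum_rs = sum_rs, mean_rs = mean_rs, nrp = nrp,
    pc_width = if (comparable) peak_capacity_width(gradient, sub_peaks$width_s)
               else NA_real_,
    pc_rs = if (!is.na(sum_rs)) peak_capacity_resolution(sum_rs) else NA_real_,
    comparable = comparable, stringsAsFactors = FALSE)
  class(out) <- c("merit_summary", "data.frame")
  out
}
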