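#' Hit criteria for acceptable chromatographic peaks
#'
#' A peak is a "hit" when its shape and retention fall within the screen's
#' acceptance window: asymmetry b/a strictly below `max_asymmetry`,
#' retention factor `k` within `[k_min, k_max]` (inclusive), and S/N at or
#' above `min_snr`. Defaults mirror the library screen: b/a < 4,
#' 2 <= k <= 20, S/N >= 3.
#'
#' @param max_asymmetry Exclusive upper bound on b/a, > 0.
#' @param k_min,k_max Inclusive retention-factor window, `k_min < k_max`.
#' @param min_snr Inclusive lower bound on S/N, > 0.
#' @return An object of class `hit_criteria`.
#' @export
hit_criteria <- function(max_asymmetry = 4, k_min = 2, k_max = 20,
                         min_snr = 3) {
  if (k_min >= k_max) stop("k_min must be < k_max")
  if (max_asymmetry <= 0 || k_min <= 0 || min_snr <= 0)
    stop("all thresholds must be > 0")
  structure(list(max_asymmetry = max_asymmetry, k_min = k_min,
                 k_max = k_max, min_snr = min_snr),
            class = "hit_criteria")
}

#' Evaluate one peak against the hit criteria
#'
#' @param desc One-row data frame (or list) with fields `asym`, `k`, `snr`.
#' @param criteria A [hit_criteria()].
#' @return A list with `hit` (logical) and `failures` (character vector of
#'   violated criteria among `"asymmetry"`, `"retention"`, `"snr"`; empty
#'   when hit).
#' @export
evaluate_hit <- function(desc, criteria = hit_criteria()) {
  stopifnot(inherits(criteria, "hit_criteria"))
  for (f in c("asym", "k", "snr")) {
    v <- desc[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      stop(sprintf("descriptor field '%s' is missing", f))
  }
  failures <- character(0)
  if (!(desc$asym < criteria$max_asymmetry)) failures <- c(failures, "asymmetry")
  if (!(desc$k >= criteria$k_min && desc$k <= criteria$k_max))
    failures <- c(failures, "retention")
  if (!(desc$snr >= criteria$min_snr)) failures <- c(failures, "snr")
  list(hit = length(failures) == 0, failures = failures)
}

#' Classify a compound from its per-modifier verdicts
#'
#' Classes follow the library-screen definitions:
#' \itemize{
#'   \item responder — a hit in every tested modifier;
#'   \item sub-responder — a peak eluted in every modifier, but at least one
#'     verdict fails on the retention-factor or asymmetry limit;
#'   \item non-responder — no peak observed in any modifier;
#'   \item intermediate — everything else (eluted in only some modifiers, or
#'     failures on S/N only).
#' }
#'
#' @param per_modifier Named list, one entry per modifier: either the result
#'   of [evaluate_hit()] (or a descriptor row, which is evaluated with
#'   `criteria`), or `NULL` / `"no peak"` when no peak was observed.
#' @param criteria A [hit_criteria()] used when raw descriptors are passed.
#' @return A list with `class`, `n_modifiers`, and `verdicts` (named list of
#'   per-modifier verdicts).
#' @export
classify_compound <- function(per_modifier, criteria = hit_criteria()) {
  if (length(per_modifier) < 1) stop("need at least one modifier entry")
  verdicts <- lapply(per_modifier, function(e) {
    if (is.null(e) || identical(e, "no peak")) return(NULL)
    if (is.list(e) && !is.null(e$hit) && !is.null(e$failures)) return(e)
    evaluate_hit(e, criteria)
  })
  eluted <- !vapply(verdicts, is.null, logical(1))
  if (!any(eluted)) {
    cls <- "non-responder"
  } else if (all(eluted)) {
    hits <- vapply(verdicts, function(v) v$hit, logical(1))
    if (all(hits)) {
      cls <- "responder"
    } else {
      fails <- unlist(lapply(verdicts, function(v) v$failures))
      cls <- if (any(fails %in% c("retention", "asymmetry"))) "sub-responder"
             else "intermediate"  # S/N-only failures
    }
  } else {
    cls <- "intermediate"
  }
  list(class = cls, n_modifiers = length(per_modifier), verdicts = verdicts)
}

#' Hit rate over a panel
#'
#' @param verdicts Logical vector (or list of [evaluate_hit()] results) over
#'   the panel; `NA`/`NULL` entries count as misses (compound not observed).
#' @return Hit rate as a percentage of the panel size.
#' @examples
#' hit_rate(c(rep(TRUE, 45), rep(FALSE, 15)))  # 75
#' @export
hit_rate <- function(verdicts) {
  if (length(verdicts) == 0) stop("empty verdict list")
  if (is.list(verdicts))
    verdicts <- vapply(verdicts, function(v)
      if (is.null(v)) FALSE else isTRUE(v$hit), logical(1))
  verdicts[is.na(verdicts)] <- FALSE
  100 * sum(verdicts) / length(verdicts)
}

#' Best peak per analyte within a modifier's peak table
#'
#' When an analyte matches several peaks (e.g. both MS polarities), the hit
#' evaluation uses the peak with the highest S/N.
#'
#' @param table A [peak_table()] possibly containing duplicate-matched rows
#'   (analyte labels of the form `name` or `name#2`).
#' @param analyte Analyte id.
#' @return The best matching descriptor row, or `NULL` if absent.
#' @export
best_peak <- function(table, analyte) {
  rows <- as.data.frame(table)[sub("#.*$", "", table$analyte) == analyte, ,
                               drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  rows[which.max(rows$snr), , drop = FALSE]
}

#' Set-membership counts across modifiers (Venn-style)
#'
#' Counts, for every non-empty combination of modifiers, how many compounds
#' were hits in exactly that combination.
#'
#' @param hits Named list: modifier -> character vector of compound ids that
#'   were hits in that modifier.
#' @return Data frame with columns `combination` (modifiers joined by
#'   `" & "`) and `count`, covering every non-empty subset (zero counts
#'   included).
#' @export
venn_counts <- function(hits) {
  if (length(hits) == 0) stop("no modifier sets supplied")
  mods <- names(hits)
  all_compounds <- unique(unlist(hits))
  membership <- vapply(mods, function(m) all_compounds %in% hits[[m]],
                       logical(length(all_compounds)))
  if (length(all_compounds) == 1)
    membership <- matrix(membership, nrow = 1, dimnames = list(NULL, mods))
  combos <- unlist(lapply(seq_along(mods), function(k)
    utils::combn(mods, k, paste, collapse = " & ", simplify = FALSE)),
    use.names = FALSE)
  counts <- vapply(combos, function(cmb) {
    members <- strsplit(cmb, " & ", fixed = TRUE)[[1]]
    exact <- apply(membership, 1, function(r)
      all(r[mods %in% members]) && !any(r[!mods %in% members]))
    sum(exact)
  }, numeric(1))
  data.frame(combination = combos, count = counts, stringsAsFactors = FALSE)
}
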