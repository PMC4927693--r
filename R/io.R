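#' Chromatogram container
#'
#' A sampled intensity-versus-time trace for one injection and one detection
#' channel. Time must be a strictly increasing, uniform grid (relative step
#' tolerance 1e-9) with at least 2 samples; all values must be finite.
#'
#' @param time Time grid (seconds).
#' @param intensity Detector intensities (arbitrary units).
#' @param channel `"MS"` or `"UV"`.
#' @param condition_id Condition label.
#' @return An object of class `chromatogram` (a list with elements `time`,
#'   `intensity`, `channel`, `condition_id`).
#' @export
chromatogram <- function(time, intensity, channel = c("MS", "UV"),
                         condition_id = "unknown") {
  channel <- match.arg(channel)
  if (length(time) != length(intensity))
    stop("time and intensity must have equal length")
  if (length(time) < 2) stop("no samples: a chromatogram needs >= 2 points")
  if (!all(is.finite(time)) || !all(is.finite(intensity)))
    stop("chromatogram values must all be finite")
  check_uniform_grid(time)
  structure(
    list(time = as.numeric(time), intensity = as.numeric(intensity),
         channel = channel, condition_id = condition_id),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> condition '%s', channel %s, %d samples, %.2f-%.2f s\n",
              x$condition_id, x$channel, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Write / read a chromatogram as tab-delimited text
#'
#' Two numeric columns (`time_s`, `intensity`), tab separator, "." decimal,
#' one header line; comment lines start with `#` and carry the condition id,
#' channel and (if present) the simulation seed. A write/read round trip
#' reproduces the trace to full printed precision (17 significant digits).
#'
#' @param chrom A [chromatogram()].
#' @param path File path.
#' @return `read_chromatogram` returns a [chromatogram()];
#'   `write_chromatogram` returns `path` invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# condition: %s", chrom$condition_id),
    sprintf("# channel: %s", chrom$channel),
    if (!is.null(attr(chrom, "seed"))) sprintf("# seed: %d", attr(chrom, "seed")),
    "time_s\tintensity"
  ), con)
  writeLines(paste(format(chrom$time, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(chrom$intensity, digits = 17, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  if (length(body) < 1) stop("no samples: file has no data rows")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("expected two tab-separated columns (time_s, intensity)")
  rows <- body[-1]
  if (length(rows) == 0) stop("no samples: header-only file")
  dat <- utils::read.table(text = rows, sep = "\t", col.names = header,
                           colClasses = "numeric")
  tm <- dat[[1]]
  bad <- which(diff(tm) <= 0)
  if (length(bad) > 0)
    stop(sprintf("time not strictly increasing at data row %d (t = %g)",
                 bad[1] + 1, tm[bad[1] + 1]))
  grab <- function(key) {
    m <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(m) == 0) NULL else trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  cond <- grab("condition")
  chan <- grab("channel")
  chrom <- chromatogram(tm, dat[[2]],
                        channel = if (is.null(chan)) "MS" else chan,
                        condition_id = if (is.null(cond)) "unknown" else cond)
  seed <- grab("seed")
  if (!is.null(seed)) attr(chrom, "seed") <- as.integer(seed)
  chrom
}

#' Peak table container
#'
#' A data frame of per-peak descriptors for one condition, sorted by
#' retention time, with unique analyte ids. Columns: `analyte`, `tr_s`,
#' `area`, `height`, `width_s`, `asym`, `snr` and optionally `k`. `asym` and
#' `snr` may be `NA` (absent); widths and heights must be positive.
#'
#' @param df Data frame with at least `analyte`, `tr_s`, `area`, `height`,
#'   `width_s` columns.
#' @param condition_id Condition label.
#' @param gradient Optional [gradient_method()] stored as an attribute.
#' @return A data frame of class `peak_table`.
#' @export
peak_table <- function(df, condition_id = "unknown", gradient = NULL) {
  req <- c("analyte", "tr_s", "area", "height", "width_s")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("peak table missing columns: ", paste(missing_cols, collapse = ", "))
  for (opt in c("asym", "snr", "k")) if (!opt %in% names(df)) df[[opt]] <- NA_real_
  df <- df[, c("analyte", "tr_s", "area", "height", "width_s", "asym", "snr", "k")]
  df$analyte <- as.character(df$analyte)
  for (num in setdiff(names(df), "analyte")) df[[num]] <- as.numeric(df[[num]])
  if (nrow(df) > 0) {
    if (any(!is.finite(df$width_s)) || any(df$width_s <= 0))
      stop("invalid peak width: widths must be positive and finite")
    if (any(df$height <= 0)) stop("peak heights must be positive")
    if (anyDuplicated(df$analyte))
      stop("analyte ids must be unique within a peak table")
    if (is.unsorted(df$tr_s)) {
      message("peak table not sorted by retention time; sorting")
      df <- df[order(df$tr_s), , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df, condition_id = condition_id, gradient = gradient,
            class = c("peak_table", "data.frame"))
}

#' Write / read a peak table as tab-delimited text
#'
#' Header columns `analyte`, `tr_s`, `area`, `height`, `width_s`, `asym`,
#' `snr` (plus `k` when known); tab separator, "." decimal; comment lines
#' start with `#`. Missing `asym`/`snr` are serialised as `NA` and read back
#' as absent. Negative widths are rejected on read.
#'
#' @param table A [peak_table()].
#' @param path File path.
#' @return `read_peak_table` returns a [peak_table()]; `write_peak_table`
#'   returns `path` invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condition: %s", attr(table, "condition_id")), con)
  gr <- attr(table, "gradient")
  if (!is.null(gr))
    writeLines(sprintf("# gradient: t_g=%g t0=%g", gr$t_g, gr$t0), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  if (length(body) < 1) stop("empty peak table file")
  dat <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           na.strings = "NA",
                           colClasses = c(analyte = "character"))
  req <- c("analyte", "tr_s", "area", "height", "width_s", "asym", "snr")
  missing_cols <- setdiff(req, names(dat))
  if (length(missing_cols) > 0)
    stop("peak table header must declare columns: ",
         paste(missing_cols, collapse = ", "))
  cond <- grep("^# condition:", meta, value = TRUE)
  cond <- if (length(cond)) trimws(sub("^# condition:", "", cond[1])) else "unknown"
  grl <- grep("^# gradient:", meta, value = TRUE)
  gradient <- NULL
  if (length(grl)) {
    tg <- as.numeric(sub(".*t_g=([0-9.eE+-]+).*", "\\1", grl[1]))
    t0 <- as.numeric(sub(".*t0=([0-9.eE+-]+).*", "\\1", grl[1]))
    gradient <- gradient_method(t_g = tg, t0 = t0)
  }
  peak_table(dat, condition_id = cond, gradient = gradient)
}

#' Read a screen design from a structured text (YAML) file
#'
#' The design file lists one block per screening phase; each block names its
#' columns, additives and temperatures, and the block's conditions are the
#' full factorial of the three. Detection mode is derived from the additive:
#' alkylamine additives (isopropylamine, isobutylamine, isopentylamine) are
#' UV-only (they are incompatible with the MS source); all other additives
#' use MS detection. A block that explicitly requests `detection: MS` for an
#' alkylamine additive is rejected, as is any design whose blocks enumerate
#' the same (column, additive, temperature) cell twice.
#'
#' @param path Path to a YAML design file with a top-level `blocks` list.
#' @return A [screen_design()] object.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$blocks) || length(spec$blocks) == 0)
    stop("design has no blocks")
  blocks <- lapply(spec$blocks, function(b) {
    design_block(columns = b$columns, additives = b$additives,
                 temperatures = b$temperatures, detection = b$detection)
  })
  screen_design(blocks)
}
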