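#' Factor-level vocabularies for the SFC screen
#'
#' Stationary phases, modifier additives and column temperatures recognised
#' by the design validator. The Torus family (2-PIC, Diol, DEA, 1-AA) is the
#' only column set allowed at 55 degC; the alkylamine additives are UV-only.
#'
#' @name screen_levels
NULL

#' @rdname screen_levels
#' @export
SFC_COLUMNS <- c("BEH 2-EP", "BEH", "CSH FP", "HSS C18 SB",
                 "BEH Amide", "BEH HILIC", "BEH Phenyl", "HSS Cyano",
                 "2-PIC", "Diol", "DEA", "1-AA")

#' @rdname screen_levels
#' @export
TORUS_COLUMNS <- c("2-PIC", "Diol", "DEA", "1-AA")

#' @rdname screen_levels
#' @export
SFC_ADDITIVES <- c("formic acid", "acetic acid", "ammonium formate",
                   "ammonium acetate", "ammonium hydroxide", "water",
                   "isopropylamine", "isobutylamine", "isopentylamine")

#' @rdname screen_levels
#' @export
ALKYLAMINE_ADDITIVES <- c("isopropylamine", "isobutylamine", "isopentylamine")

#' @rdname screen_levels
#' @export
SFC_TEMPERATURES <- c(35, 40, 45, 55)

#' Detection mode implied by an additive
#'
#' Alkylamines contaminate the ESI source, so conditions using them are run
#' with UV-vis detection only; all other additives are MS-compatible.
#'
#' @param additive Character vector of additive names.
#' @return Character vector, `"UV"` or `"MS"`.
#' @export
detection_for_additive <- function(additive) {
  ifelse(additive %in% ALKYLAMINE_ADDITIVES, "UV", "MS")
}

#' One screening-phase block of a design
#'
#' @param columns Character vector of column names.
#' @param additives Character vector of additive names.
#' @param temperatures Numeric vector of column temperatures (degC).
#' @param detection Optional explicit detection mode for the whole block
#'   (`"MS"` or `"UV"`); by default derived per additive.
#' @return An object of class `design_block`.
#' @export
design_block <- function(columns, additives, temperatures, detection = NULL) {
  if (length(columns) == 0 || length(additives) == 0 || length(temperatures) == 0)
    stop("design block needs at least one column, additive and temperature")
  bad <- setdiff(columns, SFC_COLUMNS)
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(additives, SFC_ADDITIVES)
  if (length(bad)) stop("unknown additive(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(temperatures, SFC_TEMPERATURES)
  if (length(bad)) stop("unsupported temperature(s): ", paste(bad, collapse = ", "))
  if (!is.null(detection)) {
    detection <- match.arg(detection, c("MS", "UV"))
    if (detection == "MS" && any(additives %in% ALKYLAMINE_ADDITIVES))
      stop("alkylamine additives are UV-only (stand-alone mode); ",
           "cannot pair with MS detection")
  }
  structure(list(columns = columns, additives = additives,
                 temperatures = temperatures, detection = detection),
            class = "design_block")
}

#' Screen design: enumerated (column, additive, temperature) conditions
#'
#' Expands each block to its full factorial and concatenates the blocks.
#' Validation enforces: no duplicate conditions across blocks; 55 degC only
#' for Torus columns; alkylamine additives never paired with MS detection.
#'
#' @param blocks List of [design_block()] objects.
#' @return A data frame of class `screen_design` with columns
#'   `condition_id`, `column`, `additive`, `temperature`, `detection`.
#' @examples
#' d <- screen_design(list(design_block("Diol", "water", 40)))
#' @export
screen_design <- function(blocks) {
  if (length(blocks) == 0) stop("design has no blocks")
  stopifnot(all(vapply(blocks, inherits, logical(1), "design_block")))
  grids <- lapply(blocks, function(b) {
    g <- expand.grid(column = b$columns, additive = b$additives,
                     temperature = b$temperatures,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    g$detection <- if (is.null(b$detection)) detection_for_additive(g$additive)
                   else b$detection
    g
  })
  d <- do.call(rbind, grids)
  key <- paste(d$column, d$additive, d$temperature, sep = " | ")
  dup <- key[duplicated(key)]
  if (length(dup) > 0)
    stop("duplicate condition(s) in design: ", paste(unique(dup), collapse = "; "))
  hot <- d$temperature == 55 & !(d$column %in% TORUS_COLUMNS)
  if (any(hot))
    stop("55 degC is only valid for Torus columns; offending: ",
         paste(unique(d$column[hot]), collapse = ", "))
  d$condition_id <- sprintf(
    "%s_%s_%g%s", gsub("[ /]", "-", d$column), gsub(" ", "-", d$additive),
    d$temperature, ifelse(d$detection == "UV", "_UV", ""))
  d <- d[, c("condition_id", "column", "additive", "temperature", "detection")]
  rownames(d) <- NULL
  structure(d, blocks = blocks, class = c("screen_design", "data.frame"))
}

#' The full method-development screen design
#'
#' Reproduces the study layout: an initial block of eight columns (four SFC
#' phases and four UHPLC phases) crossed with nine modifier additives and
#' three temperatures (35/40/45 degC), plus a Torus block of four columns
#' crossed with the three best-performing MS-compatible modifiers (water,
#' ammonium formate, formic acid) and four temperatures (35/40/45/55 degC):
#' 8 x 9 x 3 + 4 x 3 x 4 = 264 unique conditions.
#'
#' @param torus_additives The three MS-compatible modifiers used for the
#'   Torus block.
#' @return A [screen_design()] with 264 conditions.
#' @export
sfc_method_development_design <- function(
    torus_additives = c("water", "ammonium formate", "formic acid")) {
  initial <- design_block(
    columns = c("BEH 2-EP", "BEH", "CSH FP", "HSS C18 SB",
                "BEH Amide", "BEH HILIC", "BEH Phenyl", "HSS Cyano"),
    additives = SFC_ADDITIVES,
    temperatures = c(35, 40, 45))
  torus <- design_block(
    columns = TORUS_COLUMNS,
    additives = torus_additives,
    temperatures = c(35, 40, 45, 55))
  screen_design(list(initial, torus))
}

#' Write a screen design to a YAML file readable by [read_design()]
#'
#' @param design A [screen_design()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "screen_design"))
  blocks <- attr(design, "blocks")
  out <- list(blocks = lapply(blocks, function(b) {
    bl <- list(columns = b$columns, additives = b$additives,
               temperatures = b$temperatures)
    if (!is.null(b$detection)) bl$detection <- b$detection
    bl
  }))
  yaml::write_yaml(out, path)
  invisible(path)
}
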