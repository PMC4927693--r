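#' Compound metadata for the emulated polar-analyte panel
#'
#' @param analyte_id Analyte label.
#' @param compound_class One of `"nucleobase/nucleoside"`, `"amino acid"`,
#'   `"organic acid"`, `"sugar"`, `"amine"`, `"other"`.
#' @param clogp Calculated logP; the emulated panel spans roughly -7 to +2.
#' @param clogd Calculated logD (pH 5.5).
#' @param mw Molecular weight (Da), <= 505 for this panel.
#' @param uv_active Whether the compound is detectable by UV-vis (only
#'   UV-active analytes appear in UV-only conditions).
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(analyte_id, compound_class = "other", clogp = 0,
                          clogd = clogp, mw = 150, uv_active = FALSE) {
  classes <- c("nucleobase/nucleoside", "amino acid", "organic acid",
               "sugar", "amine", "other")
  compound_class <- match.arg(compound_class, classes)
  if (clogp < -7 || clogp > 2)
    stop("clogp outside the emulated panel range [-7, +2]")
  if (mw > 505) stop("mw exceeds the panel maximum of 505 Da")
  structure(list(analyte_id = analyte_id, compound_class = compound_class,
                 clogp = clogp, clogd = clogd, mw = mw,
                 uv_active = isTRUE(uv_active)),
            class = "compound_spec")
}

#' Default 20-analyte test panel
#'
#' A synthetic stand-in for the twenty test-mixture compounds (eleven
#' responders plus nine sub-responders) used in the method-development
#' screen. The ten analytes of the comparability subset (2-aminobutyric
#' acid, adenine, adenosine, creatinine, cytosine, hippuric acid, leucine,
#' proline, uracil, xylitol) are included by name; retention anchors and
#' widths are synthetic. The seven UV-active analytes are flagged so that
#' UV-only (alkylamine) conditions observe only those.
#'
#' @return A list of [compound_spec()] objects with attributes
#'   `tr_base` (seconds), `width_base` (seconds), `asym_base` and
#'   `amplitude` aligned with the list order.
#' @export
default_test_panel <- function() {
  tab <- data.frame(
    analyte = c("2-aminobutyric acid", "adenine", "adenosine", "creatinine",
                "cytosine", "hippuric acid", "leucine", "proline", "uracil",
                "xylitol", "cytidine", "uridine", "methionine", "tryptophan",
                "lysine", "taurine", "hypoxanthine", "inosine",
                "pantothenic acid", "nicotinamide"),
    class = c("organic acid", "nucleobase/nucleoside", "nucleobase/nucleoside",
              "other", "nucleobase/nucleoside", "organic acid", "amino acid",
              "amino acid", "nucleobase/nucleoside", "sugar",
              "nucleobase/nucleoside", "nucleobase/nucleoside", "amino acid",
              "amino acid", "amino acid", "amine", "nucleobase/nucleoside",
              "nucleobase/nucleoside", "organic acid", "other"),
    clogp = c(-2.8, -0.1, -1.1, -1.8, -1.7, 0.3, -1.5, -2.5, -1.1, -2.9,
              -2.5, -1.9, -1.9, -1.1, -3.1, -4.2, -0.7, -2.1, -1.1, -0.4),
    mw = c(103, 135, 267, 113, 111, 179, 131, 115, 112, 152,
           243, 244, 149, 204, 146, 125, 136, 268, 219, 122),
    uv = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
           FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
           FALSE, FALSE),
    tr_base = c(150, 95, 180, 120, 160, 80, 140, 170, 110, 230,
                260, 210, 190, 130, 300, 280, 125, 240, 100, 90),
    width_base = c(21, 17, 19, 18, 20, 16, 22, 21, 17, 26,
                   24, 22, 21, 18, 28, 27, 18, 23, 19, 17),
    asym_base = c(1.6, 1.3, 1.4, 1.3, 1.5, 1.2, 1.7, 1.6, 1.3, 2.0,
                  1.8, 1.6, 1.6, 1.4, 2.2, 2.1, 1.4, 1.7, 1.5, 1.3),
    amplitude = c(600, 1500, 1200, 1400, 1100, 1600, 700, 650, 1300, 400,
                  900, 1000, 800, 1200, 350, 380, 1250, 850, 950, 1350),
    stringsAsFactors = FALSE)
  panel <- mapply(function(a, cl, lp, mw, uv)
    compound_spec(a, cl, clogp = lp, mw = mw, uv_active = uv),
    tab$analyte, tab$class, tab$clogp, tab$mw, tab$uv,
    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  attr(panel, "tr_base") <- stats::setNames(tab$tr_base, tab$analyte)
  attr(panel, "width_base") <- stats::setNames(tab$width_base, tab$analyte)
  attr(panel, "asym_base") <- stats::setNames(tab$asym_base, tab$analyte)
  attr(panel, "amplitude") <- stats::setNames(tab$amplitude, tab$analyte)
  panel
}

#' Generative effect model for the synthetic screen
#'
#' Encodes, as multiplicative/additive knobs, the condition-dependent
#' phenomena the evaluation is designed to detect: per-additive, per-column
#' and per-temperature base-width multipliers; retention-time shifts;
#' asymmetry factors; per-compound elution probabilities; and the
#' per-condition coefficient of variation of the internal-standard peak area
#' (emulating electrospray pulsing at high CO2 fractions).
#'
#' Defaults qualitatively reproduce the screen's findings: ammonium salts
#' and water narrow peaks relative to the acids, alkylamines narrow them
#' further (UV detection), the Torus Diol and 2-PIC columns give the
#' narrowest peaks while BEH Phenyl gives very broad ones, 55 degC narrows
#' peaks, and ammonium hydroxide / Diol / 2-PIC conditions carry elevated
#' internal-standard area variability.
#'
#' @param additive_width,column_width,temperature_width Named positive
#'   multipliers on peak base width (missing levels default to 1).
#' @param additive_shift,column_shift Named retention-time shifts (seconds).
#' @param additive_asym,column_asym Named multipliers on asymmetry b/a.
#' @param elution_prob Base probability that a panel compound elutes in a
#'   given condition.
#' @param elution_overrides Optional data frame with columns `analyte`,
#'   `additive` (`NA` for any), `column` (`NA` for any), `prob` overriding
#'   the base elution probability.
#' @param is_area_cv_additive,is_area_cv_column Named percent CVs /
#'   multipliers composing the internal-standard area CV per condition:
#'   `cv = is_area_cv_additive[additive] * is_area_cv_column[column]`.
#' @param tr_jitter_rsd Injection-to-injection retention jitter, percent RSD.
#' @param width_noise_sdlog Log-sd of the multiplicative width noise.
#' @param baseline_sd Detector baseline noise sd used to assign S/N.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(
    additive_width = c("water" = 1.00, "ammonium formate" = 0.96,
                       "ammonium acetate" = 1.00, "ammonium hydroxide" = 0.86,
                       "formic acid" = 1.69, "acetic acid" = 1.50,
                       "isopropylamine" = 0.22, "isobutylamine" = 0.235,
                       "isopentylamine" = 0.25),
    column_width = c("Diol" = 0.63, "2-PIC" = 0.67, "DEA" = 0.75,
                     "1-AA" = 0.78, "HSS C18 SB" = 0.87, "BEH 2-EP" = 0.87,
                     "BEH" = 1.10, "BEH HILIC" = 1.05, "BEH Amide" = 1.25,
                     "CSH FP" = 1.40, "HSS Cyano" = 1.00, "BEH Phenyl" = 2.50),
    temperature_width = c("35" = 1.00, "40" = 0.99, "45" = 0.98, "55" = 0.83),
    additive_shift = c("ammonium hydroxide" = -10, "formic acid" = 15,
                       "acetic acid" = 10),
    column_shift = c("Diol" = -15, "2-PIC" = -10, "BEH Amide" = 25,
                     "BEH Phenyl" = 30),
    additive_asym = c("ammonium formate" = 0.85, "ammonium acetate" = 0.85,
                      "ammonium hydroxide" = 0.80, "formic acid" = 1.40,
                      "acetic acid" = 1.30, "isopropylamine" = 0.70,
                      "isobutylamine" = 0.72, "isopentylamine" = 0.75),
    column_asym = c("BEH Phenyl" = 2.2, "CSH FP" = 1.4, "Diol" = 0.85,
                    "2-PIC" = 0.90),
    elution_prob = 0.95,
    elution_overrides = NULL,
    is_area_cv_additive = c("water" = 8, "formic acid" = 8, "acetic acid" = 8,
                            "ammonium formate" = 10, "ammonium acetate" = 9,
                            "ammonium hydroxide" = 16.3,
                            "isopropylamine" = 4, "isobutylamine" = 4,
                            "isopentylamine" = 4),
    is_area_cv_column = c("Diol" = 1.6, "2-PIC" = 1.35, "BEH 2-EP" = 0.3),
    tr_jitter_rsd = 0.3,
    width_noise_sdlog = 0.10,
    baseline_sd = 5) {
  chk_pos <- function(x, nm) if (any(x <= 0))
    stop(nm, " multipliers must be > 0")
  chk_pos(additive_width, "additive_width"); chk_pos(column_width, "column_width")
  chk_pos(temperature_width, "temperature_width")
  if (elution_prob < 0 || elution_prob > 1)
    stop("elution_prob must be in [0, 1]")
  if (!is.null(elution_overrides)) {
    stopifnot(is.data.frame(elution_overrides),
              all(c("analyte", "prob") %in% names(elution_overrides)))
    if (any(elution_overrides$prob < 0 | elution_overrides$prob > 1))
      stop("override probabilities must be in [0, 1]")
    if (!"additive" %in% names(elution_overrides))
      elution_overrides$additive <- NA_character_
    if (!"column" %in% names(elution_overrides))
      elution_overrides$column <- NA_character_
  }
  if (any(is_area_cv_additive < 0) || any(is_area_cv_column < 0) ||
      tr_jitter_rsd < 0)
    stop("CVs must be >= 0")
  structure(list(
    additive_width = additive_width, column_width = column_width,
    temperature_width = temperature_width,
    additive_shift = additive_shift, column_shift = column_shift,
    additive_asym = additive_asym, column_asym = column_asym,
    elution_prob = elution_prob, elution_overrides = elution_overrides,
    is_area_cv_additive = is_area_cv_additive,
    is_area_cv_column = is_area_cv_column,
    tr_jitter_rsd = tr_jitter_rsd, width_noise_sdlog = width_noise_sdlog,
    baseline_sd = baseline_sd), class = "effect_model")
}

lookup1 <- function(tbl, key, default = 1) {
  if (is.null(tbl) || !(as.character(key) %in% names(tbl))) default
  else unname(tbl[[as.character(key)]])
}

effect_elution_prob <- function(effects, analyte, additive, column) {
  p <- effects$elution_prob
  ov <- effects$elution_overrides
  if (!is.null(ov)) {
    hit <- ov$analyte == analyte &
      (is.na(ov$additive) | ov$additive == additive) &
      (is.na(ov$column) | ov$column == column)
    if (any(hit)) p <- ov$prob[which(hit)[length(which(hit))]]
  }
  p
}

effect_is_cv <- function(effects, additive, column) {
  lookup1(effects$is_area_cv_additive, additive, 8) *
    lookup1(effects$is_area_cv_column, column, 1)
}

#' Generate a full synthetic screen dataset
#'
#' Draws, for every condition of the design, a peak table for the test panel
#' (descriptor-level generation: retention, base width, asymmetry, height,
#' area, S/N and k are sampled from the effect model) plus replicate
#' internal-standard (caffeine analogue) descriptors whose area fluctuates
#' with the condition's internal-standard CV. Generation is deterministic in
#' `(design, panel, effects, seed)`; compounds with elution probability 0
#' never appear; UV-only conditions observe only UV-active compounds.
#'
#' @param design A [screen_design()].
#' @param panel A compound panel, e.g. [default_test_panel()].
#' @param effects An [effect_model()].
#' @param seed Integer master seed (required).
#' @param gradient A [gradient_method()]; its `t0` feeds retention factors.
#' @param n_is_replicates Internal-standard injections per condition (>= 4,
#'   mirroring the 4 x 1 uL caffeine injections used to confirm column
#'   equilibration).
#' @return An object of class `screen_dataset`: a list with `design`,
#'   `tables` (named list of [peak_table()]), `is_replicates` (data frame),
#'   and provenance (`seed`, `effects`, `gradient`).
#' @export
generate_screen <- function(design, panel, effects = effect_model(), seed,
                            gradient = gradient_method(t_g = 441, t0 = 30),
                            n_is_replicates = 4) {
  stopifnot(inherits(design, "screen_design"), inherits(effects, "effect_model"))
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a screen dataset requires an explicit integer seed")
  if (length(panel) == 0) stop("panel must be non-empty")
  if (n_is_replicates < 4)
    stop("n_is_replicates must be >= 4 (equilibration-check injections)")

  tr_base <- attr(panel, "tr_base")
  width_base <- attr(panel, "width_base")
  asym_base <- attr(panel, "asym_base")
  amplitude <- attr(panel, "amplitude")
  ids <- vapply(panel, `[[`, character(1), "analyte_id")
  uv_ok <- vapply(panel, `[[`, logical(1), "uv_active")
  # synthetic anchors for panels built without them
  if (is.null(tr_base))
    tr_base <- stats::setNames(seq(80, 380, length.out = length(ids)), ids)
  if (is.null(width_base))
    width_base <- stats::setNames(rep(20, length(ids)), ids)
  if (is.null(asym_base))
    asym_base <- stats::setNames(rep(1.5, length(ids)), ids)
  if (is.null(amplitude))
    amplitude <- stats::setNames(rep(1000, length(ids)), ids)

  with_seed(as.integer(seed), {
    cond_seeds <- sample.int(.Machine$integer.max - 1L, nrow(design))
  })

  tables <- vector("list", nrow(design))
  is_rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    cond <- design[i, ]
    wmult <- lookup1(effects$additive_width, cond$additive) *
      lookup1(effects$column_width, cond$column) *
      lookup1(effects$temperature_width, cond$temperature)
    shift <- lookup1(effects$additive_shift, cond$additive, 0) +
      lookup1(effects$column_shift, cond$column, 0)
    amult <- lookup1(effects$additive_asym, cond$additive) *
      lookup1(effects$column_asym, cond$column)
    observed <- if (cond$detection == "UV") which(uv_ok) else seq_along(ids)

    res <- with_seed(cond_seeds[i], {
      rows <- list()
      for (j in observed) {
        a <- ids[j]
        p_elute <- effect_elution_prob(effects, a, cond$additive, cond$column)
        if (stats::runif(1) > p_elute) next
        tr <- (tr_base[[a]] + shift) *
          (1 + stats::rnorm(1, sd = effects$tr_jitter_rsd / 100))
        w <- width_base[[a]] * wmult *
          stats::rlnorm(1, sdlog = effects$width_noise_sdlog)
        asym <- max(asym_base[[a]] * amult *
                      stats::rlnorm(1, sdlog = 0.05), 1.0)
        h <- amplitude[[a]] * stats::rlnorm(1, sdlog = 0.15) /
          sqrt(wmult)  # broader peaks are shorter at equal load
        area <- h * (w / 4) * sqrt(2 * pi)
        rows[[length(rows) + 1]] <- data.frame(
          analyte = a, tr_s = tr, area = area, height = h, width_s = w,
          asym = asym, snr = h / (2 * effects$baseline_sd),
          k = (tr - gradient$t0) / gradient$t0,
          stringsAsFactors = FALSE)
      }
      cv <- effect_is_cv(effects, cond$additive, cond$column) / 100
      sdl <- sqrt(log(1 + cv^2))
      is_tr <- 60 * (1 + stats::rnorm(n_is_replicates,
                                      sd = effects$tr_jitter_rsd / 100))
      is_area <- 5e4 * stats::rlnorm(n_is_replicates,
                                     meanlog = -sdl^2 / 2, sdlog = sdl)
      is_df <- data.frame(
        condition_id = cond$condition_id, replicate = seq_len(n_is_replicates),
        analyte = "caffeine (IS)", tr_s = is_tr, area = is_area,
        height = is_area / ((12 / 4) * sqrt(2 * pi)), width_s = 12,
        stringsAsFactors = FALSE)
      list(rows = rows, is_df = is_df)
    })
    tab <- if (length(res$rows)) do.call(rbind, res$rows) else
      data.frame(analyte = character(0), tr_s = numeric(0), area = numeric(0),
                 height = numeric(0), width_s = numeric(0), asym = numeric(0),
                 snr = numeric(0), k = numeric(0), stringsAsFactors = FALSE)
    tables[[i]] <- suppressMessages(
      peak_table(tab, condition_id = cond$condition_id, gradient = gradient))
    is_rows[[i]] <- res$is_df
  }
  names(tables) <- design$condition_id
  structure(list(design = design, tables = tables,
                 is_replicates = do.call(rbind, is_rows),
                 seed = as.integer(seed), effects = effects,
                 gradient = gradient),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> %d conditions, %d peaks total, seed %d\n",
              nrow(x$design), sum(vapply(x$tables, nrow, integer(1))), x$seed))
  invisible(x)
}

#' Simulate a compound-library screen with planted response classes
#'
#' Emulates the initial library screen in which every compound of a panel is
#' injected once per organic modifier and its descriptors decide a hit
#' verdict. Each compound is given a planted class and descriptors are drawn
#' so that classification recovers the plant: responders satisfy every hit
#' criterion in every modifier; sub-responders elute everywhere but violate
#' the retention-factor or asymmetry limit in at least one modifier;
#' non-responders never produce a peak; intermediates elute in only a subset
#' of modifiers.
#'
#' @param classes Character vector of planted classes (one per compound),
#'   each of `"responder"`, `"sub-responder"`, `"non-responder"`,
#'   `"intermediate"`.
#' @param modifiers Character vector of modifier names (>= 2).
#' @param seed Integer seed.
#' @param t0 Dead time (seconds) used to convert retention factors to times.
#' @return A named list (one element per compound) of per-modifier entries:
#'   either a one-row descriptor data frame or `NULL` ("no peak").
#' @export
simulate_library_screen <- function(classes,
                                    modifiers = c("5% water/methanol",
                                                  "ammonium formate/methanol",
                                                  "formic acid/methanol",
                                                  "7% water/isopropanol"),
                                    seed, t0 = 30) {
  ok <- c("responder", "sub-responder", "non-responder", "intermediate")
  if (!all(classes %in% ok))
    stop("classes must be among: ", paste(ok, collapse = ", "))
  if (length(modifiers) < 2) stop("need >= 2 modifiers")
  if (missing(seed)) stop("simulate_library_screen requires a seed")

  good_desc <- function() data.frame(
    tr_s = t0 * (1 + stats::runif(1, 2.2, 18)), width_s = stats::runif(1, 8, 30),
    asym = stats::runif(1, 1.0, 3.0), snr = stats::runif(1, 5, 200),
    height = stats::runif(1, 100, 2000))
  with_seed(as.integer(seed), {
    out <- lapply(seq_along(classes), function(i) {
      cl <- classes[i]
      if (cl == "non-responder")
        return(stats::setNames(rep(list(NULL), length(modifiers)), modifiers))
      per <- lapply(modifiers, function(m) {
        d <- good_desc()
        d$height <- d$snr * 10  # noise sd 5, snr = height / (2 * sd)
        d$area <- d$height * d$width_s / 4 * sqrt(2 * pi)
        d$k <- (d$tr_s - t0) / t0
        d
      })
      names(per) <- modifiers
      if (cl == "sub-responder") {
        nbad <- sample(seq_along(modifiers), 1)
        bad <- sample(seq_along(modifiers), nbad)
        for (b in bad) {
          if (stats::runif(1) < 0.5) {
            per[[b]]$asym <- stats::runif(1, 4.2, 8)   # b/a >= 4: shape fail
          } else {
            kbad <- if (stats::runif(1) < 0.5) stats::runif(1, 0.2, 1.8)
                    else stats::runif(1, 21, 40)
            per[[b]]$k <- kbad
            per[[b]]$tr_s <- t0 * (1 + kbad)
          }
        }
      } else if (cl == "intermediate") {
        nmiss <- sample(seq_len(length(modifiers) - 1), 1)
        miss <- sample(seq_along(modifiers), nmiss)
        for (b in miss) per[b] <- list(NULL)
      }
      per
    })
    names(out) <- if (!is.null(names(classes)) && all(nzchar(names(classes))))
      names(classes) else sprintf("compound_%03d", seq_along(classes))
    out
  })
}
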