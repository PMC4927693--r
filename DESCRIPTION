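Package: sfcscreen
Title: Chromatographic Performance Evaluation for SFC Method Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating chromatographic separation quality in
    supercritical fluid chromatography (SFC) method-development screens of
    polar metabolites. Simulates gradient-elution chromatograms from
    exponentially modified Gaussian peak models, detects peaks and extracts
    the standard descriptors (retention time, height, area, base width,
    asymmetry b/a, signal-to-noise, retention factor), classifies analytes
    against hit criteria, computes figures of merit (width- and
    resolution-based peak capacity, sum of resolution, normalised resolution
    product), aggregates performance over column/additive/temperature
    factors with Tukey five-number summaries, monitors internal-standard
    repeatability, and ranks screening conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
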