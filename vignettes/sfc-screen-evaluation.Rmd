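---
title: "Evaluating SFC screening conditions: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating SFC screening conditions: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcscreen)
```

## The problem

Method development for supercritical fluid chromatography (SFC) of polar
metabolites screens a large factorial space — stationary phases, modifier
additives dissolved in the methanol co-solvent, and column temperatures —
and must reduce each condition's chromatogram to a handful of comparable
quality metrics. `sfcscreen` implements that reduction as a reusable,
tested pipeline: per-peak descriptors, hit classification, figures of
merit, factor-level aggregation, repeatability monitoring and condition
ranking. Because no raw instrument data is publicly available for this
kind of screen, the package also ships a first-class synthetic-data
generator whose statistical structure matches what the evaluation assumes,
so every stage can be exercised end to end at a desk.

## Peak model

Simulated peaks are exponentially modified Gaussians (EMG): a Gaussian of
width $\sigma$ and apex height $A$ convolved with a normalised exponential
decay of time constant $\tau$. The EMG is the standard model for tailing
chromatographic peaks: $\tau = 0$ recovers the pure Gaussian, the peak
area is $A\sigma\sqrt{2\pi}$ for every $\tau$, and the asymmetry $b/a$
grows monotonically with $\tau/\sigma$ — which is what makes $\tau$ a
clean generative knob for peak-shape effects. The closed form is
evaluated through the scaled complementary error function with an
asymptotic branch for large arguments, so narrow peaks deep in a long run
do not overflow.

```{r emg}
grid <- seq(0, 300, by = 0.05)
tailing <- emg_profile(grid, tr_center = 100, sigma = 2, tau = 4,
                       amplitude = 1000)
c(apex_time = grid[which.max(tailing)], apex_height = max(tailing))
```

## Descriptor conventions

Vendor peak-processing software rarely documents its width, asymmetry or
signal-to-noise definitions, so the package fixes explicit conventions and
applies them uniformly:

* **Base width** `width_s` — tangent method: tangents through the
  leading and trailing inflection points of each flank, intersected with
  the local straight-line baseline. Each tangent is fitted by least
  squares over the flank samples between 45 % and 75 % of apex height
  (the flank is nearly linear around its inflection there), which keeps
  the slope estimate stable on broad, low peaks where the per-sample
  slope is comparable to the noise. For a Gaussian the width equals
  $4\sigma$, which gives the test suite an analytic oracle.
* **Asymmetry** `asym` — trailing over leading half-width ($b/a$)
  measured at 10 % of baseline-corrected apex height; $> 1$ means
  tailing.
* **Signal-to-noise** `snr` — apex height divided by $2\times$ the
  baseline noise standard deviation, the noise being estimated as the
  standard deviation of a linearly detrended peak-free window.
* **Retention factor** `k` — $(t_R - t_0)/t_0$ with the dead time $t_0$
  a gradient-method parameter (default 30 s; dead-time markers are
  measured per column in practice but no per-column values are modelled).
* **Local baseline** — the straight line joining the peak boundaries,
  found by walking outward from the apex to the first sample below 0.5 %
  of apex height or to the valley before a neighbouring peak. On noisy
  traces the walk tracks the running minimum and only terminates on a
  rise exceeding $5\times$ the noise sd, because broad low peaks have
  near-zero slope at the apex and sample-to-sample noise would otherwise
  stop the walk immediately. Shape measurements on noisy traces are taken
  on an 11-point cubic Savitzky–Golay smoothed copy (0.55 s at the
  default 0.05 s sampling), which is narrow relative to every simulated
  peak width.

Peak detection reports local maxima that clear a minimum height and a
minimum *topographic prominence* (height above the key saddle toward
taller terrain). Co-eluting shoulders are split only when both apexes
clear the prominence threshold; fully co-eluting peaks are not
deconvolved — that is a stated non-goal.

## Hit criteria and response classes

A peak is a *hit* when $b/a < 4$ (strict), $2 \le k \le 20$ (inclusive)
and $S/N \ge 3$ (inclusive). Boundary semantics follow the printed
inequalities exactly. Over a set of modifiers a compound is a

* **responder** — hit in every modifier;
* **sub-responder** — eluted in every modifier but violating the $k$ or
  $b/a$ limit in at least one (S/N-only failures are deliberately *not*
  sub-responders, since the class is defined by retention/shape, and are
  labelled intermediate instead);
* **non-responder** — no peak observed in any modifier;
* **intermediate** — everything else.

When several detected peaks match one analyte (e.g. both MS polarities),
the highest-S/N peak is evaluated. Classification is invariant under
modifier order, and tightening any criterion can only reduce the hit
count — both properties are asserted in the test suite.

## Figures of merit

For a gradient of length $t_g$ and $n$ peaks of base widths $w_p$:

$$P_c = 1 + \frac{t_g}{\tfrac1n\sum_1^n w_p} \qquad\text{(width-based peak capacity)}$$

$$P_c = 1 + \sum_n R_S \qquad\text{(resolution-based peak capacity)}$$

$$R_S = \frac{2\,|t_{r,1}-t_{r,2}|}{w_{p,1}+w_{p,2}} \qquad\text{(resolution of adjacent peaks)}$$

$$\bar r = \prod_n \left( R_S / \bar R_S \right) \qquad\text{(normalised resolution product)}$$

Conventions adopted where the definitions leave room:

* $R_S$ uses the magnitude of the retention difference; resolution is
  reported as a magnitude throughout.
* $\sum R_S$ and $\bar r$ run over adjacent pairs in elution order only.
  Schoenmakers' original normalised resolution product includes boundary
  terms for the chromatogram edges; no boundary terms are used here, and
  the choice is documented rather than hidden.
* A single-peak table has $\sum R_S = 0$ and an *absent* $\bar r$ (not 0,
  not 1): the product over fewer than two resolutions measures nothing.
* A zero adjacent resolution (full co-elution) makes $\bar r = 0$ with a
  warning.
* By the AM–GM inequality $\bar r \le 1$, with equality exactly when all
  adjacent resolutions are equal — asserted over thousands of random
  tables in the tests.

```{r merit}
tab <- peak_table(data.frame(
  analyte = sprintf("p%d", 1:5), tr_s = seq(100, by = 60, length.out = 5),
  area = 1, height = 1, width_s = 10))
c(sum_rs = sum_resolution(tab),
  nrp = normalized_resolution_product(tab),
  pc = peak_capacity_resolution(sum_resolution(tab)))
```

## The comparability-subset convention

Conditions differ in how many panel compounds elute, and width statistics
over different peak sets are not comparable. Width boxplots are therefore
restricted to a ten-analyte subset observed in essentially all conditions
(2-aminobutyric acid, adenine, adenosine, creatinine, cytosine, hippuric
acid, leucine, proline, uracil, xylitol — `COMPARABILITY_SUBSET`,
configurable), while $\sum R_S$ and $\bar r$ necessarily use *all*
observed peaks, because resolution is a property of the whole
chromatogram. Both the median and the mean are always reported.

Aggregation uses Tukey five-number summaries: quartiles by linear
interpolation (`stats::quantile` type 7 — the statistics tool behind the
original boxplots is unknown, so the most common convention is used and
named), whiskers at the most extreme point within $1.5\times$IQR, no
outliers drawn. One column (BEH Phenyl) produces such poor peak shapes
that it is excluded from column-level comparisons by default; the
exclusion provably does not alter any other level's statistics.

## The screen design

The full design enumerates 264 unique conditions: an initial block of
eight columns × nine additives × three temperatures (35/40/45 °C), plus a
Torus block of four columns × three MS-compatible modifiers × four
temperatures (adding 55 °C, valid only for the Torus family). The three
Torus-block modifiers default to water, ammonium formate and formic acid —
the per-co-solvent column comparisons are reported for exactly those
three, which identifies them as the modifiers carried into the later
block. Alkylamine additives (isopropylamine, isobutylamine,
isopentylamine) contaminate electrospray sources and are therefore
UV-only; the design validator rejects any attempt to pair them with MS
detection, and UV conditions observe only the UV-active analytes (7 of
the 20-compound panel).

## What the synthetic generator emulates — and what it does not

`generate_screen()` draws descriptor-level peak tables: for each
condition, each panel compound elutes with probability given by the
effect model, at a retention time shifted per additive/column with a
0.3 % RSD injection jitter (chosen to sit comfortably below the 2 %
repeatability bound the evaluation monitors; the true jitter magnitude is
not published, so this is a modelling default, not a claim), with base
width scaled by per-additive × per-column × per-temperature multipliers
under multiplicative lognormal noise (sdlog 0.10), and asymmetry scaled
similarly. The internal standard (a caffeine analogue at ~60 s) is drawn
`n >= 4` times per condition with a lognormal area whose CV is the
condition's spray-pulsing knob. Default effect sizes reproduce the
qualitative structure the evaluation must detect: ammonium salts and
water narrow peaks relative to acids, alkylamines narrow them further,
Torus Diol/2-PIC are the narrowest columns while BEH Phenyl is by far the
broadest, 55 °C narrows peaks, and ammonium-hydroxide/Diol/2-PIC
conditions carry elevated internal-standard area CVs.

The generator deliberately does **not** model retention mechanisms,
CO2–methanol thermodynamics, MS ionisation or detector saturation, and
its conditions are statistically independent given the effect model.
Passing tests therefore demonstrate that the *evaluation machinery*
recovers planted structure correctly — they say nothing about which real
column or additive is chemically superior.

Determinism is strict: every generator requires an explicit integer seed,
per-condition seeds are derived once from the master seed, and the
session RNG state is restored after every draw, so equal inputs give
byte-identical datasets.

## Ranking

The screen is ranked by an explicit lexicographic objective — default:
lower median base width, then higher $\sum R_S$, then higher $\bar r$ —
with remaining ties broken by condition id for determinism. A
lexicographic rule was chosen over a weighted score because the
underlying metrics are on incommensurable scales and practitioners weigh
them qualitatively; the objective is user-configurable.

## Problem sizes and numerical choices

The test suite and the analysis scripts run at the following sizes,
chosen so that a full check completes in well under a minute on one core:
chromatograms sampled at 0.05 s over a 441 s (7.35 min) run window;
property suites over 1000 random peak tables (AM–GM bound), 50 tables
(brute-force oracle equality) and a $\sigma \in \{1,\dots,8\}$ s grid
(tangent-width oracle); parameter recovery with planted width multipliers
$\{1.0, 1.5, 2.0\}$ at 30 peaks/condition over 100 seeds; 100 planted
classification cases; and one full 264-condition screen evaluation.
Tolerances mirror the oracles' accuracy: 5 % on tangent widths against
the $4\sigma$ analytic value (finite sampling and the discrete tangent
placement), 1 % on the EMG closed form against a discrete-convolution
oracle (rectangle-rule error), exact equality against brute-force
re-implementations of $\sum R_S$ and $\bar r$.

## Known limitations

* Absolute agreement with vendor-software descriptor values is
  unverifiable, because the vendor definitions of base width, $b/a$ and
  S/N are unpublished; all conventions here are explicit and versioned
  instead.
* Overlapping peaks closer than the prominence threshold merge; the
  descriptor extractor is not a deconvolution tool.
* The per-boxplot pooling rules of the original study (across mixtures
  and temperatures) are under-specified; pooling is therefore exposed as
  configuration (`restrict`, `exclude_levels`) rather than asserted.
* Whether hits were merged across MS polarities by best peak or by union
  is unstated; the package implements best-peak-by-S/N and keeps per-mode
  bookkeeping possible.
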