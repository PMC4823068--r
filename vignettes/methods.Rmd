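---
title: "Methods: Bliss synergy screening and profiling statistics in blisshit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bliss synergy screening and profiling statistics in blisshit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blisshit)
```

# The screen model

`blisshit` analyzes combination cytotoxicity screens of the classic
anchor-by-library design: each cell line of a panel is treated with a
"primary" (anchor) inhibitor at three sub-lethal doses, crossed against a
library of "secondary" drugs at one dose each, in replicate wells of 96-well
plates, with a resazurin-type fluorescence readout. Three modelling
assumptions run through the whole pipeline:

* **Fractional effects.** Cytotoxicity of a well is
  `C = 1 − RFU / vehicle mean`, computed per cell line and clamped to
  [0, 1]. The clamp matters: the Bliss formula below is only meaningful for
  fractional effects, and a well reading above its vehicle control (apparent
  growth stimulation) would otherwise produce a negative "kill fraction".
  The raw, unclamped value is retained in the profile (`cytotox_raw`) for
  diagnostics such as paradoxical pathway activation.
* **Bliss independence as the null.** Two drugs acting through independent
  mechanisms combine multiplicatively on survival, so the expected combined
  cytotoxicity is `1 − (1 − C_p)(1 − C_s)`. The synergy score is the
  observed combination cytotoxicity minus this prediction; it lives in
  [−1, 1], is zero under additivity, and can detect synergy even when one
  agent is inactive alone.
* **Hill-shaped single agents.** Single-agent dose–response is modelled as
  `C(d) = Emax · d^h / (d^h + IC50^h)` with `C(0) = 0` — the minimal
  monotone saturating form. The assay conflates growth inhibition and
  killing, and so does the model; no attempt is made to separate cytostatic
  from cytotoxic effects.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `percentile` | 98 | percentile of pooled scores | hit cutoff calibrated on the empirical score distribution; 98 leaves a 2% upper tail |
| `pooling` | `per_primary` | — | each anchor drug has its own score distribution; a `global` switch pools all three |
| `pool` | `statistics` | — | what the percentile is taken over (see below) |
| `fdr` | 0.01 | proportion | 1% expected false discoveries among significant features |
| `replicates` | 3 | wells | triplicate wells per condition |
| `n_vehicle` | 6 | wells/line/plate set | vehicle-control count per line |
| `noise_cv` | 0.1 | CV of RFU | multiplicative plate-reader noise |
| `bootstrap` | 1000 | iterations | branch-support resampling depth |

**Percentile over statistics, not dose-level scores.** A combination is
summarized by the *maximum* over its dose grid of the replicate-mean score
(a combination is called synergistic if any of its dose pairings is), and by
default the calibration percentile is taken over the pooled distribution of
those same combination statistics. Taking it over the dose-level scores
instead (`pool = "scores"`) is also supported, but then the realized hit
fraction exceeds the nominal tail mass — the maximum of three correlated
dose-level scores clears the dose-level 98th percentile more than 2% of the
time. With `pool = "statistics"` the threshold is self-consistent: by
construction about 2% of combinations exceed it under the null, which is
what the acceptance checks verify.

**Strictness and the nearest rank.** The threshold is the nearest-rank
percentile (the smallest observed score with at least the requested fraction
at or below it, no interpolation) — deterministic and well-defined for the
modest score counts a screen produces — and a hit must exceed it *strictly*:
a statistic exactly at the cutoff is not a hit. Small pools make percentiles
unstable, so `empirical_threshold()` refuses fewer than 50 scores; for small
designs use `pooling = "global"` and/or `pool = "scores"`.

# The synthetic-data generator

The generator exists so that every downstream stage has an oracle. It
emulates:

* Hill-shaped single-agent response with per-(line, drug) parameters whose
  IC50 spread (about 2.3 decades around drug-specific reference values)
  covers highly sensitive through near-resistant lines;
* anchor doses chosen by the analytic Hill inverse at 15/25/35% inhibition
  on the panel-reference curve, and library doses near 20% — the sub-lethal
  anchoring a synthetic-lethal screen uses;
* Bliss-additive combination cytotoxicity plus a planted additive offset
  delta on chosen (line, primary, secondary) triples, clamped to [0, 1];
* multiplicative fluorescence noise, `RFU = baseline · (1 − C) · (1 + ε)`
  with `ε ~ N(0, CV)`, truncated at a configurable 1-RFU floor; and
* six vehicle wells per line per replicate plate set (a conventional count;
  the design is not sensitive to it).

Because the offset is additive on the Bliss prediction, the planted delta
*is* the true synergy score wherever no clamping occurs, which keeps ground
truth legible. The default demo truth enforces this by construction: planted
triples are chosen deterministically among those whose Bliss-predicted
cytotoxicity stays at least `delta + 0.02` below 1 at every dose, so a
planted effect is never silently truncated. Planted interactions default to
delta = 0.35 on 2% of triples.

The generator deliberately does **not** model plate-position artifacts, edge
evaporation, serum-lot effects on synergy manifestation (documented in real
screens but without a quantitative model to emulate), or correlated noise
between wells. Passing tests therefore demonstrate correctness of the
*computations* under the stated noise model, not robustness to every
plate-level pathology of real screens.

The feature-matrix generator mirrors a paired profiling design (control and
treated sample per line, phosphosite-scale feature count of 114): entries
are `feature baseline + per-pair baseline + planted shift + N(0, sd)` on the
log2 scale. The shared per-pair baseline is what makes the paired analysis
strictly more powerful than an unpaired one, and is the only correlation
structure simulated.

# Statistical methods

**Moderated t.** Per-feature variances of paired log2 differences are shrunk
toward a pooled prior under a scaled-inverse-chi-square model. The prior
degrees of freedom `d0` and scale `s0²` are estimated by moment matching on
the log variances (the expectation and variance of `log s²` under the model
involve digamma/trigamma functions; `d0` solves
`trigamma(d0/2) = Var(log s²) − trigamma(df/2)`, inverted by bisection).
The statistic is `t = mean / sqrt(s2_post / n)` with
`s2_post = (d0·s0² + df·s²)/(d0 + df)` on `df + d0` degrees of freedom.
`prior_df` is exposed: 0 recovers the classical paired t-test exactly, `Inf`
pools all features onto one variance — both limits are pinned by tests, and
the estimated fit is cross-checked against an independent empirical-Bayes
implementation. When the moment estimate of `trigamma(d0/2)` is
non-positive, `d0 = Inf` is used (the data show no excess variance
dispersion). BH adjustment uses the standard step-up procedure.

**Rank-sum.** For combined samples of at most 12 the two-sided p-value is
computed by full enumeration of all `C(N, nA)` rank assignments (midranks
for ties): the permutation mass of rank sums at least as far from their null
mean as observed. The smallest two-sided p attainable in a 3-vs-3 contrast
is therefore 2/20 = 0.1. Larger samples use the normal approximation with
tie and continuity correction; the method used is reported.

**Clustering.** Features are clustered on `1 − Pearson r` with average
linkage (UPGMA), which is scale- and shift-invariant in each feature.
Zero-variance features make the correlation undefined and are rejected by
name rather than silently imputed. Branch stability is the plain bootstrap
proportion: resample samples (columns) with replacement, recluster, and
count the fraction of iterations in which exactly the branch's leaf set
reappears. A perturbation-calibrated (multiscale) estimator would need a
perturbation schedule we have no basis to pick; the simpler estimator is
used and labelled as such in the output. In a bootstrap replicate a feature
can lose all variance (all resampled columns identical); its undefined
correlations are treated as distance 1 for that iteration.

# Numerical choices

* Hill fits run on bounded parameters (`Emax ∈ [0, 1.05]`,
  `h ∈ [0.2, 5]`, IC50 on the log10 scale within ±3 decades of the dose
  range) via Levenberg–Marquardt least squares, initialized at the maximum
  response, the dose nearest half-max, and `h = 1`. Curves whose largest
  observed response is below 0.2 are flagged `resistant — IC50 not
  identifiable` instead of extrapolating an IC50 far beyond the tested
  range; non-convergence yields a flagged result, not an exception.
* `doses_for_inhibition()` is the exact algebraic inverse of the fitted
  curve (round-trip accurate to 1e-9 in the tests) and refuses targets at or
  above `Emax`.
* Ties in clustering are broken by `hclust`'s deterministic merge order;
  merge heights are what the oracle tests pin down, since tie order among
  equal heights is arbitrary under any convention.
* All generators route randomness through one seed stored in the truth
  object and restore the caller's RNG state afterwards, so identical
  (truth, seed) gives bit-identical outputs and runs compose
  deterministically.

# Problem sizes

The tests and the acceptance script run the full stated design — 12 lines ×
3 primaries × 3 doses × 58 secondaries in triplicate (21,420 wells, 2,088
combinations) — for the generator-inversion and null-calibration checks;
smaller 3-line and 6-line screens for per-operation tests; 50 random curves
for Hill recovery; 200 replicate null data sets of 500 features × 3 pairs
for FDR calibration; and 100 bootstrap iterations for the separable-block
support check. These sizes give the calibration checks enough resolution
(binomial 99% intervals at n ≈ 2,000) while keeping a full run in the
order of seconds.

# Limitations

* Hit calling compares each combination against a percentile of the pooled
  empirical distribution, which presumes most combinations are non-synergistic;
  a screen in which synergy is pervasive would shift its own threshold.
* The 98th-percentile/2%-tail correspondence is a calibration convention,
  not a frequentist test; the implied empirical tail mass is reported
  alongside the threshold rather than re-derived as a p-value.
* Bliss independence is the only null model implemented (no Loewe
  additivity, Chou–Talalay, or HSA); screens anchored on a different
  additivity concept need a different scorer.
* The bootstrap support estimator scores exact leaf-set recurrence; branches
  that are nearly but not exactly reproduced receive no partial credit.
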