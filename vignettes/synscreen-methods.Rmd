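---
title: "Methods: dose-response, Bliss synergy and drug-set enrichment in synscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response, Bliss synergy and drug-set enrichment in synscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synscreen)
```

synscreen analyses cell-viability drug screens in three layers:
plate-level normalization and four-parameter logistic (4PL) dose-response
fitting; anchored drug-combination synergy scoring under the Bliss
independence model; and set-enrichment analysis of differential drug
sensitivity built on empirical-Bayes moderated t-statistics. This
vignette records the models, the tunable parameters, and the design and
numerical choices behind each layer, including the ones where more than
one defensible convention exists.

## Normalization

Raw well readouts (MTT-style, arbitrary units) are converted to
fractional viability within each cell line (and plate, when a `plate`
column is present):

$$v = \frac{s - \overline{s}_{\text{neg}}}{\overline{s}_{\text{pos}} - \overline{s}_{\text{neg}}}$$

where the positive controls are DMSO-treated wells (defining 100%
viability) and the negative controls are empty wells or a cytotoxic
kill control (defining 0%). The transform is affine-invariant in the raw
signal and maps the control means to exactly 1 and 0. Values outside
[0, 1] are deliberately **retained**: clipping before least-squares
fitting would bias the plateau estimates. Clipping happens only where a
formula requires a probability (inhibition fractions entering the Bliss
model) or a bounded integrand (the AUC). Replicate wells are averaged per
dose point after normalization, keeping the standard error of the mean.

A degenerate plate (positive-control mean not above the negative-control
mean) is an error, never a silent sign flip. Whether controls are pooled
per plate or per screen is a data-preparation decision; the implementation
normalizes per group and a `plate` column opts into per-plate pooling.

## Dose-response model and derived metrics

Viability is modeled as

$$V(c) = E_\infty + \frac{E_0 - E_\infty}{1 + (c/\mathrm{EC}_{50})^{h}}$$

with `E0` the untreated baseline (fraction, ~1), `Einf` the infinite-dose
plateau, `EC50` the inflection (nM) and `h > 0` the Hill slope. Fitting is
ordinary least squares in log10-dose space.

* **Optimizer.** Bounded L-BFGS-B over
  (log10 EC50, h, E0, Einf) with bounds E0 ∈ [0.5, 1.5],
  Einf ∈ [−0.1, 1.2], h ∈ [0.1, 10] and log10 EC50 within two decades of
  the tested range — wide enough for real curves, tight enough to keep a
  6-point fit identifiable. A fixed 5 × 3 multi-start grid (five log-EC50
  starts spanning the tested range × Hill starts 0.5, 1, 3) makes the fit
  deterministic without random restarts; the lowest SSE wins, with
  numerically tied optima broken toward the smaller Hill slope, then the
  smaller EC50. The winning start is polished at high precision
  (`factr = 1`) with an analytic gradient, which recovers noise-free
  synthetic curves to ~1e-6 relative error in EC50.
* **Degenerate inputs.** Fewer than four distinct positive doses is an
  error. Perfectly flat data leave the slope unidentifiable: the fit is
  flagged, the level is reported, and the metrics fall out of the level
  alone. If no optimizer start converges, model-free fallback metrics are
  used (IC50 by log-linear interpolation between the bracketing observed
  points, AUC by trapezoid on the observed points) and the row is flagged
  `converged = FALSE`.
* **Absolute IC50.** The reported IC50 is the *absolute* one — the
  smallest dose at which the fitted curve crosses 50% of control,
  obtained by closed-form inversion — not the EC50 inflection (the two
  coincide only when E0 = 1 and Einf = 0). Curves that never reach 50%
  within the tested range are censored `">cmax"`; curves already below
  50% at the lowest dose are censored `"<cmin"`. Downstream fold changes
  substitute the censoring bound, a conservative choice that keeps ratios
  defined and understates, never overstates, improvements.
* **AUC.** The normalized mean of the clipped fitted viability over the
  tested log10-dose window, computed by trapezoid quadrature on 1,025
  evenly spaced nodes (error well below 1e-5 for realistic slopes). This
  is the GDSC-style convention: AUC ∈ [0, 1], 1 for a fully resistant
  flat curve, lower = more sensitive. Public drug-sensitivity resources do
  not all share one integration variable or normalization; the single
  GDSC-style convention is used everywhere in the package so that in-house
  and public AUCs are on one scale.
* **Z-scores and classification.** Per-compound AUC Z-scores use the
  sample standard deviation across all cell lines; constant columns yield
  zeros with a warning rather than NaN. The sensitive/insensitive call is
  strictly `viability > 0.5` at the configured top dose (default
  10,000 nM = 10 µM) and refuses to classify measurements taken at any
  other dose.

## Anchored combination synergy

Combinations are screened with one drug (the *anchor*) held at a fixed
dose while the library drug is titrated. Anchor doses are derived per cell
line by inverting the anchor's monotherapy curve at viability 0.85, 0.75
and 0.50 (IC15 / IC25 / IC50), so each line is challenged at comparable
effect levels. Three outcome metrics are computed per combination and
averaged across the anchors at which they are defined:

1. **dEmax** — fold change in maximal effect at the highest library dose,
   `Emax = clip(1 - viability, 0, 1)`, combination over monotherapy. A
   monotherapy Emax of exactly 0 with any combination effect yields an
   explicit `Inf` (maximal evidence of improvement; it satisfies any
   finite threshold), and 0/0 is defined as 1.
2. **dIC50** — `IC50_mono / IC50_combo`, so values above 1 mean the
   combination lowers the IC50. Censored IC50s enter as their bounds; two
   IC50s censored at the same bound give 1 with a flag.
3. **Average Bliss excess** — observed inhibition minus the Bliss
   independence expectation `f_a + f_b − f_a f_b`, averaged over all
   combination cells with both doses > 0. Monotherapy margins carry zero
   excess by definition and would only dilute the average, so they are
   excluded. Inhibition fractions are clipped to [0, 1] before entering
   the Bliss formula, which requires probabilities.

A combination is a **hit** when dEmax > 5 or dIC50 > 5 or average
Bliss > 0, all strict. The Bliss rule in particular is a lenient screening
rule: with ~5% viability noise on singlicate wells, the per-combination
average excess has a standard deviation of roughly 0.015 and only a small
negative clipping bias, so a sizeable minority of truly independent
combinations exceeds 0 by chance. The synthetic-screen tests measure this
null rate directly; users should treat the rule as candidate nomination,
not inference, and rely on the dose-matrix metrics for confirmation.

Two conventions deserve explicit mention:

* **dIC50 orientation** is mono/combo, so "greater than five" reads as a
  five-fold improvement by the combination — consistent with describing
  results as *n*-fold decreases in IC50.
* **Combination-curve normalization.** By default the combination series
  is fitted as measured against untreated control. Because the anchor
  alone already depresses the whole curve, this convention inflates dIC50
  even in the absence of synergy (a curve starting at 50% of control
  crosses the absolute-IC50 threshold almost immediately). The
  alternative — dividing by the anchor-alone viability so the fit isolates
  the library drug's contribution — is available via
  `score_anchored_screen(ic50_normalize = "anchor")`. The default stays
  with untreated control for comparability with monotherapy fits; the
  Emax and Bliss metrics are unaffected either way.

Full dose-matrix screens additionally report the **maximum effective
synergy**: the largest Bliss excess among cells whose observed viability
is below 50%. This filters out "synergy" at doses where the combination
still fails to kill half the cells. Hit tables from several cell lines are
intersected by `cross_entity_overlap()`; a compound left unscreened in any
line is excluded from the intersection domain rather than counted as a
miss, because absence of evidence in one line says nothing about the
others.

## Moderated t-statistics and set enrichment

Differential sensitivity (and biomarker expression) testing uses
per-feature ordinary least squares over an arbitrary design matrix,
followed by empirical-Bayes shrinkage of the residual variances: a scaled
inverse-chi-square prior with df `d0` and scale `s0²` is fitted by method
of moments on the log sample variances, and each feature's variance is
replaced by

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

with the t-statistic referred to `d + d0` degrees of freedom. With a
single feature, or when moderation is impossible, this reduces exactly to
the ordinary t-test; the test suite verifies agreement with the reference
implementation of this scheme to machine precision. Features with missing
responses are fitted on their complete cases; binary contrasts require at
least 3 observations per group (continuous designs at least p + 3 in
total) or the feature is dropped with a logged count — the minimum that
keeps the per-feature OLS well posed.

Features are ranked by descending moderated t (ties broken
lexicographically on the identifier, so rankings are reproducible), and
sets are scored with the weighted Kolmogorov–Smirnov running sum: hits
advance the sum by `|t|^p / Σ_set |t|^p`, misses retreat by
`1/(N − |set|)`; the enrichment score (ES) is the signed extremum. The
weight default `p = 1` is the classic GSEA choice (configurable); exact
ties between the positive and negative extremum resolve to the positive
one, stabilized against floating-point summation order by a 1e-12 slack.

* **Null model.** Random member sets of matching size drawn from the
  ranked universe (the set-resampling scheme of the fast GSEA
  implementations), not phenotype permutation — feasible and appropriate
  for compound sets with as few as five members. NES divides the observed
  ES by the mean magnitude of same-sign null scores; the p-value is
  `(1 + #{same-sign nulls at least as extreme}) / (1 + #{same-sign
  nulls})`, so the smallest achievable p with `n_perm` draws is roughly
  `2/n_perm`.
* **Multiple testing** is Benjamini–Hochberg across the sets of one
  analysis. Because BH multiplies the permutation floor by the number of
  sets, the collection size and `n_perm` must be matched to the target
  FDR: with 20 sets and `n_perm = 2000`, the smallest reachable adjusted
  p is ~0.02. The validation analyses use exactly such matched sizes.
* **Sign conventions.** For the pediatric-vs-adult contrast the tested
  coefficient is the pediatric indicator, so negative NES means the set's
  compounds are more effective (lower AUC) in pediatric lines. For
  biomarker analyses genes are regressed on a compound's AUC adjusted for
  tumor type; negative t means higher expression accompanies lower AUC,
  i.e. sensitivity, so sensitivity-associated gene sets carry negative
  NES. Minimum set size defaults to 5 members present in the ranking.

The mutation-stratified view (`mutation_association()`) summarizes a
compound's AUC by a binary mutation flag and tests it with a two-sided
Wilcoxon rank-sum test (exact where sample sizes permit) — a deliberately
assumption-light companion to the linear-model machinery.

## The synthetic-screen generator

Every pipeline input can be generated with known ground truth:
monotherapy screens on the 6-point log grid 0.1 nM–10 µM; combination
matrices on 10 five-fold steps from 0.03 nM; anchored library screens
(198 compounds × 3 anchors × 6 doses); sensitivity panels with group-level
AUC shifts; and expression matrices with planted gene-set associations
(`expr = −β·AUC + noise`). Ground-truth parameters, planted Bliss excesses
and association coefficients are returned alongside the data, and all
generators are deterministic in their seed without disturbing the
caller's RNG stream.

Modeling choices, fixed once on realism grounds:

* Noise is additive Gaussian on the viability fraction, default
  sigma = 0.05 (a typical CV for MTT readouts), with a configurable
  replicate count — monotherapy screens default to duplicates, combination
  and anchored-library wells to singlicate, matching how such screens are
  actually run. Raw signals are scaled by 10,000 with empty-well mean 0
  and floored at 0; empty wells carry only instrument background
  (sigma/5), since they contain no cells.
* Monotherapy truths draw EC50 log-uniformly inside the tested grid
  (1–1,000 nM), Hill slopes 0.8–2.5 and plateaus Einf ∈ [0, 0.3], so
  curves are identifiable from 6 points. Library-compound truths for
  anchored screens span EC50 10–5,000 nM and Einf ∈ [0, 0.9]: real
  libraries mix active and inactive compounds.
* Combination wells observe
  `inhibition = clip(Bliss expectation + δ + noise, 0, 1)` with a planted
  uniform excess δ for designated synergists, so average-Bliss recovery is
  analytically checkable (clipping at full inhibition attenuates the
  recovered δ toward grid corners; the tests compare against the
  closed-form truncated-normal expectation).
* The anchor-alone margin is averaged over 16 wells, because anchor-only
  reference wells recur on every plate of an anchored screen; library
  margins are singlicate like the rest of the screen.

What the generator does **not** emulate: plate-position effects, signal
heteroscedasticity, drug-specific deviations from the 4PL shape,
correlated biological replicates, batch structure across a panel, and any
real pharmacology. Passing the recovery tests therefore demonstrates that
the estimators are correct and calibrated under the stated noise model,
not that real screens meet that model.

## Validation problem sizes

The test suite validates at sizes chosen to mirror the screen designs
while keeping the full suite fast to run routinely: 200 simulated
monotherapy curves (median absolute-IC50 error under 15% and AUC error
under 3% at sigma = 0.05 in duplicate); 1,000 random curves for the
closed-form-vs-bisection IC50 oracle (1e-6 relative); 50 combination
matrices for planted-excess recovery; a 198-compound anchored screen with
8 planted synergists (at least 7 recovered, and the null rate of the
Bliss rule measured and reported); 500 random 10×10 grids against a
brute-force maximum-effective-synergy scan; 1,000 random instances against
a brute-force running-sum ES oracle; 200 null sets at n_perm = 1,000 for
type-I calibration; a 240-line panel with one pathway shifted −0.15 for
planted-NES recovery; and a 2,000-gene × 60-line expression set for
biomarker recovery at β = 1 noise-SD (a deliberately marginal effect size;
its significance after BH is seed-dependent) plus 50 null repetitions for
p-value uniformity.

## Known limitations

* The 4PL bounds assume inhibitory, roughly monotone curves normalized to
  control; strongly biphasic responses or growth stimulation beyond 150%
  of control are out of scope.
* The Bliss > 0 hit rule has a substantial null-positive rate at realistic
  noise (see above); it is a nomination filter, not a test.
* Censored-IC50 substitution by the bound makes dIC50 conservative but
  scale-dependent: fold changes against a `">cmax"` monotherapy IC50
  depend on the tested range.
* Set-resampling permutations test enrichment relative to random sets of
  the same size; they do not model inter-feature correlation, which can
  make nominal p-values optimistic for strongly co-regulated gene sets.
* The moderated-t machinery assumes exchangeable residual variances around
  one prior; it does not implement robust or trended variants.
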