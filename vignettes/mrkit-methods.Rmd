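---
title: "Methods: two-sample MR with mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The inferential problem

Two-sample Mendelian randomization treats genetic variants as
instruments for an exposure: if a variant's only path to the outcome
runs through the exposure, the ratio of its outcome association to its
exposure association estimates the causal effect. `mrkit` implements
this for binary exposures and outcomes summarised at the per-SNP level
(effect on the log-odds scale, standard error, p-value, allele pair,
frequency, sample sizes), with the three instrument assumptions —
relevance, independence from confounders, and exclusion restriction —
addressed respectively by instrument-strength screening, the
multivariable models, and the pleiotropy/outlier battery.

## Data model and harmonization

`GwasTable` holds one trait's records; validity enforces unique SNP ids,
positive SEs, p-values in (0, 1], A/C/G/T allele pairs with distinct
alleles, and frequencies strictly inside (0, 1) when present. Genomic
coordinates are 1-based, carried for the clumping window only; matching
is always by SNP id.

`harmonize()` intersects exposure and outcome tables and re-expresses
each outcome effect relative to the exposure's effect allele. Allele
codes are compared as given and after reverse complementation, so a
strand flip alone never drops a variant; swapped alleles negate the
outcome beta and complement its frequency. Palindromic variants (A/T,
C/G) are ambiguous across strand conventions; the default policy drops
them all, mirroring standard conservative practice when no proxy lookup
is available. An optional `infer_by_eaf` policy keeps a palindrome when
both datasets' frequencies fall outside the 0.42–0.58 window — that
window is a community convention, not an identity, which is why it is
not the default. Every SNP in the intersection receives exactly one
audit action; the audit partitions the intersection, harmonization is
idempotent, and flipping both alleles with a negated beta in the input
reproduces the identical result (all property-tested).

## Instrument selection

`selectInstruments()` applies, in order: exposure significance
(p < 5e-8), greedy LD clumping (accept in ascending p-value order, ties
broken lexicographically by id so the result is independent of row
order; reject a candidate whose r² with any accepted SNP within the
5000 kb window reaches 0.01), and exclusion of SNPs associated with the
outcome at 5e-8 (likely direct outcome loci). Variance explained uses
the binary-trait approximation r² = 2p(1−p)β² on the log-odds scale —
the paper trail for binary exposures rarely states a variant, and this
is the common choice; the method label is recorded in the thresholds of
every `InstrumentSet`. The overall F statistic,
F = (R²/k) / ((1−R²)/(n−k−1)) with R² the summed per-SNP contribution
and n the exposure sample size, gates validity at F > 10; the printed
formula contains k, which indicates a multi-instrument F, so the gate
is on the overall value while per-SNP F values (k = 1) are reported
alongside for inspection.

The LD matrix is an explicit input (readable from a TSV with an id
header); the bundled simulator emits its true matrix, so no external
reference panel is required anywhere.

## Univariable estimators

All ratio-based methods consume a `HarmonizedSet`. First-order ratio
weights are \(w_j = \beta_{Xj}^2/\sigma_{Yj}^2\) throughout.

- **IVW**: origin regression with weights \(1/\sigma_{Yj}^2\);
  fixed-effect SE \(1/\sqrt{\sum w_j \beta_{Xj}^2\,/\,\beta_{Xj}^2}\)
  from the weighted LS formula, and by default a multiplicative
  random-effects SE multiplying it by \(\sqrt{\max(1, Q/(k-1))}\). The
  floor at 1 means heterogeneity can only widen intervals, never narrow
  them; the analytic cost is a mildly conservative test (size ≈ 4.2%
  rather than 5% under a clean null with k = 30), which we judged the
  right trade for reported analyses.
- **MR-Egger**: intercept regression after orienting rows so exposure
  effects are non-negative (the frame in which the intercept, the mean
  directional pleiotropic effect, is identified). SEs use the weighted
  LS covariance scaled by \(\max(1, \hat\sigma)\) (same floor logic);
  a plain-dispersion variant and a t(k−2) reference are available by
  argument — the plain + t combination is exact under the null and is
  what the calibration tests exercise.
- **Weighted median**: ratios sorted, cumulative standardised weights
  \((\sum_{i\le j} w_i - w_j/2)/\sum w\), linear interpolation at 0.5.
  SE by parametric bootstrap (default 1000 draws, mandatory seed):
  per-SNP betas resampled from their sampling distributions.
- **Modes**: normal-kernel density of the ratios, bandwidth
  φ × 0.9·min(sd, mad)·k^(−1/5) (φ = 1 default; the modified Silverman
  rule with the MAD guards against outlier-inflated bandwidths),
  unweighted (simple) or 1/se²-weighted; estimate is the density argmax,
  SE by the same bootstrap. Mode estimators are implemented for
  completeness but excluded from the default report set, which is
  {IVW, MR-Egger, WeightedMedian} — the methods a reader of standard MR
  result grids expects.

Degenerate inputs are first-class: identical ratios give Q = 0 and
coinciding fixed/random SEs; a zero exposure beta is an explicit
undefined-ratio error; estimator minimums (2 for IVW, 3 for the rest)
raise insufficient-instrument errors.

A practical caveat verified in simulation: with instrument effects
spread over a narrow magnitude range, MR-Egger's slope suffers
regression dilution from exposure measurement error (no-measurement-
error assumption), attenuating it toward zero even without pleiotropy.
This is a property of the method, not a defect of the fit, and is why
IVW remains the primary estimator in the default report.

## Multivariable MR

`buildMvmrSet()` forms the union of each exposure's genome-wide-
significant SNPs, clumps the union in one greedy pass ranked by the
best p-value across exposures (union rather than intersection: the
standard choice that keeps instruments specific to each exposure, and
deterministic given the tie rule; the audit trail records the decision),
aligns all tables to a common effect allele per SNP, drops palindromes,
and requires complete exposure effects. `mvmrIVW()` solves the weighted
normal equations without intercept; `mvmrEgger()` adds one after
sign-fixing rows on the first exposure. SEs apply the same
multiplicative random-effects floor with df = k − m (− 1 with
intercept); residual Cochran's Q is reported, as are per-exposure
conditional instrument-strength statistics (each exposure's effects
regressed on the others', residual heterogeneity scaled by k − m + 1) —
reported, not gated on. With a single exposure both reduce numerically
to their univariable counterparts (tested to 1e−12). An exactly
collinear design — including an all-zero exposure column — is an
explicit error naming the columns.

## Sensitivity battery

- **Cochran's Q** under an IVW (df k−1) or Egger (df k−2) reference,
  with per-SNP contributions that sum to Q.
- **MR-PRESSO**: observed residual sum of squares from leave-one-out
  IVW predictions (residuals standardised by outcome SE), compared to
  its null distribution over `nSim` parametric simulations of both
  exposure and outcome betas; per-SNP outlier p-values from the
  analogous per-observation comparison, Bonferroni-corrected by k;
  distortion test against random same-size removals. Default
  nSim = 5000 with a mandatory seed; results are bit-reproducible.
- **Radial MR**: slope \(\sum w_j\hat\theta_j/\sum w_j\) with modified
  second-order weights
  \(w_j = (\sigma_{Yj}^2/\beta_{Xj}^2 + \hat\beta^2\sigma_{Xj}^2/\beta_{Xj}^2)^{-1}\)
  iterated to 1e−8 on the slope (max 100 passes, non-convergence is an
  error reporting the last iterate). Per-SNP contributions are
  chi-square(1) under homogeneity; flags use the Bonferroni-adjusted
  level α/k — without the adjustment, a 30-instrument analysis would
  flag a clean SNP in most runs.
- **Leave-one-out**: k IVW refits; a run is flagged when the full-set
  estimate is significant but the left-out CI no longer supports an
  effect of the same sign — the conclusion hinges on that SNP.
- **Steiger**: instrument variance explained on each side via the same
  2p(1−p)β² rule applied symmetrically (the approximation is stated in
  the output rather than hidden); Fisher-z comparison of the implied
  correlations from the two independent samples. The verdict requires
  both ordering and significance.
- **Power**: closed form Φ(√NCP − z) + Φ(−√NCP − z) with
  NCP = n·r²·K(1−K)·β², the binary-outcome approximation used by the
  standard online calculator; it returns exactly α at β = 0.

## Meta-analysis

Log-odds ratios pooled with inverse-variance weights; random effects
add τ² to every variance. τ² defaults to REML (profiled restricted
likelihood maximised directly over τ² ≥ 0), with the DerSimonian–Laird
moment estimator max(0, (Q−df)/C), C = Σw − Σw²/Σw, available as
`random_DL`. REML is the default because it is the modern default of
the standard meta-analysis tooling for log-OR inputs and, unlike DL, is
not perturbed by the τ² > 0 artifacts that rounding published ORs to
two decimals induces: on the four-stage example in the README, REML
gives τ² = 0 and reproduces the published pooled OR 1.11 [1.08, 1.15]
exactly at two decimals, while DL on the same rounded inputs gives
1.12 [1.08, 1.16]. CI-to-SE conversion assumes symmetric normal 95%
intervals on the log scale, which is how such tables are constructed.
Subgroup pooling (per exposure, across outcome stages) reuses the same
machinery; forest output is a plain data file of rows and diamonds so
results stay diffable and testable.

## The simulator: what it emulates and what it does not

`simulateTwoSample()` generates summary statistics directly at the
summary level: per-block true instrument effects (random sign,
magnitudes normal around a mean set so the block's expected Σ2p(1−p)β²
hits a target), propagation along declared acyclic trait edges, outcome
effects as causal effect × true exposure effect plus structural and
pleiotropic terms, and observed betas with
se = 1/√(2p(1−p)·n·K(1−K)) — the case-control (logistic variance
factor) approximation with K the case fraction. Exposure and outcome
samples are strictly independent, matching the two-sample assumption.
Scenario defaults mirror a national-registry study of thyroid and
retinal endpoints: case counts 8 173 / 40 926 / 2 836 / 12 555 for the
four exposure-side traits and 10 413 / 3 098 / 672 / 9 511 for the
outcome stages, with cohort totals of 270 000 (exposures) and
190 000–210 000 (outcomes) chosen as registry-scale round numbers, and
instrument-block sizes 30 / 160 / 15 / 40. Per-block variance targets
(0.4 / 0.8 / 0.5 / 0.6) were set so that, after the full selection
chain, retained counts land near the 27–37 / 144–179 / 11–17 ranges a
study of this design reports; a few low-frequency or weak-tail
instruments failing genome-wide significance is expected and realistic.

Directional pleiotropy is applied in the exposure-increasing allele
orientation: a direct outcome effect that is constant in a fixed allele
frame cancels across randomly signed instruments and biases nothing,
whereas real directional pleiotropy shifts the ratio distribution. The
breakdown scenario (`directional_pleiotropy`) uses a large balanced
case-control design with near-equal frequencies (U(0.45, 0.55)) and
near-equal effect magnitudes (cv 0.05): homogeneous weights ensure the
invalid 48% of instruments never outweighs the valid half, which is the
condition under which the weighted median's breakdown bound is visible
at finite sample sizes. The mediation scenario uses upstream→downstream
0.4, upstream→outcome 0.25, downstream→outcome 0, with a strengthened
upstream block (target 1.0) so the exposure columns are well measured
and the downstream direct effect is cleanly identified.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: LD affects clumping only (observed
betas of correlated SNPs are drawn independently rather than with
LD-induced correlation); allele frequencies are identical across
cohorts; there is no sample overlap (registry exposures and outcomes in
practice share participants — an optional overlap knob is deliberately
left out of the tested surface); no population stratification,
winner's-curse re-use of discovery data, or liability-scale
non-collapsibility effects. Estimator guarantees shown here are
guarantees about the summary-statistic model, not about any particular
consortium's data.

## Pipeline decision rules

`runStudy()` executes the grid with the study's decision rules:
significance judged at the Bonferroni-adjusted threshold 0.05/n_tests
with n_tests defaulting to 2 (threshold 0.025, the operative value in
the motivating analysis; exposed as configuration because the "number
of MR tests" is a judgement call), MR-PRESSO and radial outliers
removed before final estimation by default (recorded per pair in the
log), per-pair seeds derived deterministically from the study seed, and
partial-failure tolerance: a failing exposure–outcome pair is recorded
and the rest of the grid completes, with status 2 signalling partial
failure. Reports carry a manifest (seeds, thresholds, package version)
sufficient to recompute every number; two runs with the same
configuration are identical.

## Problem sizes used by the tests

The calibration suite runs 1000 null replicates (size of IVW at the
fixed-effect reference, Kolmogorov–Smirnov uniformity of Q p-values,
Egger-intercept size with the exact plain-dispersion/t variant), 500
recovery replicates (IVW bias and coverage; weighted-median vs IVW
under 48% invalid instruments), 200 mediation replicates and 200
spike-in replicates (MR-PRESSO at nSim = 1000), sizes at which the
whole suite completes in well under a minute of simulation time while
leaving Monte-Carlo error comfortably inside the asserted bands.

## Known limitations

MVMR direct-effect intervals run slightly below nominal coverage
(≈93% at the mediation scenario's scale) because exposure measurement
error both leaks a little of the upstream effect into the downstream
column and is not reflected in the outcome-side weights; the
multiplicative heterogeneity floor absorbs most but not all of it.
MR-Egger attenuates under narrow instrument-strength spread (see
above). The REML τ² uses direct likelihood maximisation and can differ
from other implementations in the 5th decimal. None of these affect the
qualitative conclusions any scenario in this package is designed to
demonstrate.
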