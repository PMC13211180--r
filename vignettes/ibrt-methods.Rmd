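---
title: "Methods behind ibrtox: the IBR-T index and its companion pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ibrtox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrtox)
```

## Scope and data model

`ibrtox` analyses multi-tissue biomarker panels from dose-by-time
exposure designs. The canonical on-disk representation is a long
(tidy) table — one measurement per row, keyed by
(tissue, treatment, day, biomarker, subject) — because every stage of
the pipeline groups by a different subset of those keys; wide
matrices are derived views. Units are fixed per biomarker
(SOD: U mg⁻¹ protein; GPx: nmol (mg·min)⁻¹; GST: nmol (µg·min)⁻¹;
MDA: µmol mg⁻¹ protein) and validated on input. A cell observed once
carries an *undefined* standard deviation (`NA`), never 0, so
degenerate cells fail loudly downstream instead of silently shrinking
variance.

## The IBR-T index

For each (tissue, day) stratum and biomarker $b$ the control sample
defines a reference $R_b$ (median) and induction threshold $T_b$
(95th percentile). Both use linear interpolation on order statistics
at position $h = (n-1)p + 1$ (R's type-7 quantile), so a control
sample of 1..20 gives $R_b = 10.5$, $T_b = 19.05$. For each treatment
$t$ with group mean $m_{t,b} > 0$:

$$L_{t,b} = \ln\frac{m_{t,b}}{R_b}, \qquad
  z_{t,b} = \frac{L_{t,b}}{\mathrm{sd}_t(L_{\cdot,b})}, \qquad
  \mathrm{IBR\text{-}T}_t = \underset{b:\, m_{t,b} > T_b}{\mathrm{mean}} |z_{t,b}|$$

with score 0 when no biomarker is induced. Design choices made where
the construction was genuinely open:

- **Log base.** Natural log. Any base cancels in $z$ after the SD
  division, so the choice is observationally neutral; it is recorded
  here rather than guessed silently.
- **SD "across treatments".** The sample SD ($n-1$) of the four
  treatment log-ratios within one (tissue, day, biomarker) — the only
  reading under which per-day, per-tissue scores are computable from
  group means alone. If all log-ratios coincide the SD is 0 and every
  $z$ is set to 0 by convention.
- **Induction is one-sided.** Only upward exceedance
  ($m_{t,b} > T_b$, strict) counts; suppressed biomarkers are not
  "induced". A symmetric option (`two_sided = TRUE`, adding the 5th
  percentile as a lower gate) exists but is off by default.
- **Per-day strata.** Reference and threshold come from the same
  day's control, because scores are reported per tissue and day;
  `pool_days = TRUE` pools the controls across days instead.
- **Empty inclusion sets score 0**, not `NA`, so every treatment —
  including the control, whose mean rarely exceeds its own 95th
  percentile — carries a plottable value.

These conventions are locked by tests: an independent straight-line
re-derivation (explicit loops, hand-written order-statistic
interpolation) must agree with `compute_ibrt()` to $10^{-12}$ on
randomized tables, and the index must be exactly invariant to
rescaling any single biomarker.

## Rank tests

`kruskal_wallis()` uses pooled midranks and the tie-corrected
statistic $H' = H / (1 - \sum(t^3 - t)/(N^3 - N))$ referred to
$\chi^2_{k-1}$. The chi-square approximation is used at all sample
sizes (the study design has $n \approx 7$ per group, where it is
standard practice); for $N \le 10$ an exhaustive-enumeration
permutation p-value is available (`p_method = "exact"`) and is
checked against Monte-Carlo resampling. All-tied data returns
$H = 0$, $p = 1$. `dunn_posthoc()` standardizes mean-rank differences
with the tie-corrected variance
$N(N+1)/12 - \sum(t^3-t)/(12(N-1))$ and reports two-sided normal
p-values. The default multiplicity adjustment is **none** — the most
literal reading of a Dunn follow-up — with Holm and Bonferroni
switchable; the choice is recorded in the output. Stars follow the
strict bands \*\*\* $p<0.001$, \*\* $p<0.01$, \* $p<0.05$.

## Ordination

The ordination chain is impute → z-score → Euclidean distances →
NMDS.

- **Imputation** (`impute_missing()`) is iterative low-rank EM-PCA:
  initialize missing cells with column means, alternate a
  rank-$k$ SVD reconstruction of the column-centered matrix with
  reimposition of observed cells, and stop when the largest change in
  an imputed cell drops below `tol` (default $10^{-6}$; default rank
  2). A masked cell of an exactly rank-1 matrix is recovered to
  $10^{-8}$, and under 10% MCAR masking of rank-2-plus-noise data the
  imputed cells land closer to the underlying signal than one noise
  SD — the sense in which imputation denoises. The rank and tolerance
  the motivating analyses used are not knowable, so they are exposed
  as arguments and echoed in results metadata.
- **Z-scoring** uses the mean and $n-1$ SD of each column's observed
  entries; constant columns map to zeros with a warning.
- **NMDS** (`nmds()`) minimizes Kruskal stress-1,
  $\sqrt{\sum(\hat d - d)^2 / \sum d^2}$, with monotone regression
  under primary tie treatment — the de facto standard behind the
  "stress < 0.2 acceptable" rule (`classify_stress()`, strict at
  0.2). The optimizer is `vegan::monoMDS` (global nonmetric model);
  `ibrtox` contributes the start policy: one deterministic
  principal-coordinates start plus seeded random starts
  (default 100 in total), each start's stream derived from
  (seed, start index) so the start sequence is nested — raising
  `n_starts` can only add candidates, never change existing ones.
  The best configuration is centered and rotated to principal axes;
  the PCoA start's own stress (evaluated with a 0-iteration fit) is
  reported so the contract "optimization never worsens the best
  start" is checkable. Convergence: relative stress improvement below
  `tol` ($10^{-7}$) or 300 inner iterations — unspecified upstream,
  fixed here to make the contract testable.

## Factorial model

`assemble_model_data()` stacks the enzyme panel (Matrix = tissue) and
viability (Matrix = compartment, Biomarker = `"viability"`, Neutral
Red and Trypan Blue pooled on the common percent scale) and z-scores
the response within each measured variable. Folding viability in as
one extra Biomarker level is what makes the factor structure match
the reported shape (Biomarker on 5 levels, Matrix on 4 including
hemolymph). `type3_anova()` then tests each term marginally: refit
with the term's columns deleted, all other terms retained,
$SS_T = RSS_{reduced} - RSS_{full}$,
$F = (SS_T/df_T)/(RSS_{full}/df_{res})$.

Two numerical commitments matter here:

- **Sum-to-zero contrasts are mandatory.** Type III sums of squares
  are contrast-dependent; requesting treatment coding is an error,
  not a warning.
- **Interaction columns are elementwise products** of the factors'
  contrast columns, so a term over factors with $l_1, \dots, l_m$
  levels always spans $\prod (l_j - 1)$ columns — including the
  three-way Treatment:Day:Biomarker term (12 columns for 4×2×5
  levels) even though the Day:Biomarker margin is deliberately absent
  from the default model. (R's `model.matrix` would instead promote
  the coding and spend 16 columns.) Only the stated interactions are
  included by default; `ibrt_model_formula(full_factorial = TRUE)`
  adds the rest.

On balanced designs the Type III sums of squares provably equal the
sequential (Type I) ones, and on unbalanced data the implementation
is cross-checked in the test suite against `car::Anova(type = 3)`
under identical coding — `car` serves as an independent oracle, never
as the implementation.

## The synthetic-study generator

Because per-animal measurements from the motivating study are not
published, the pipeline is exercised on a seeded generator that
emulates the design's statistical structure:

$$\text{value} = \text{baseline} \times
  \exp\big(\text{slope} \cdot g(\text{day}) \cdot \log(1+\text{dose})
  + \varepsilon\big), \quad \varepsilon \sim N(0, \sigma),\;
  \sigma = \sqrt{\ln(1 + cv^2)}$$

so values are lognormal (positive, right-skewed — the reason the
group tests are nonparametric), the baseline is the control geometric
mean, and dose enters through $\log(1+\text{dose})$ so the control
(dose 0) carries exactly zero effect. Defaults, chosen once as
realistic for a chronic sublethal exposure: 4 treatments at 0, 0.5, 5
and 25 mg L⁻¹; days 10 and 20; `n_per_cell = 7` (a conservative
even split of 15 animals per treatment over the two sampling days,
which the design leaves unstated); $cv = 0.25$; strong dose slopes
for SOD and MDA (0.20–0.25 per unit log-dose), moderate for GST
(0.04–0.10), weak for GPx (0.03); `day_gain = 1.25` amplifying
effects at day 20. Viability is truncated-normal on [0, 100] with
hemolymph controls above 99% and a dose- and time-dependent
hepatopancreatic decline whose affected-cell moments follow the
magnitudes reported for this kind of exposure.

Two structural choices:

- **Per-cell RNG substreams.** Each design cell hashes
  (seed, cell key) into its own stream, so adding or removing cells
  never perturbs the draws of the cells that remain, and identical
  seeds give byte-identical tables.
- **Independent noise across treatments.** Groups are different
  animals, so treatment cells draw independent noise — required for
  the rank-test and ANOVA calibration checks to be meaningful.
  Consequently exact dose monotonicity holds for the generative cell
  means, not for every noisy realization; `noise = FALSE` switches to
  the noise-free mode (every value equals its generative mean), which
  is what the monotonicity and dose-ordering properties are tested
  on.

What the generator does **not** emulate: between-animal correlation
across tissues (beyond shared labels), sex effects, mortality or
molting, water-chemistry covariates, and any heavier-tailed or
zero-inflated error structure real assays can produce. Passing tests
therefore demonstrate that the *pipeline computes its statistics
correctly under the stated model*, not that real data satisfy that
model.

## Problem sizes and calibration checks

The test suite runs at sizes chosen to finish in minutes on one CPU
while keeping the Monte-Carlo error small relative to each
acceptance band: 100 randomized tables for the IBR-T oracle
equivalence; 10,000 simulations of 4 lognormal groups of 7 for the
Kruskal–Wallis type-I error (empirical rate required in
[0.04, 0.06]); 20,000 resamples against the exhaustive permutation
distribution at $N = 9$; 5,000 null simulations for Type III p-value
uniformity (Kolmogorov–Smirnov distance < 0.02 — p-values are exactly
uniform here, so the bound is pure sampling noise); 60 replicates of
the full default study for power (> 0.9 against the generator's
configured Treatment effect); NMDS with 100 starts on 50 planar
points for the exact-embedding limit.

## Known limitations

- IBR-T scores depend on group *means*; with $n = 7$ per cell a
  single extreme animal moves the score noticeably. The index has no
  built-in uncertainty measure; seeded replication of the generator
  is the honest way to see its sampling spread.
- The 95th-percentile threshold from small control groups (7 values)
  is effectively the control maximum's neighbourhood, making
  inclusion conservative at small $n$.
- The chi-square reference for Kruskal–Wallis is approximate below
  $N \approx 15$; the exact enumeration is available there.
- The factorial model treats animals as independent rows; repeated
  measures across tissues of the same animal are not modelled (no
  random effects).
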