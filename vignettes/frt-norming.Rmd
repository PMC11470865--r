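---
title: "Methods: normative modelling and Equivalent Scores for the False Recognition Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative modelling and Equivalent Scores for the False Recognition Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frtnorms)
```

This vignette is the package's own account of the science it implements:
the scoring rules, the demographic-adjustment model, the nonparametric
Equivalent-Score construction, the correction grids, and the synthetic
cohort that stands in for the original normative sample. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The test and its scores

The FRT is a DRM-paradigm instrument: three word lists (positive, neutral,
negative valence), each semantically converging on a non-presented
critical lure. Each list is encoded, freely recalled, and probed with a
12-item recognition list of 6 studied words, the lure, 2 strong semantic
associates and 3 unrelated words. Words are not modelled here — items are
abstract slots tagged `OLD` / `LURE` / `SEMANTIC_ASSOCIATE` / `UNRELATED`
— so scoring is list-content-agnostic.

Two scoring conventions deserve comment because the printed score ranges
alone do not pin them down:

* **Recognition counts hits *and* correct rejections** (0–36 over
  3 × 12 items). This reading is forced by the arithmetic identity of the
  published marginal means, 29.35 + 2.15 + 4.50 = 36.00, i.e.
  `recognition + failed_recognition + total_fm = 36`, which the scorer
  enforces and the test suite asserts on every random sheet.
* **Semantic false memory pools the lure with the two associates**
  (3 × 3 = 9 items), forced by its printed 0–9 range. No lure-only
  subscore exists. Free-recall intrusions are representable in the sheet
  format but enter no subscore, since no intrusion score is defined.

## 2. Demographic adjustment

Raw scores are adjusted by centered linear models on transformed
covariates:

* age enters as $t_a = \log_{10}(100 - \text{age})$, centering constant
  1.69 — strictly decreasing on the normative range 18–99, linearising
  the accelerating decline at older ages; undefined at age $\ge$ 100;
* education (years of schooling) enters as $t_e = \sqrt{e}$, centering
  3.54 (raw years are used only when screening failed recognition, whose
  final model retains no education term anyway);
* sex enters as a centered male indicator, M = 0.58 / F = −0.42.

The uniform adjustment rule is
$\text{adjusted} = \text{raw} - \sum_j B_j (x_j - c_j)$ with the signed
published coefficients (free recall age 10.23, education 2.317;
recognition 6.771, 0.693; failed recognition −3.099 age, 0.601 sex;
semantic FM −3.553 age; non-semantic FM −1.19, −0.261; total FM −3.837,
−0.698). Positive $B$ (higher-better scales) means the demographic terms
are subtracted; negative $B$ (higher-worse scales) means they are added —
reproducing all six published formulas verbatim. At the centering
covariates the adjustment is the identity, which the acceptance suite
checks exactly.

Numerical choices: adjusted scores are kept at full precision (rounding
to 2 decimals is presentation only) and are *not* clamped to the raw
score range — Equivalent-Score bands, not ranges, interpret them. The
centering constants are used exactly as printed rather than recomputed,
for bit-compatibility with the published formulas; the synthetic cohort's
means of $t_a$ and $\sqrt{e}$ land within 0.02 of them (asserted as a
soft check), and the 0.42 male share implied by the sex codes matches the
98/134 male/female split of the decoded demographic table.

`fit_normative_model()` re-estimates these models by OLS with
threshold-based selection (drop predictors with $p \ge 0.05$ in the
multiple model and refit — not stepwise AIC, matching the published
"ns" pattern). Its centering constants are cohort means of the
transformed covariates, so fitted adjustments are the identity at the
cohort centroid; the tests verify the estimates against an explicit
normal-equations solve and verify that adjusted scores are uncorrelated
with the retained covariates.

## 3. Tolerance limits, Equivalent Scores, cut-offs

With $X \sim \mathrm{Binomial}(n, 1 - \text{coverage})$:

* outer rank = largest $r \ge 1$ with $P(X \le r-1) \le 1-\text{confidence}$,
* inner rank = smallest $r$ with $P(X \ge r) \le 1-\text{confidence}$,

both counted from the worst score. At the 95/95 defaults and $n = 232$
these are ranks 6 and 18; the smallest usable sample is $n = 59$
($0.95^{59} \approx 0.0485$), below which the package returns an explicit
"no valid limit" result rather than an exception. The implementation uses
`pbinom`; the suite checks it against direct term-by-term binomial
summation for every $n$ in 60–500.

Equivalent Scores band the adjusted scores after orienting them so larger
= better (negation for higher-worse scales): ES 0 at/below the outer
limit (abnormal; the cut-off is this limit, with direction ≤ or ≥ by
orientation), ES 1 up to the inner limit, ES 4 above the sample median,
and ES 2/3 splitting the observations strictly between inner limit and
median into two equal-count halves. Since the nonparametric procedure
ranks observations, "area" is interpreted as observation mass; with an
odd count the boundary observation goes to the *lower* band, consistent
with the tie rule everywhere ("equal to a boundary falls in the worse
band", matching "equal or lower than the outer tolerance limit" for
ES 0). Degenerate samples (zero spread) are rejected.

Semantic and non-semantic false memory need no formula correction in the
published norms; they receive **stratified raw cut-offs** instead
(semantic: age < 60 / ≥ 60; non-semantic: age < 60, 60–79 split at 5
years of education, ≥ 80), each stratum's cut-off being its outer
tolerance limit. A consequence the package surfaces honestly: at
$n = 232$, the 60–79 and 80+ strata contain fewer than 59 subjects, so no
95/95 outer limit exists for them and the package reports `n/a (small
stratum)` rather than fabricating a value; how the originally printed
cut-offs for those strata were obtained is not reconstructable from the
published material.

## 4. Correction grids

Grids tabulate the additive correction (`adjusted = raw + correction`) at
one representative demographic point per age band × education band (× sex
for failed recognition, which has no education dimension; semantic and
non-semantic FM get no grid). The representative values are band
midpoints — ages 24, 34.5, 44.5, 54.5, 64.5, 74.5, 85; education 3, 7,
11, 16.5. The values behind the originally printed grid are unstated, so
printed cells are *not* reproduced digit-for-digit (a stated non-goal);
the grid builder is instead validated against its own formula oracle to
1e-9 and against the printed grid's qualitative sign/ordering pattern
(corrections increase with age and decrease with education for
higher-better scales, reversed otherwise).

Cells whose age × education combination is empty in the normative
demographic table are flagged `extrapolated`, mirroring the original
grid's asterisks; "extrapolation formula" is interpreted as direct
evaluation of the (global) regression equation. `adjust_via_grid()` falls
back to the exact formula for demographics outside every band and reports
which route was used; within the covariate domain the fallback always
exists, while true domain violations (age 17, age 100) error.

Grids produced from *fitted* models may retain a sex term for scales
whose published model has none (recognition inherits one through the
structural identity below); age × education grids then show the
sex-averaged correction, which is exact at the centered sex code.

## 5. The synthetic normative cohort

The generator's defaults are the published conditions, not free dials:

* **Demographics** reproduce the decoded education × age × sex cell
  counts of the normative table (n = 232; 134 F / 98 M — the running text
  says 99 males, the table's cells sum to 98; the table wins for the
  generator and the discrepancy is recorded, not resolved). Age is
  uniform within its decade band (80+ capped at the sample maximum, 91).
  Education within band is drawn from weights concentrated on the Italian
  terminal attainments (5, 8, 13, 18 years), chosen once so the cohort
  mean education (~12.9) and mean $\sqrt{e}$ (~3.53) match the published
  descriptives; a uniform-within-band scheme would underestimate both.
* **Scores**: the four directly generated scales (free recall, failed
  recognition, semantic FM, non-semantic FM) follow
  $\text{intercept} + \sum_j B_j (x_j - c_j) + \lambda_a g_a +
  \lambda_b g_b + \varepsilon$, with published coefficients and
  intercepts at the published means. The two standard-normal latent
  factors are a *general memory ability* ($g_a$: raises free recall,
  lowers misses and false memories) and a *liberal response bias*
  ($g_b$: lowers misses while raising false alarms) — the bias factor is
  what lets misses and false memories be nearly uncorrelated in the
  presence of a shared ability factor, as the published correlation block
  shows. Loadings, residual sds and the non-semantic offset were
  calibrated **once** (`scratch/calibrate.R`, Nelder–Mead on simulated
  moments) against the published marginal SDs and within-test
  correlations, then frozen as package defaults.
* **Structural identities** are generated, not fitted:
  `total_fm = semantic_fm + non_semantic_fm` and
  `recognition = 36 − failed_recognition − total_fm`, then (if
  discretizing) scores are rounded, clamped to their printed ranges and
  the identity scales re-derived so the invariants hold exactly.

**Known fidelity limits** (what a green test does and does not
establish):

* Non-semantic FM is strongly zero-inflated (mean 0.26, SD 0.68, median
  0). A rounded-clamped Gaussian centered at the mean cannot match both
  moments, so the discretized path applies a calibrated negative latent
  offset before rounding; the config intercept remains the published mean
  and is used directly on the continuous path. OLS on the *discretized*
  non-semantic scale is therefore attenuated by censoring; the
  parameter-recovery properties are asserted on continuous
  (`discretize = FALSE`) cohorts, where recovery is clean for all six
  scales.
* The published per-scale regressions are not mutually consistent with
  the structural identities (the recognition coefficients implied by
  failed recognition + total FM are age 7.842 / sex −0.601 / education
  0.261, not the printed 6.771 / ns / 0.693). The generator gives the
  identities priority — they are hard invariants of the instrument — so
  recovery tests for recognition and total FM target the *implied*
  structural coefficients.
* Item-level response sheets are simulated only with independent
  per-class endorsement probabilities (for pipeline testing); no claim of
  word-level semantic realism is made.
* The generator emulates one region's community sample; nothing about
  regional, clinical or floor/ceiling behaviour of real patients follows
  from green tests.

## 6. Design decisions that were genuinely open

* **Inner/outer rank convention**: outer = more extreme (6th worst at
  n = 232), inner = 18th worst; the binomial construction above
  reproduces both and is adopted as the general rule for all n.
* **Sex-centered identity**: the centered sex code never equals 0 for an
  individual, so the "adjustment is the identity at centering" property
  for failed recognition is asserted through linearity — the
  0.42/0.58-weighted mean of the male and female adjustments equals the
  raw score exactly.
* **Determinism over timestamps**: artifacts (model JSON, norms JSON,
  grids, reports) carry schema versions but no timestamps, so identical
  inputs and seeds give byte-identical files; run metadata goes to
  stderr.
* **Seeding**: demographics consume the seed, scores consume seed + 1,
  so the two stages are independently reproducible.
* **Printed fit statistics** (R, R², F, p) are stored verbatim as
  reference metadata and never used in computation; the printed F for
  recognition (7.385) is arithmetically incompatible with its printed
  R² = 0.376 at n = 232 and is carried as-is.

## 7. Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `coverage` | 0.95 | population fraction | the "lowest 5%" abnormality convention |
| `confidence` | 0.95 | probability | standard one-sided tolerance-limit confidence |
| `alpha` (selection) | 0.05 | p-value threshold | matches the published ns pattern |
| `n` (generator) | 232 | subjects | the normative sample size |
| `noise_sd`, `ability`, `bias`, `nonsem_offset` | calibrated | score units | frozen one-time calibration to the published moments |
| `discretize` | TRUE | — | real scores are integers in range; turn off for coefficient-recovery studies |

## 8. What the acceptance script computes

`scripts/acceptance.R --seed S --out F` recomputes, at run time: the
outer/inner tolerance ranks at n = 232 via the binomial construction
(targets t1/t2), and the OLS-recovered age coefficients for free recall,
semantic FM and failed recognition from freshly generated 5000-subject
uniform-demographic cohorts with the stated noise levels (t3/t5/t6).
Nothing is looked up; changing the seed perturbs t3/t5/t6 within their
sampling error (about 1–3% of the coefficient values).
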