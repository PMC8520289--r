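---
title: "Five risk-difference confidence intervals and non-inferiority concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five risk-difference confidence intervals and non-inferiority concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdci)
```

## The problem

A non-inferiority trial compares a new treatment against an active control
on a binary success outcome and declares non-inferiority when the lower
limit of the two-sided 95% CI of the risk difference d = p₁ − p₂ exceeds
−δ, the pre-specified margin (δ is quoted in percentage points, most often
10). The CI method is therefore not a cosmetic choice: two methods whose
lower limits differ by a few tenths of a percentage point can disagree on
the trial's verdict. `rdci` implements the five methods in common use and
the cohort-level analyses needed to measure how often they disagree.

## The estimators and their assumptions

All five assume two independent binomial counts x₁ ~ Bin(n₁, p₁),
x₂ ~ Bin(n₂, p₂), individual outcomes independent within arm, and no
stratification or covariate adjustment.

**Wald.** `d̂ ± z·√(p̂₁q̂₁/n₁ + p̂₂q̂₂/n₂)`. The variance is estimated at
the unconstrained MLE, which makes the interval anti-conservative for
small n or proportions near 0/1 and degenerate (width zero) when both
arms are at a boundary — the mechanism behind "non-inferiority shown by
Wald only" discordances.

**Agresti–Caffo.** The Wald formula applied to (xᵢ+1, nᵢ+2). Our
implementation is literally that reduction, so the equivalence is exact by
construction (and asserted exactly in the tests). The interval is centred
at the augmented estimate, not at d̂.

**Newcombe.** Wilson score limits (lᵢ, uᵢ) per arm, combined as
lower = d̂ − √((p̂₁−l₁)² + (u₂−p̂₂)²), upper = d̂ + √((u₁−p̂₁)² + (p̂₂−l₂)²).
Limits are inside [−1, 1] by construction.

**Miettinen–Nurminen.** The score test of H₀: p₁ − p₂ = d uses the
restricted MLE (p̃₁, p̃₂) under the constraint, obtained from the
closed-form trigonometric solution of the cubic score equation, and the
variance Ṽ(d) = (p̃₁q̃₁/n₁ + p̃₂q̃₂/n₂)·N/(N−1). The interval is the set of
d not rejected at level α; its limits solve |z(d)| = z_{α/2}.

**SCAS.** Keeps z(d) and Ṽ(d) exactly as in MN (including the N/(N−1)
inflation) and corrects for the skewness of the score statistic: limits
solve z(d) − γ(d)(z(d)² − 1) = ±z_{α/2} with
γ = μ̃₃/(6Ṽ^{3/2}), μ̃₃ = p̃₁q̃₁(q̃₁−p̃₁)/n₁² − p̃₂q̃₂(q̃₂−p̃₂)/n₂².
Matching the MN variance convention makes the γ → 0 reduction exact,
which the tests assert; the reference implementation of SCAS offers
further optional corrections that we deliberately do not add, for internal
consistency with the MN family. This is a genuinely open choice — the
published cohort analysis does not state which options its SCAS runs used —
and is the one place where our SCAS could differ from another
implementation by more than root-finding tolerance.

## Numerical choices

* `z_{α/2}` always comes from `qnorm` at run time; nothing is hard-coded.
* **Root finding (MN/SCAS).** The corrected statistic is monotone in d
  near d̂ but can recross the critical value close to d = ±1, so blind
  bisection over the whole half-range can land on a spurious root. We
  scan outward from d̂ in 512 equal steps per side, bracket the sign
  change *nearest* d̂, then bisect to an absolute tolerance of 1e−8
  (iteration cap 200, non-convergence is an error, never a silent
  result). If no sign change exists on a side the limit is exactly −1 or
  1 (boundary attainment, e.g. the upper limit when d̂ = 1). The
  score-equation residual at every finite returned limit is below 1e−6.
* **Restricted MLE.** The arccos argument is clamped to [−1, 1]; if the
  cubic degenerates (|p|³ < 1e−300 or a non-finite root) we fall back to
  bounded one-dimensional likelihood maximisation. The closed form is
  tested against a likelihood-grid oracle.
* **Truncation.** Wald and Agresti–Caffo limits are truncated to [−1, 1]
  and widths are computed from the truncated limits, since widths are what
  the cohort comparison summarises. Whether the original cohort analysis
  truncated before computing widths is unknowable from the publication;
  the choice only matters for extreme tables.
* **Non-inferiority rule.** `shown` iff lower > −δ, strictly; exact
  equality is measure-zero in floating point. The convention lives in one
  predicate (`ni_conclude`).
* **Quantiles.** Medians/IQRs use linear interpolation between order
  statistics (R type 7). At cohort sizes of a few hundred the printed
  precision is insensitive to the quantile type.
* **Conservatism ties.** `most_conservative` keeps the full arg-max set;
  the single-winner counts in `summarize_methods` break exact width ties
  by the fixed order MN > SCAS > Newcombe > AC > Wald (widest on average
  first). This is a reporting convention, not a mathematical claim.
* **Coverage.** Intervals count as covering when a limit equals the true
  difference (closed intervals). Exact enumeration is O(n₁·n₂) with all
  estimators vectorised over the outcome grid.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `level` | 0.95 | — | the two-sided convention of non-inferiority practice (one-sided 97.5% is the same limit) |
| margin grid | 0–20 by 1 | % points | spans every margin used in practice; 10 is the common choice |
| loess `span` | 0.75, degree 2 | — | smooth width-versus-size curves; qualitative display only |
| subsample sizes | 50, 100, 150, 200 | patients | the small-trial sizes the sensitivity analysis projects large trials onto |
| subsample threshold | 200 | patients | "large" means smallest arm above 200 |
| 1:1 threshold | max/min ≤ 1.2 | — | computable stand-in for the "approximately 1:1" label; configurable |
| subgroup bounds | rate > 0.90, smallest arm ≤ 100 | — | the regime where the five methods disagree most; "91% to 100%" is implemented as strictly above 0.90, half-open bands everywhere |

Two further conventions where the source description is ambiguous: the
subsampling draw is one size per comparison, applied to the smaller arm,
with the other arm scaled by the original allocation ratio and rounded —
this preserves the design ratio, and is moot for the ~95% of trials that
are 1:1; and successes after subsampling are `round(new_total × rate)`
(nearest integer).

## The synthetic cohort generator

`generate_trials()` emulates the marginal structure of the published
cohort of antibiotic non-inferiority trials: smallest-arm sizes are
log-normal with median 182 and IQR (101, 291); per-study true success
rates are logit-normal with median 0.84 and IQR (0.78, 0.91); 94.6% of
studies randomize 1:1 (the rest 2:1); margins are drawn from
{10, 12.5, 15} with weights (0.8, 0.1, 0.1); 8/224 of comparisons carry
no margin; 15% of studies report failures instead of successes; a few
percent of studies contribute two treatment arms sharing one control.
Calibration matches the target median exactly (location on the
transformed scale) and the IQR through the spread
σ = (T(q75) − T(q25))/(2·z₀.₇₅) with T = log or logit.

Where the published cohort gives no number we fixed a value once: the
failure-reporting share (0.15 — described only as a minority), the margin
weights (margins "typically 10"), two treatment arms per multi-arm study
(the cohort had nine two-arm and one three-arm such studies), and a floor
of 10 patients per arm. Both arms share one true success rate — the
non-inferiority null — so the generator makes no claim about true
treatment effects.

What the generator does **not** emulate: correlation between size, rate,
year and margin; reported-method mix by era; stratified designs; loss to
follow-up and the ITT/PP distinction (the population label is decorative
in synthetic data). A green pipeline test on synthetic data therefore
establishes that the machinery is correct and that the *qualitative*
subgroup ordering (Wald narrowest and most permissive at high success
rates and small n; MN among the widest) emerges from the stated marginal
structure — it does not reproduce the published cohort's printed numbers,
which requires that cohort's own data.

## Known limitations

* The exact SCAS option set used in the published analysis is unknown
  (see above); our SCAS is pinned to its defining equation and verified
  against a grid-search oracle, not against the reference implementation.
* Exact-method intervals (Clopper–Pearson style), Farrington–Manning,
  bootstrap, GLM-based and stratified/covariate-adjusted intervals are out
  of scope.
* `exact_coverage` enumerates (n₁+1)(n₂+1) outcomes and is meant for
  desk-scale arm sizes (≤ ~200); beyond that use `mc_coverage`.
* The CSV reader validates counts and margins but trusts metadata fields
  (year, labels) as free text.
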