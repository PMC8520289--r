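# rdci

Confidence intervals for the risk difference of two independent binomial
proportions, and the trial-level machinery to study how the choice of
interval method changes the conclusion of a non-inferiority trial.

## Who this is for

In a non-inferiority randomized trial the primary outcome is usually a
success proportion per arm, and the verdict rests on a single number: the
lower limit of the two-sided 95% CI of the risk difference
d = p₁ − p₂ (treatment minus control). Non-inferiority is shown when that
lower limit lies above −δ, the pre-specified margin. Different interval
methods give different lower limits for the same 2×2 table, so the same
trial can succeed under one method and fail under another. `rdci` is for
trialists and meta-researchers who want to quantify that sensitivity: it
implements the five methods most used in this setting and a pipeline that
re-evaluates a whole cohort of trials under all five at once.

## The five methods

For a table (x₁, n₁; x₂, n₂) with p̂ᵢ = xᵢ/nᵢ and d̂ = p̂₁ − p̂₂:

* **Wald** — d̂ ± z·√(p̂₁q̂₁/n₁ + p̂₂q̂₂/n₂). Simple, anti-conservative,
  and degenerate (zero width) when both arms sit at 0% or 100%.
* **Agresti–Caffo** — the Wald formula after adding one success and one
  failure to each arm.
* **Newcombe** — Wilson score limits per arm, combined by square-and-add.
* **Miettinen–Nurminen (MN)** — inverts the score test: limits are the two
  roots of |z(d)| = z_{α/2}, where z(d) uses restricted-MLE proportions
  under p₁ − p₂ = d (closed-form cubic) and the N/(N−1) variance inflation.
* **SCAS** — skewness-corrected asymptotic score: roots of
  z(d) − γ(d)·(z(d)² − 1) = ±z_{α/2} with γ = μ̃₃ / (6Ṽ^{3/2}) built from
  the constrained third central moment; reduces exactly to MN when γ = 0.

On top of the estimators the package provides: per-comparison widths and
"most conservative" (widest) method, non-inferiority conclusions against
study margins, five-method concordance, a margin sweep (0–20% by 1%),
subgroup stratification by smallest arm size and pooled success rate,
loess width-versus-size curves, a subsampling sensitivity analysis for
large trials, an exact coverage-probability engine, and a synthetic cohort
generator calibrated to the published distribution of antibiotic
non-inferiority trials.

## Worked example

One 2×2 table — 8/10 successes versus 6/10:

```r
library(rdci)
ci_all(8, 10, 6, 10)
#>               method estimate   lower  upper  width level
#> 1               wald      0.2 -0.1920 0.5920 0.7840  0.95
#> 2      agresti_caffo      0.2 -0.2046 0.5379 0.7425  0.95
#> 3           newcombe      0.2 -0.1870 0.5211 0.7080  0.95
#> 4 miettinen_nurminen      0.2 -0.2133 0.5568 0.7702  0.95
#> 5               scas      0.2 -0.2208 0.5775 0.7983  0.95
```

The point estimate is +20 percentage points, but the lower limit ranges
from −0.187 (Newcombe) to −0.221 (SCAS): with a 20% margin all five would
show non-inferiority, with a 19% margin SCAS alone would not.

A small cohort (the packaged 6-comparison fixture):

```r
td  <- read_trials(system.file("extdata", "example_trials.csv", package = "rdci"))
res <- evaluate_trials(td)
summarize_methods(res)[, c("method", "width_median", "ni_shown_n",
                           "ni_evaluable", "most_conservative_n")]
#>               method width_median ni_shown_n ni_evaluable most_conservative_n
#> 1               wald        13.88          5            5                   0
#> 2      agresti_caffo        14.34          5            5                   0
#> 3           newcombe        15.05          5            5                   1
#> 4 miettinen_nurminen        14.96          5            5                   4
#> 5               scas        14.58          5            5                   1

cc <- concordance(res)
#> concordant in 5 of 5 evaluable comparisons (100.0%)
```

Median widths are in percentage points; `ni_evaluable` is 5 because one
fixture comparison has no specified margin; MN is the widest method in 4
of 6 comparisons. `margin_sweep(res)` repeats the conclusion for margins
0–20%, and `sensitivity_sweep(td)` re-runs the sweep after subsampling
trials larger than 200 per arm down to 50–200 patients.

## Coverage engine

```r
exact_coverage("wald", 50, 50, 0.95, 0.95)$coverage                 # 0.9461
exact_coverage("miettinen_nurminen", 50, 50, 0.95, 0.95)$coverage   # 0.9566
```

Exact enumeration over all (n₁+1)(n₂+1) outcomes; `mc_coverage()` is the
Monte-Carlo cross-check. At high success rates the Wald interval is
anti-conservative relative to MN, the behavior that motivates discouraging
it.

## Command line

A CLI wrapping the same functions ships under `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "rdci.R", package = "rdci"))')" \
    compute-ci --x1 8 --n1 10 --x2 6 --n2 10 --json
```

Subcommands: `compute-ci`, `compare`, `sweep`, `subgroup`, `sensitivity`,
`coverage`, `simulate`.

## Data format

`read_trials()` expects one CSV row per comparison; see `rd_schema()` for
the column dictionary. Counts may be reported as successes or failures per
arm (exactly one of the pair); failure-reported rows are converted so the
risk difference always reads success-rate treatment minus control.
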