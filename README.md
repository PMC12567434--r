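# mubudget

Bottom-up measurement-uncertainty evaluation for analytical assays with
product-form content models, following the GUM (Guide to the Expression of
Uncertainty in Measurement) and its Supplement 1 Monte Carlo method.

Quality-control laboratories working under ISO/IEC 17025 must attach a
defensible uncertainty to every reported assay value. `mubudget` is for the
analyst building that budget bottom-up: it evaluates every component
(Type A statistics, rectangular/triangular Type B conversions, volumetric
calibration + temperature effects, calibration-curve inverse prediction,
pooled repeatability), combines them through the law of propagation,
cross-checks the result by Monte Carlo distribution propagation, and runs
the Supplement 1 numerical-tolerance validation of the two coverage
intervals.

For a product/quotient measurand the combined relative uncertainty is

```
u(C)/C = sqrt( sum_i ( u(x_i)/x_i )^2 ),    U = k * u(C)  (k = 2, ~95 %)
```

and the Monte Carlo stage propagates the full probability distribution of
every input (normal, rectangular, triangular) through the model, reading
the coverage interval off the simulated output. The GUM result is
*validated* when both interval endpoints agree with the Monte Carlo ones
within `delta = 0.5 * 10^l`, where `u = c * 10^l` with an integer mantissa.

The package ships a complete worked budget — an HPLC-UV assay of the
antiemetic Metopimazine in an injectable solution, 11 input quantities and
16 distribution components — as a JSON fixture, plus synthetic raw-data
generators so every evaluation stage is testable without chromatograms.

## Worked example

```r
library(mubudget)

budget <- mpz_budget()              # packaged assay budget
gum <- gum_uncertainty(budget, content = budget$reference$reported_content_pct)
gum
#> C = (99.41 ± 0.69)% (k = 2)
#> combined standard uncertainty u(C) = 0.3427% (relative 0.003447)
#> expanded uncertainty U = 0.6853%; interval [98.7247, 100.095]

head(tidy(gum), 3)                  # Pareto-ordered variance shares
#> # A tibble: 3 × 6
#>   symbol  value       u   u_rel share cumulative_share
#>   <chr>   <dbl>   <dbl>   <dbl> <dbl>            <dbl>
#> 1 VSample     2 0.0042  0.0021  0.371            0.371
#> 2 Cx          1 0.002   0.002   0.337            0.708
#> 3 Vp          5 0.00659 0.00132 0.146            0.854

y <- mcs_propagate(budget, m = 1e6, seed = 1)
mcs_summarize(y)
#> <mu_mcs> M = 1000000 trials (seed 1)
#>   mean 99.7002, median 99.6996, sd 0.3432, skewness 0.0087
#>   95% interval [99.0316, 100.372]; U = 0.6702; k = 1.9528

validate_intervals(99.41, 0.6853, c(98.7623, 100.0679), u = 0.3426)
#> <mu_validation> GUM vs MCS coverage-interval comparison
#>   GUM  [98.7247, 100.095]  (y = 99.41, U = 0.6853)
#>   MCS  [98.7623, 100.068]
#>   d_low = 0.0376, d_high = 0.0274, delta = 0.05 -> VALIDATED
```

Reading the numbers: the specimen volume and the calibration prediction
dominate the budget (together about 71 % of the combined variance), the
expanded uncertainty is about ±0.69 % of content at `k = 2`, the Monte
Carlo output is near-normal (empirical coverage factor ≈ 1.95, skewness
≈ 0), and the GUM interval agrees with the simulated one well inside the
0.05 tolerance — so the simpler GUM propagation is fit for routine use on
this assay.

Note that the product model evaluated at the budget's nominal values gives
`evaluate_content(budget)` = 99.700 %, while the content value published
with this budget is 99.41 %; the two are deliberately kept distinct (see
the vignette for the analysis of this inconsistency).

`run_pipeline()` chains all stages and writes CSV/text reports; a thin
command-line front end with `gum`, `mcs`, `validate`, `simulate` and
`report` subcommands lives at `inst/cli/mubudget.R`.

## Package layout

- `R/` — budget model and config I/O, component evaluators, GUM engine,
  Monte Carlo engine, interval validation, synthetic-data generators,
  tidiers and plots.
- `inst/extdata/mpz_budget.json` — the packaged assay budget fixture.
- `inst/cli/mubudget.R` — command-line front end.
- `vignettes/uncertainty-budget.Rmd` — the methods write-up.
- `tests/testthat/` — unit, property and end-to-end reproduction tests.
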