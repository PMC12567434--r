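---
title: "Measurement uncertainty for a product-form assay: GUM and Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement uncertainty for a product-form assay: GUM and Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mubudget)
library(dplyr)
```

## The measurand and its model

`mubudget` evaluates the measurement uncertainty of analytical assays whose
result is a pure product/quotient of input quantities. The packaged worked
example is an HPLC-UV assay of Metopimazine, an antiemetic, in an injectable
solution. The measurand is the drug content in percent:

$$
C\,(\%) = \frac{A_t}{A_{st}} \times \frac{P_t}{V_{t1}} \times
\frac{V_p}{V_{t2}} \times \frac{V_t}{V_{Sample}} \times P \times
\delta_r \times C_x \times V_{mDose} \times 100
$$

with the test/standard peak areas $A_t, A_{st}$, the reference mass $P_t$
(mg), four dilution volumes (mL), the reference purity $P$, and the
dose-ratio constant $V_{mDose} = 0.1$ mL/mg, which carries no uncertainty.
Two terms are *relative-effect factors* with nominal value 1: $\delta_r$,
the pooled repeatability of the whole procedure, and $C_x$, the
calibration-prediction effect. They carry their relative uncertainties
directly (0.0005 and 0.002 in the packaged budget) because their physical
scales (percent content, mg/mL) cancel out of the product.

```{r}
budget <- mpz_budget()
budget$quantities |> select(symbol, value, unit, u, u_rel, dof)
```

The dilution train is designed to cancel at nominal values:
$(P_t/V_{t1})(V_p/V_{t2})(V_t/V_{Sample})\,V_{mDose} = 1$, so with equal
peak areas the content is just $P \times 100$. Evaluating the model at the
nominal values of the packaged budget gives:

```{r}
evaluate_content(budget)
```

This computed value (99.700 %) differs from the content value published
with this budget (99.41 %, preserved in `budget$reference`), which instead
equals $(A_t/A_{st})^2 \, P \times 100$ to four significant figures — the
area ratio appears to have been folded into the $C_x$ factor in the
original calculation. The engine always reports its own computed value;
functions that reproduce the published combined uncertainty accept the
published content explicitly via the `content` argument. We deliberately do
not guess at a correction: the model, the budget, and the reference
metadata are kept separate so the discrepancy stays visible.

## Evaluating the components

Every standard uncertainty in the budget is computable from raw inputs:

* **Type A** — `type_a_uncertainty()` gives $s/\sqrt m$ on $m-1$ degrees of
  freedom, used for the replicate-injection system-suitability series
  (`sst_statistics()` adds the CV acceptance checks: area < 2.0 %,
  retention time < 1.0 %).
* **Type B** — `rectangular_u()` and `triangular_u()` convert bounded
  half-widths by $\sqrt 3$ and $\sqrt 6$. Rectangular is the conservative
  choice when only limits are known (purity certificate, balance
  linearity, temperature band); triangular suits manufacturer glassware
  tolerances where values near nominal are most likely.
* **Volumes** — `volume_budget()` combines the calibration tolerance
  (triangular) with the temperature effect $V \Delta T \alpha$
  (rectangular; default $\Delta T = 4$ °C around the 20 °C calibration
  temperature, $\alpha = 2.1\times10^{-4}$ per °C for aqueous solutions)
  in quadrature; `dilution_relative_u()` gives the whole dilution train's
  relative uncertainty.
* **Calibration prediction** — `fit_calibration()` is unweighted OLS
  (justified when residuals are homoscedastic); `prediction_u()` is the
  inverse-prediction standard error
  $\frac{S_{res}}{a_1}\sqrt{\frac1p + \frac1n +
  \frac{(C_x-\bar c)^2}{SSD_x}}$, minimal at the calibration centroid.
* **Repeatability** — `pooled_repeatability()` pools within-run variances
  (dof-weighted, i.e. one-way ANOVA pooling; the original source states
  only that the value derives from the 18 measurements, so the pooling
  rule is our documented choice) and divides by $\sqrt{n_{total}}$ by
  default; the divisor is exposed as an argument because some laboratories
  prefer the per-future-run replicate count.

```{r}
glassware <- tibble::tibble(volume = c(2, 5, 25, 100),
                            tolerance = c(0.01, 0.015, 0.04, 0.1))
vb <- volume_budget(glassware)
vb
dilution_relative_u(vb)
```

One Type B value in the packaged budget, the chromatographic measurement
uncertainty 0.0022 shared by both peak areas, is stored as given: it is not
derivable from the suitability series statistics by any stated rule
(quadrature of the two sd-of-means gives 0.00168), so recomputing it would
misrepresent the published budget.

## GUM combination

For a product model the law of propagation reduces to quadrature of
relative uncertainties, $u_{rel}(C) = \sqrt{\sum_i (u_i/x_i)^2}$, with
$u(C) = u_{rel} \cdot C$ and $U = k\,u(C)$. The default coverage factor is
$k = 2$ (≈ 95 % for a normal measurand); `welch = TRUE` instead derives
$k$ from the Student t at the Welch–Satterthwaite effective degrees of
freedom, $\nu_{eff} = u^4/\sum u_i^4/\nu_i$, truncated down for the
quantile lookup. Welch–Satterthwaite is opt-in because the headline result
of the reference budget uses $k = 2$.

```{r}
g <- gum_uncertainty(budget, content = budget$reference$reported_content_pct)
glance(g)
head(tidy(g))
```

Contribution shares are defined on squared relative uncertainties
(variance shares), which sum to one by construction and are reported in
Pareto order (`autoplot(g)` draws the chart). The shares published
alongside this budget (39.9 % and 36.2 % for the top two sources) do not
match the variance shares implied by its own table (37.1 % and 33.7 %);
since the published denominator is not stated, the engine reports the
computed shares and keeps the published ones as reference metadata.

`propagate_numeric()` offers an independent check: central
finite-difference sensitivity coefficients ($c_i = \partial C/\partial
x_i$, relative step $10^{-6}$, safe because the model is smooth and
scale-free) combined as $u^2 = \sum c_i^2 u_i^2$. On product models it
agrees with the closed form to first order, and it accepts an arbitrary
model function for non-product equations.

## Monte Carlo propagation

`mcs_propagate()` implements distribution propagation: each distribution
component is sampled independently — normal by `rnorm`, rectangular as
$a + (b-a)U$, triangular as $a + \frac{b-a}{2}(U_1 + U_2)$ — and a
quantity's trial value is its nominal value perturbed by the sum of its
components' relative deviations from their centers. Two conventions are
worth spelling out:

* **Multi-component quantities.** Each volume has a calibration and a
  temperature row; they are sampled independently and added as deviations
  around the shared nominal, because they are listed as separate
  components and volumetric repeatability is already captured by
  $\delta_r$ (double-counting is the thing to avoid).
* **Relative-effect factors on another scale.** $C_x$ is assigned
  N(0.2 mg/mL, 0.0004); dividing the draw by its center converts it to the
  dimensionless multiplier with relative sd 0.002, exactly the budget's
  declared value, keeping the model dimensionless.

The purity row of the packaged distribution table uses the certificate
bounds 0.9999 ± 0.0001 (rectangular), which reproduce the declared
standard uncertainty 0.000058; the loader's 3 % cross-check between
declared and distribution-implied uncertainties enforces this kind of
consistency for every symbol.

`mcs_summarize()` reports mean, median, sd, skewness, the equal-tailed
percentile interval (2.5th/97.5th at 95 %), the expanded uncertainty as
half the interval width, and the empirical coverage factor $k = U/sd$. The
equal-tailed convention is the default because the output distribution of
a near-linear product model is close to symmetric; a shortest-interval
option exists for asymmetric cases. Interval estimates are refused below
1000 samples. All randomness is seeded locally, so a fixed seed gives a
bit-identical result without disturbing the caller's RNG state.

```{r}
y <- mcs_propagate(budget, m = 1e5, seed = 1)
mcs_summarize(y)
```

`mcs_convergence()` reruns the propagation over an ascending trial ladder
and flags stability when the relative change of the interval width drops
below a tolerance (default 0.1 %). In the package's own checks the ladder
$10^4, 10^5, 10^6$ stabilizes well below that tolerance at $10^6$ trials.

## Validating GUM against the simulation

`validation_tolerance()` writes $u = c \cdot 10^l$ with a one- or
two-digit integer mantissa and returns $\delta = 0.5 \cdot 10^l$. Rounding
to the mantissa is half-away-from-zero — the convention matters and is
documented because $\delta$ jumps an order of magnitude at digit
boundaries. `validate_intervals()` then compares endpoints:
$d_{low} = |y - U - y_{low}|$, $d_{high} = |y + U - y_{high}|$, validated
iff both are below $\delta$. The verdict is monotone in $\delta$, and both
differences are always reported so the comparison table can be regenerated
in full.

```{r}
validate_intervals(99.41, 0.6853, c(98.7623, 100.0679), u = 0.3426)
```

Of the two published endpoint differences for this budget only the lower
one (0.0376) is reproducible from the published bounds; the upper one
(0.0474) is inconsistent with every printed bound pair, so the package's
tests assert the lower difference only.

## Synthetic raw data

`synthetic_design()` and the `simulate_*()` generators produce the three
raw-data layouts the evaluators consume, with defaults matching the
assay's validation design: a 5-level × 3-replicate calibration over
0.12–0.28 mg/mL (60–140 % of the 0.2 mg/mL target, giving
$SSD_x = 0.048$), homoscedastic normal residuals; a 3 × 6 repeatability
study; a 6-injection suitability series. The default slope (350 response
units per mg/mL, of the order of the observed area 70.5 at 0.2 mg/mL) is
arbitrary in the sense that the prediction uncertainty depends only on
$S_{res}/a_1$; the default residual sd 0.285 puts that ratio at the order
observed in the assay. `recovery_u_cx()` closes the loop: it simulates
calibrate–predict cycles and compares the empirical sd of predicted
concentrations against the closed-form `prediction_u()` at the true
parameters.

What the generators emulate is the *statistical* structure the analysis
assumes — independent homoscedastic normal noise, balanced designs. They
do not emulate chromatographic reality: drift, integration artifacts,
heteroscedasticity at the range ends, run-to-run bias. Passing
parameter-recovery tests therefore shows the formulas are implemented
correctly, not that the assumptions hold for any particular instrument.

## Numerical choices and problem sizes

* Finite-difference step $10^{-6}$ relative, central differences.
* Equal-tailed percentile interval via `quantile()` (type 7 default).
* Mantissa rounding half away from zero.
* Degenerate inputs: constant series give zero Type A uncertainty; a
  zero-width tolerance gives zero Type B; fewer than 1000 Monte Carlo
  samples refuse interval estimates; single-run repeatability studies are
  rejected.
* Degrees of freedom in the packaged budget beyond the stated
  repeatability dof (17): calibration prediction 13 ($n - 2$ from 15
  points), peak areas 5 (six injections), Type B components infinite.
  These matter only to the opt-in Welch–Satterthwaite path.
* Test and example problem sizes: unit tests run the simulation-based
  checks at $10^4$–$2\times10^5$ trials and a few hundred replicate
  studies; the full-scale checks (the $10^6$-trial propagation, the
  2000-repetition recovery study) run in the acceptance-style tests. These
  sizes give Monte Carlo errors comfortably inside the asserted
  tolerances.

## Known limitations

* Only product/quotient models with scalar constants and relative-effect
  factors; no symbolic algebra, no correlated inputs (the covariance term
  of the general propagation law is out of scope, matching the reference
  budget's no-correlation finding).
* Unweighted calibration regression only; no outlier rejection.
* No adaptive Monte Carlo or quasi-random sequences.
* The configuration dialects are JSON and YAML.
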