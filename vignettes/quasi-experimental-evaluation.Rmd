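---
title: "Evaluating population-level policies with controlled ITS and synthetic controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating population-level policies with controlled ITS and synthetic controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthits)
```

## The problem

National policies aimed at population health outcomes — here, programmes to
reduce teenage pregnancy — cannot be evaluated by randomisation. What is
observable is an annual outcome rate (events per 1000 women in an age group)
for the exposed country and for a set of comparison countries, typically over
two or three decades. The question is counterfactual: would the exposed
country's rates have followed the same path without the policy? This package
implements two complementary quasi-experimental designs for country-year
rate panels, together with the placebo-based inference that such small-n
designs require, and a synthetic data generator that reproduces the
statistical structure the designs assume, so that the whole pipeline is
testable without access to any national statistics extract.

All analyses consume one tidy table (`rate_panel`): one row per
(country, year, age group), holding counts and/or a pre-computed rate per
1000 women. Rates derive from counts as
`1000 * (births + abortions) / population`, with a births-only mode for the
birth-rate measure where abortion counts are not comparable across
countries.

## Controlled interrupted time series

For a single country the model is segmented least squares on annual
observations $y_t$:

$$
y_t = \beta_0 + \beta_1 t + \beta_2 \,\mathrm{pill}_t + \beta_3 \,\mathbb{1}[t \ge t_0]
      + \beta_4 \,(t - t_0 + 1)^+ + \varepsilon_t,
$$

with time coded as $t - t_0$ (years relative to the intervention year,
default 1999). $\beta_3$ is the immediate level change and $\beta_4$ the
*accumulating* trend change — after $k$ post-intervention years the fitted
departure from the pre-intervention trajectory is $\beta_3 + k\beta_4$. The
"pill" term is a level corrector switching on in 1996, absorbing the upward
jump in UK rates that followed the 1995 oral-contraceptive safety scare; an
optional common-shock term adds a shared trend change from 2008, where UK
series show a second, policy-unrelated break. Phase-in years can be dropped
as rows.

The controlled design stacks a treated and a control country in a single
regression with treated-unit interactions on the level and trend-change
terms. The interaction coefficients *are* the treated-over-control
differences, so their confidence intervals come directly from the fit — the
reason for modelling jointly rather than fitting two separate ITS models and
subtracting. By construction the estimates are invariant to any shock common
to both countries at the intervention date (a property the test suite checks
exactly). Defaults follow from the design logic: one shared pre-intervention
slope (`parallel_pre_trends = TRUE`, appropriate when pre-trends track each
other closely, and much more stable with only ~7 pre-intervention points)
and a shared corrector coefficient (the triggering event hit all UK
countries alike); both can be relaxed per unit.

### Autocorrelated errors

Annual rates are positively autocorrelated at lag 1. The package reports
three diagnostics on the OLS residuals — the Durbin–Watson statistic and the
lag-1 ACF and PACF — and leaves the decision to correct to an explicit flag
(default on), rather than guessing from the diagnostics itself. Correction
is AR(1) generalized least squares with two estimators of the lag-1
parameter $\rho$:

* `rho_method = "lag1"` (default): the classical iterative scheme —
  Cochrane–Orcutt quasi-differencing with Prais–Winsten retention of each
  unit's first observation (scaled by $\sqrt{1-\rho^2}$), $\rho$ from the
  lag-1 regression of residuals within unit blocks, iterated to
  $|\Delta\rho| < 10^{-6}$ (at most 50 iterations).
* `rho_method = "reml"`: $\rho$ from a one-dimensional profile of the
  restricted likelihood, then the same GLS step at the profiled value.

The distinction matters in exactly the regime these designs live in: 25-ish
years per unit and eight or nine regressors. There the residual-regression
estimator is biased toward zero (model degrees of freedom absorb serial
dependence), which deflates the GLS standard errors; the REML profile is
nearly unbiased and restores close-to-nominal interval coverage. In the
package's own calibration experiment (1000 simulated two-country null
panels under the generator's default conditions, fit with the common-shock
term; see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`,
which recompute it), the REML variant covers the null trend difference at
the nominal rate while the classical iteration undercovers by several
points (both coverages are among the quantities `scripts/acceptance.R`
reports). The classical scheme remains the default for comparability with
standard ITS practice; calibration statements in this package use the REML
variant. `se = "newey-west"` is a third route: OLS point estimates with HAC
standard errors (`sandwich::NeweyWest`, lag 1). Confidence intervals are
t-based with residual degrees of freedom throughout — with ~25 annual
observations, normal quantiles would be noticeably anticonservative.

The controlled fit also returns a "no-policy" counterfactual for the
treated unit: its own pre-trend (and corrector) carried forward with only
the control's estimated level and trend changes applied — i.e. the fit with
the treated interactions zeroed.

## Synthetic control

Where several comparison countries are available, the counterfactual is a
*synthetic control*: a convex combination of donor countries,
$w \ge 0, \sum_j w_j = 1$, chosen so the weighted donors track the treated
unit before the intervention. Weights solve

$$
\min_{w \in \Delta} \sum_k v_k \big(x_{1k} - X_{0k}\, w\big)^2,
$$

where the predictors $x_1, X_0$ are block means of the pre-intervention
outcome over a contiguous partition of the pre-period years (optionally
plus auxiliary covariates, z-scaled across units because GDP-scale and
rate-scale predictors differ by orders of magnitude), and $v$ weights the
predictors' importance. The quadratic program is solved exactly by a dual
active-set method (`quadprog`) on the ridge-stabilised normal matrix, with
an accelerated projected-gradient fallback (`method = "pgd"`, 1000
iterations, simplex projection by sort-and-threshold); the test suite
certifies the solution against a dense simplex grid search. Two numerical
details are deliberate:

* *Support polish.* Active-set solutions on the ridge-stabilised matrix are
  re-solved on their support without the ridge, so vertex solutions (treated
  identical to one donor) come out exactly 0/1.
* *Degeneracy tie-break.* With few predictors the weights can be
  under-identified — many $w$ match the predictor targets exactly. In that
  case the package re-solves for the best pre-period *outcome* fit subject
  to the exact predictor match, a deterministic and interpretable rule
  (the audit trail stays meaningful; without it, a one-predictor model may
  return an arbitrary point of the optimal face with a poor outcome fit).

`v_mode = "optimized"` runs the nested search: for candidate $v$ (softmax
parameterisation, Nelder–Mead from equal weights plus four random restarts
under a fixed seed), solve for $w^*(v)$ and score by pre-period outcome
MSPE; equal weights are kept if the search cannot beat them. Whether the
original analyses optimised $v$ or used equal weights is not knowable from
the published record; both modes are exposed and optimised is the default.

### Choosing the year grouping

Rather than fixing the predictor partition a priori, the grouping is
data-driven: all $2^{n-1}$ contiguous partitions of the $n$ pre-period
years are enumerated (for $n = 9$, 256 candidates; a guard refuses $n > 15$
without an explicit override). "As few groups as possible with a minimised
MSPE" is a bi-objective rule with no stated trade-off, so the package makes
it precise: among partitions within a tolerance band (default 5%) of the
global minimum MSPE, take the fewest groups, break ties by lower MSPE, then
by lexicographic block boundaries; the full enumeration table is returned
for audit, and any partition can be forced by configuration. Inside the
enumeration each partition is scored with equal predictor weights —
running the full $v$ search for each of 256 partitions would multiply the
cost a thousand-fold without changing what the rule means — and $v$ is then
optimised once for the selected partition. The tolerance band carries a
tiny absolute floor ($10^{-9}$) so that in the degenerate case where every
partition fits essentially exactly, solver noise does not defeat the
fewest-groups preference.

## Placebo inference

With one treated unit, classical standard errors for the synthetic-control
gap are unavailable; inference is permutation-style:

* **In-space placebos** refit the entire protocol for each donor as if it
  had been treated (pool = the other donors; the truly treated unit is
  excluded so no placebo borrows the real intervention signal). By default
  the grouping search itself is re-run per placebo ("full" protocol) —
  the methodologically symmetric choice — with a cheaper "fixed" mode that
  reuses the treated unit's predictor spec.
* **The post/pre-MSPE ratio test** ranks the treated unit among all units
  (itself included) by descending ratio of post- to pre-intervention MSPE,
  ties counting as outranking (conservative), and reports
  $p = \text{rank}/n_{\text{units}}$. This is the only rank/p convention
  consistent with reporting both $14/16 = 0.88$ and $11/16 = 0.69$; under
  an exchangeable null it makes $p$ uniform on $\{1/n, \dots, 1\}$, which
  the test suite verifies by Kolmogorov distance over 500 simulated nulls.
* **5× filtering** (`filter_placebos`) drops placebos whose pre-period
  MSPE exceeds five times the treated unit's before gap plots, so the
  visual comparison is against placebos that actually fit; the ratio test
  itself uses all units. The filter is idempotent and always retains the
  treated unit.
* **In-time placebos** re-run the protocol at fictitious intervention
  dates (default 1995–1998; at least three pre-dummy years required). At
  the true date the result is bit-for-bit the main fit. A model that
  "finds" divergence at dates when nothing happened is overfitting — or,
  as with a 1996-only treated shock, is reacting to a genuine
  pre-intervention event, which the dummy-date pattern localises.
* **Leave-one-out** iteratively removes the top-weighted donor and refits
  (weight ties drop the alphabetically first donor; the predictor spec is
  held fixed so changes are attributable to donor removal alone), probing
  dependence on any single donor.

## The synthetic data generator

`sim_config()`/`generate_panel()` emulate the joint structure the designs
assume, with defaults chosen to mirror teenage-pregnancy panels in
high-income countries:

* a common secular trend: baseline 45 per 1000 at 1990, slope +0.5/yr
  through the 1990s, a −2.0/yr slope change at 1999 and a further −1.0/yr
  at 2008 (so increments run +0.5, −1.5, −2.5);
* country offsets, i.i.d. normal with s.d. 3 per 1000;
* a +2.0 level shock from 1996 for "UK-like" units (the pill-scare
  signature);
* an optional treated-only intervention effect from 1999, `c(level,
  trend)`, default `c(0, 0)` — a null world;
* AR(1) observation noise, $\rho = 0.3$, innovation s.d. 0.8, initialised
  at stationarity (variance $\sigma^2/(1-\rho^2)$) so 25-point series have
  no burn-in artefact;
* `mixture_mode`: the treated latent mean is a stated convex combination
  of donor latent means, and each donor additionally carries i.i.d.
  idiosyncratic year effects (s.d. 1.5) — without them donor trajectories
  differ only by level and the planted weights would not be identifiable.

Everything is deterministic in the seed; rates are truncated at zero with
a warning (negligible under the defaults). Counts can be emitted against a
fixed population of 100,000 for exercising count-based I/O.

What the generator does *not* emulate: age-structured fertility, cohort
effects, measurement revisions, cross-country correlation of shocks other
than the shared trend, or calibration to any real national series. Passing
tests therefore certify the *statistical machinery* — unbiasedness,
coverage, weight recovery, permutation-p uniformity — under the stated
conditions, not the substantive conclusions one would draw from real
extracts, which also carry reporting corrections (conception dating,
multiple births) this package deliberately treats as upstream of its
inputs: supplied rates are taken as authoritative.

## Problem sizes used in the checks

The stochastic properties are verified at sizes a laptop reproduces in a
few minutes, chosen as the smallest that pin each property down: null CI
coverage over 1000 two-country panels; trend-effect recovery (−1.5/yr,
AR(1) noise $\sigma = 0.5, \rho = 0.3$) over 300–500 panels; planted-weight
recovery (0.6/0.4, observation noise s.d. 0.01) over 100 panels;
permutation-p uniformity over 500 panels of 20 exchangeable units (20 units
keep the discrete p-grid fine enough that the Kolmogorov distance to the
continuous uniform stays within the stated 0.08); the grouping search
against a brute-force re-enumeration of all 256 partitions of 9 pre-years.
`scripts/acceptance.R` recomputes the headline quantities from scratch at
these sizes.

## Known limitations

* One control country per controlled ITS fit (comparisons are pairwise);
  no seasonal terms (annual data).
* The ITS corrector is a level dummy only; a trend corrector would not be
  identifiable with so few pre-intervention points.
* Synthetic-control inference is permutation-based only; no conformal or
  projection intervals.
* The grouping search is exhaustive by design and exponential in the
  pre-period length; it refuses more than 15 pre-years without an
  override.
* With very few donors or near-collinear donor trajectories the weight
  solution can sit on a large optimal face; the outcome tie-break makes
  the reported point deterministic but the non-uniqueness is real, and the
  leave-one-out table is the honest way to read such fits.
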