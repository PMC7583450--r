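---
title: "Valuing implementation when marginal costs and benefits vary with uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing implementation when marginal costs and benefits vary with uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voimp)
```

## The problem

A health technology that is cost-effective on paper delivers no value to
patients who never receive it. Value-of-implementation analysis puts a
monetary figure on closing that gap: given an eligible population of size
$n$, a current uptake ("implementation level") $p \in [0,1]$, and a
per-patient net monetary benefit
$$\mathrm{NMB} = k\,\Delta H - \Delta C,$$
where $\Delta H$ is the incremental health gain in QALYs, $\Delta C$ the
incremental cost, and $k$ the cost-effectiveness threshold (currency per
QALY), the value of the *current* implementation is $n\,p\,\mathrm{NMB}$,
the value of *perfect* implementation is $n(1-p)\mathrm{NMB}$, and a
strategy that raises uptake from $p$ to $\sigma$ at cost $I$ is worth
$n(\sigma - p)\mathrm{NMB} - I$.

The extension this package implements drops the assumption that
$\Delta H$ and $\Delta C$ are constants. For precision-medicine
test-treat strategies in particular, early adoption is beset by
technical failures and clinicians ignoring discordant test results:
costs are incurred without benefit, so the *marginal* per-patient
quantities depend on the implementation level itself,
$$\mathrm{NMB}(p) = k\,\Delta H(p) - \Delta C(p).$$
With level-dependent NMB the value expressions must evaluate the NMB at
the level actually attained. The static measures become
$$\underbrace{n\,p\,\mathrm{NMB}(p)}_{\text{current}},\qquad
\underbrace{n\big(\mathrm{NMB}(1) - p\,\mathrm{NMB}(p)\big)}_{\text{perfect}},\qquad
\underbrace{n\big(\sigma\,\mathrm{NMB}(\sigma) - p\,\mathrm{NMB}(p)\big)}_{\text{actual}},$$
and the net value of a strategy subtracts its cost $I$. When
$\mathrm{NMB}(p)$ is constant these reduce exactly to the familiar
forms above — a reduction the test suite asserts as an identity.

A positive slope of $\mathrm{NMB}(p)$ means increasing returns to
scale: each additional adopter makes the next patient's treatment more
valuable. The flip side is a *break-even* level $p^*$ with
$\mathrm{NMB}(p^*) = 0$ below which the technology is not a
cost-effective use of resources at all, however cost-effective its
long-run estimate looks.

## Marginal profiles

`marginal_profile` objects carry $\Delta H(p)$ and $\Delta C(p)$ in one
of three forms: `constant_profile()`, `linear_profile()` and
`tabulated_profile()` (piecewise-linear through knots). Two numerical
choices deserve a note:

* **Extrapolation.** Fitted lines are valid on all of $[0,1]$, and
  tabulated profiles extrapolate linearly from their end segments. The
  case study evaluates uptake levels from 9% to 96% against data
  observed on [3%, 92%], so refusing to extrapolate would make the
  dynamic analysis impossible; linear continuation of the nearest
  segment is the least-structured choice.
* **No clamping.** A fitted line may predict a slightly negative
  $\Delta H$ near $p = 0$ (the case-study health line has intercept
  $-0.006$). Values are used as-is: clamping at zero would silently
  bend the value arithmetic and break exact reproduction of published
  results.

The currency is a label only; every computation is unit-agnostic.

## The OLS meta-model

Decision-analytic (Markov) models that generate $\Delta H$ and
$\Delta C$ at different implementation levels are rarely distributable,
but their outputs are. `nmb_metamodel()` fits unweighted
ordinary-least-squares lines with intercept — via `stats::lm()` — to
output triples $(p, \Delta H, \Delta C)$, one regression per component,
and reports $R^2 = 1 - SS_{res}/SS_{tot}$ for each. Two or more
distinct levels are required; regression through the origin is
deliberately not offered, since the level-zero intercept is part of
what the model must capture.

```{r}
fit <- nmb_metamodel(mammaprint_inputs()$triples)
fit
```

Coefficients are kept at full precision internally.
`as_linear_profile(fit, rounded = TRUE)` rounds the health coefficients
to 4 decimal places and the cost coefficients to whole currency units —
the precision at which such equations are conventionally reported. The
packaged case study uses the rounded line ($\mathrm{NMB}(p) = 4184p -
2116$ at $k = 20{,}000$) because every downstream published figure is
an arithmetic consequence of exactly those rounded coefficients;
`rounded = FALSE` carries full precision instead. On these three
fitting points full-precision OLS gives $R^2 \approx 0.9975$ for the
health component, which prints as 0.997 although the source analysis
reported 0.998 — a rounding-path difference of less than 0.001 that the
package does not attempt to reverse-engineer.

`break_even()` solves $\mathrm{NMB}(p) = 0$: closed-form for a line,
and for tabulated profiles by bracketing sign changes on the knot grid
and refining with `stats::uniroot()` to $10^{-9}$. If the NMB never
crosses zero the result is the sentinel `always_cost_effective` or
`never_cost_effective`; multiple crossings return the smallest root
with a multiplicity flag. Because "the level at which NMB turns
positive" is usually quoted as a whole percentage, the result also
carries `rounded_percent`, the smallest integer percent with strictly
positive NMB (51% for the case study, against an exact root of
50.57%).

## Dynamic streams, diffusion and discounting

`schedule_set()` assembles per-year inputs over a horizon $T$:
population $n_t$ (scalars broadcast), baseline uptake $p_t$, strategy
uptake $\sigma_t$ and strategy costs $i_t$. `linear_diffusion(start,
step, T)` builds the uptake path $p_t = \min(1,\; start + step\,(t-1))$
— uptake grows by a fixed number of percentage points a year and is
capped at full uptake. The four streams mirror the static measures,
discounted:
$$\sum_{t=1}^{T} \frac{n_t\,p_t\,\mathrm{NMB}(p_t)}{(1+r)^{t-1}}
\quad\text{(current)},\qquad
\sum_{t=1}^{T} \frac{n_t\big(\sigma_t \mathrm{NMB}(\sigma_t) - p_t \mathrm{NMB}(p_t)\big) - i_t}{(1+r)^{t-1}}
\quad\text{(net)},$$
and analogously for the perfect and actual streams.

**The discount convention is always explicit.** Two conventions are in
circulation: dividing year $t$ by $(1+r)^{t-1}$ (year 1 at face value)
or by $(1+r)^t$ (year 1 already discounted). They differ by a uniform
factor $1+r$ — an identity the property tests assert — but quoting a
total without naming the convention makes it irreproducible. The
source analysis for the packaged case study itself mixes the two: its
printed equations use exponent $t-1$, and its strategy-value table is
consistent with that, but its current-value table can only be
reproduced with exponent $t$ (e.g. year 1:
$10000 \times 0.09 \times 1813 / 1.03 = 1{,}584{,}175$). Rather than
guess which was intended, `discount_spec()` makes the convention a
mandatory, logged part of the analysis, and the case-study fixture pins
`first_year_discounted` for the current-value stream and
`first_year_undiscounted` for the strategy stream, reproducing each
published table under its own convention.

## The MammaPrint case study

The packaged worked example concerns MammaPrint, a 70-gene
breast-cancer recurrence signature used to decide which women can
safely forgo adjuvant chemotherapy. Its inputs, shipped as plain-text
files under `inst/extdata/`, are: three decision-model output triples
(uptake 3%, 50%, 92%), threshold €20,000/QALY, 10,000 eligible women
per year, diffusion from 9% uptake at 6 percentage points/year over 15
years, an implementation strategy adding 3 percentage points of uptake,
and a 3% discount rate. The constant-NMB comparator is built from the
92% row ($\mathrm{NMB} = 20000 \times 0.1492 - 1171 = 1813$): a
conventional CEA reports long-run values, which the highest observed
implementation level best represents.

```{r}
mammaprint_headlines()
```

The qualitative story: under constant NMB the diffusing technology
accrues value from year 1; under the fitted varying NMB it *destroys*
value for seven years (a discounted €12.9m, the health-system
equivalent of about 645 QALYs at the threshold) before uptake passes
break-even — and an uptake-raising strategy is worth about €0.7m more
over 15 years than constant-NMB accounting would suggest, because it
accelerates the climb through the loss-making region.

## Synthetic scenarios and what the tests show

`random_scenario(seed)` draws reproducible random scenarios for
property testing: linear profiles with health slope in
$[-0.2, 0.2]$ QALY/patient and intercept in $[0, 0.2]$, cost slope in
$[-2000, 2000]$ and intercept in $[0, 3000]$ currency/patient — a
bracket around the case-study magnitudes wide enough to include
decreasing returns to scale and never-cost-effective technologies —
plus random diffusion paths, horizons of 5–20 years, thresholds in
$[5000, 80000]$ and rates in $[0, 0.06]$. The suite checks, over 200
seeds, the constant-profile reduction, telescoping additivity of the
actual value, the $\sigma = 1$ / perfect-value identity, the
convention $\times(1+r)$ identity, zero-rate additivity, and agreement
of every stream total with an independent year-by-year loop oracle to
$10^{-9}$ relative.

These scenarios are deliberately *structural* stand-ins: they exercise
the algebra, not the world. Real uptake curves are S-shaped rather than
linear, eligible populations drift, marginal profiles need not be
linear in $p$, and decision-model outputs come with uncertainty that
this package does not propagate (no probabilistic sensitivity analysis,
no value-of-information integration). Passing the property suite shows
the accounting identities are implemented correctly — not that a linear
meta-model fitted to three points is an adequate emulator for any
particular technology; with three observations the $R^2$ values are
descriptive, not evidence.

## Further numerical and design notes

* Values are computed and compared un-rounded everywhere; rounding to
  whole currency units happens only in printed output and published
  comparisons (hence per-year agreement within ±€2 and totals within
  ±€30 against tables typeset from rounded cells).
* `static_scenario()` validates fractions into $[0,1]$ and non-negative
  populations and costs at construction, so the value functions carry
  no defensive code.
* Uptake paths built arithmetically (diffusion plus strategy offset)
  are capped at 1; the case-study paths peak at 0.96 and never hit the
  cap.
* Problem sizes throughout the examples and tests are desk-scale (a
  15-year, 10,000-patient stream is 15 multiplications); the full suite
  runs in seconds.
* Configuration files name every assumption explicitly; YAML authors
  should quote the population key (`"n":`), since bare `n` is YAML-1.1
  shorthand for a boolean.
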