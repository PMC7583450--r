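# voimp

Value-of-implementation analysis for health technologies whose marginal
costs and benefits vary with uptake.

A cost-effective technology that nobody uses delivers no value.
Value-of-implementation analysis monetises the gap between current and
fuller uptake: with an eligible population $n$, implementation level
$p$, and per-patient net monetary benefit
$\mathrm{NMB} = k\,\Delta H - \Delta C$ (health gain $\Delta H$ in
QALYs monetised at threshold $k$, incremental cost $\Delta C$), a
strategy raising uptake from $p$ to $\sigma$ is worth
$n(\sigma - p)\mathrm{NMB} - I$.

`voimp` implements the generalisation needed for precision medicine and
other technologies with returns to scale, where the *marginal*
per-patient quantities depend on the implementation level itself:

$$\mathrm{NMB}(p) = k\,\Delta H(p) - \Delta C(p),$$

so the actual value of a strategy becomes
$n\big(\sigma\,\mathrm{NMB}(\sigma) - p\,\mathrm{NMB}(p)\big)$, and the
dynamic (multi-year) value of a diffusing technology is
$\sum_t n_t\,p_t\,\mathrm{NMB}(p_t)/(1+r)^{t-1}$ under an explicit
discount convention. The package provides:

* **marginal profiles** (`constant_profile()`, `linear_profile()`,
  `tabulated_profile()`) and the NMB they induce
  (`net_monetary_benefit()`, `as_nmb_line()`);
* an **OLS meta-model** (`nmb_metamodel()`) that turns decision-model
  output triples $(p, \Delta H, \Delta C)$ into linear
  $\Delta H(p)$/$\Delta C(p)$ functions, with `coef()`, `predict()`,
  `summary()`, `residuals()` and `plot()` methods, and a **break-even
  solver** (`break_even()`) for the uptake level at which
  $\mathrm{NMB}(p) = 0$;
* **static values** (`current_value()`, `perfect_value()`,
  `actual_value()`, `net_value_of_strategy()`) and **dynamic discounted
  streams** (`current_value_stream()`, `actual_value_stream()`, ...)
  with linear diffusion paths and both first-year discount conventions;
* a packaged **MammaPrint case study** (`mammaprint_inputs()`,
  `mammaprint_static_table()`, `mammaprint_current_value_table()`,
  `mammaprint_strategy_value_table()`, `mammaprint_headlines()`);
* declarative **YAML/JSON scenario configs** (`load_scenario()`,
  `run_scenario()`), CSV/JSON table writers, plots, and a small CLI
  (`run_cli()`; wrapper script in `inst/cli/voimp.R`).

## Worked example

MammaPrint is a 70-gene breast-cancer recurrence test guiding who can
forgo adjuvant chemotherapy. Decision-model outputs at 3%, 50% and 92%
clinician uptake show costs falling and benefits rising with
implementation:

```r
library(voimp)
inp <- mammaprint_inputs()
fit <- nmb_metamodel(inp$triples)
fit
#> Linear meta-model of marginal incremental costs and benefits
#>   dH(p) = 0.1662 p + -0.006018   (R-squared 0.997)
#>   dC(p) = -860 p + 1996   (R-squared 0.979)
#>   fitted to 3 decision-model runs, p in [0.03, 0.92]

as_nmb_line(as_linear_profile(fit), inp$threshold)
#> NMB(p) = 4184 p - 2116 per patient

break_even(fit, inp$threshold)
#> Break-even implementation level: 0.5057 (NMB > 0 from 51%)
```

The positive NMB slope means increasing returns to scale, and the test
only pays its way once more than half the eligible women receive it.
Below 51% uptake each treated patient is a net loss at €20,000/QALY —
the per-patient NMB at 20% uptake is $4184 \times 0.2 - 2116 =
-1279$ €. Over a 15-year diffusion from 9% uptake:

```r
mammaprint_headlines()
#> NMB(p) = 4184 p - 2116 per patient
#> Break-even uptake: 50.57% (first whole percent with NMB > 0: 51%)
#> Cumulative discounted loss, years 1-7: -12,896,324 (= 644.8 QALYs at the threshold)
#> 15-year current value totals: constant 103,239,942, varying 26,390,541
#> 15-year strategy value totals: constant 6,687,834, varying 7,381,619 (difference 693,785)
```

Read: conventional (constant-NMB) accounting values 15 years of
diffusion at €103.2m; accounting for uptake-dependent marginal values
cuts that to €26.4m, with the first seven years a €12.9m discounted
loss — resources that could have bought ~645 QALYs elsewhere in the
health system. An uptake-raising strategy (+3 percentage points each
year) is worth €693,785 *more* under varying NMB, because it speeds the
climb through the loss-making region. Full per-year tables:
`mammaprint_current_value_table()` (year 1 discounted) and
`mammaprint_strategy_value_table()` (year 1 undiscounted) — the
discount convention is an explicit, logged part of every analysis
because the two conventions differ by a uniform factor $1+r$.

### From the shell

```sh
Rscript inst/cli/voimp.R casestudy --output-dir out/            # tables + summary + plots
Rscript inst/cli/voimp.R fit --input inst/extdata/mammaprint_marginals.csv
Rscript inst/cli/voimp.R dynamic --config inst/extdata/mammaprint_current_value.yaml --output-dir out/
```

Configs are YAML or JSON; see `?load_scenario` for the schema
(threshold, profile — constant/linear/tabulated coefficients or
`fit:`-from-CSV —, static block, dynamic block with diffusion,
strategy offset, cost stream, rate and convention).

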