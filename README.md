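# funcresp

Comparative functional-response analysis for no-replacement predation
trials, for ecologists quantifying and comparing predator feeding
pressure — e.g. between sexes of a size-dimorphic fish, across
temperatures, or between reproductive states.

A predator's functional response links feeding rate to prey density. The
Type-II form has two parameters: the attack rate *a* (search efficiency)
and the handling time *h* (time per prey item), with maximum feeding rate
1/(*h·T*) for a trial of duration *T*. Laboratory trials usually do not
replace eaten prey, so density declines within the trial; **funcresp**
fits Rogers' random-predator equation, which corrects for depletion:

    Ne = N0 * (1 - exp(a * (Ne * h - T)))

solved in closed form with the principal branch of the Lambert W
function, `Ne = N0 - W0(a*h*N0*exp(-a*(T - h*N0)))/(a*h)`, with a
bracketing root-finder taking over where the W argument would overflow.

The package implements the standard three-step comparative procedure:

1. **Type determination** — `classify_fr_type()`: binomial logistic
   regression of proportion eaten on density; a significantly negative
   first-order term indicates Type II.
2. **Fitting** — `fit_rogers()`: binomial maximum likelihood for
   (*a*, *h*) with standard errors, Z statistics and p-values;
   broom-style `tidy()`/`glance()`, `predict()`, `confint()`,
   `autoplot()`.
3. **Comparison** — `juliano_compare()`: indicator-variable difference
   test on Δ*a* and Δ*h* between groups (`juliano_pairwise()` adds
   Holm-adjusted letters across >2 groups); `bootstrap_fr()`:
   non-parametric bootstrap 95% confidence bands around the fitted
   curve; `overlap_verdict()` reads two bands per density.

Prey-size selection statistics (`nondepleted_filter()`,
`small_vs_large_test()`, `temperature_anova()` with Tukey letters,
`biomass()`) and a synthetic trial generator
(`simulate_trials()`, `simulate_study_design()`) emulating a full
factorial sex × temperature × prey-size × pregnancy design round out the
pipeline, which `run_fr_pipeline()` drives end to end. All user-facing
functions take data frames and return tibbles.

## Worked example

Simulate one group of 1-hour trials on the doubling density ladder
(truth: *a* = 1.5, *h* = 0.08), fit, and classify:

```r
library(funcresp)

tr  <- simulate_trials(a = 1.5, h = 0.08, densities = c(2, 4, 8, 16, 32, 64),
                       replicates = 5, seed = 42)
fit <- fit_rogers(tr)
fit
#> Rogers random-predator Type-II fit (binomial MLE)
#>   attack rate   a = 1.354  (SE 0.238, z = 5.69, p = 1.24e-08)
#>   handling time h = 0.06275  (SE 0.00782, z = 8.02, p = 1.05e-15)
#>   max feeding rate 1/(h*t) = 15.9 prey per trial; logLik = -56.2901; n = 30 trials

classify_fr_type(tr)
#> Functional response type test (binomial GLM on density)
#>   first-order term: -0.03215  (p = 1.94e-15, alpha = 0.05)
#>   inferred type:    type_II
```

The estimates sit within sampling error of the truth, the negative
first-order term correctly flags a Type-II response, and 1/(*h·T*) ≈ 16
prey per hour is the fitted ceiling on consumption. Comparing against a
slower-handling group tests the parameters directly:

```r
males <- simulate_trials(a = 0.8, h = 0.16, densities = c(2, 4, 8, 16, 32, 64),
                         replicates = 5, seed = 43)
juliano_compare(tr, males, labels = c("female", "male"))
#> Juliano difference test: female vs male (differences are male minus female)
#>   delta a = -0.4227  (SE 0.364, z = -1.16, p = 0.245)
#>   delta h = +0.1301  (SE 0.031, z = 4.2, p = 2.72e-05)
```

The male handling time is significantly higher (Δh > 0); the attack-rate
difference is not resolved at this replication. A bootstrap band around
the female curve (`bootstrap_fr(tr, n_boot = 300, seed = 1)`) gives
pointwise 95% envelopes, e.g. 1.21–1.61 prey eaten at density 2.

The full factorial pipeline, from simulation through selection
statistics, is one call:

```r
report <- run_fr_pipeline(seed = 1, n_boot = 300)
report$fits          # per-group type test + (a, h) + max feeding rate
report$comparisons   # sex, temperature and pregnancy contrasts
report$selection     # prey-size selection report per sex
```

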