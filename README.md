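# edcrowd

Stochastic population modelling of emergency-department (ED) crowding.

ED occupancy is volatile: the number of patients present swings with
strong daily and weekly cycles and spikes far above its mean. `edcrowd`
models the momentary occupancy $n(t)$ as a birth–death population process
— arrivals at a time-varying flux $f(t)$ (patients/hour), exits at a
per-capita rate $\beta(t)$ (1/hour) — with two noise channels on top of
the mean-field balance $d\bar n/dt = f - \beta\bar n$:

$$\frac{dn}{dt} = f(t) - \beta(t)\bigl[1+\xi_2(t)\bigr]n(t)
  + \sigma_1\sqrt{f(t)+\beta(t)n(t)}\,\xi_1(t)$$

where $\xi_1$ is demographic (individual-level) white noise of magnitude
$\sigma_1$ and $\xi_2$ is systematic (environment-level) white noise of
magnitude $\sigma_2$ that multiplies everyone's exit rate. Despite having
only a handful of parameters, the model captures both the average weekly
cycle and the full occupancy distribution, including rare overcrowding
events, and makes the elasticity of overcrowding to management levers
(arrival volume, length of stay, service-side variability) directly
computable.

The package provides, for anyone studying patient flow or similar
service-system crowding:

* forward simulators: closed-form mean field, exact event-driven
  birth–death (the oracle for the demographic channel), and a compiled
  Euler–Maruyama Langevin integrator;
* a synthetic minute-resolution visit-log generator and a calibrated
  trapezoid weekly arrival profile, standing in for proprietary hospital
  records;
* crowding metrics from any visit log: hourly arrival/exit fluxes,
  momentary occupancy, patient hours $C=\int n\,dt$ per 8-hour shift,
  relative crowding $x = C_\text{shift}/\langle C\rangle$, cohort
  survival curves;
* two-stage estimation: day-group exit rates from the mean-field
  solution, then $(\sigma_1,\sigma_2)$ by grid maximum likelihood on
  hour-by-hour occupancy STDs, with Gaussian uncertainties;
* overcrowding analysis: tail probabilities at the severe (~120
  patients) and dangerous (~140) thresholds, and elasticity scans with
  common random numbers.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fits, `autoplot()` on every result type.

## Worked example

```r
library(edcrowd)

params <- ed_params()        # fitted exit rates and noise magnitudes
mean_exit_rate(params)       # 0.2549 /h  (day-weighted mean)
mean_length_of_stay(params)  # 3.92 h
mean_field_fixed_point(14, mean_exit_rate(params))
                             # 54.93 patients: long-run mean occupancy

# calibrated weekly arrival profile (flux mean 14, STD 8;
# induced occupancy mean ~55, STD ~27)
profile <- calibrate_profile(params, seed = 11)
autoplot(profile)

# synthetic study: 20 weeks of minute-resolution visits
log <- generate_visit_log(profile, params, n_weeks = 20, seed = 1)
shift_summaries(log) |> relative_crowding()

# overcrowding tails from 4000 simulated stationary weeks
ens <- simulate_stationary_week(profile, params, n_realizations = 4000,
                                seed = 2)
tail_probability(ens, 140)

# elasticity: +10% arrivals vs P(n > 120)
elasticity_scan(profile, params, "arrival_flux", deltas = c(0, 0.1),
                threshold = 120, n_realizations = 4000, seed = 3)
```

Output from the run above:

```
#> [1] 0.2548571
#> [1] 3.923767
#> [1] 54.93274
# tail_probability(ens, 140):
#> # A tibble: 1 × 4
#>   threshold n_samples     prob        se
#>       <dbl>     <int>    <dbl>     <dbl>
#> 1       140    672000 0.000671 0.0000316
# elasticity_scan(...):
#> # A tibble: 2 × 5
#>   delta    prob       se ratio ratio_se
#>   <dbl>   <dbl>    <dbl> <dbl>    <dbl>
#> 1   0   0.00844 0.000112  1      0
#> 2   0.1 0.0258  0.000193  3.05   0.0464
```

Read: under the fitted parameters the model puts the chance that an
on-the-hour occupancy reading exceeds 140 patients (dangerous
overcrowding) at about 0.07%, roughly 6 hours per year; raising the
arrival flux by 10% raises the mean occupancy by just 10% but triples
the probability of severe overcrowding — the tail is strongly
non-linear in the arrival volume.

Fitting the model back from data:

```r
fit <- ed_fit(log, seed = 4)   # two-stage: betas, then sigma grid MLE
tidy(fit)                      # six parameters with 1-STD half-widths
glance(fit)
autoplot(fit$noise_fit)        # the MSE surface
```

## Package layout

* `R/params.R`, `R/profile.R` — parameters, week conventions, trapezoid
  profiles and calibration
* `R/simulate.R`, `src/cores.cpp` — mean-field, exact birth–death and
  Langevin engines
* `R/visitlog.R` — synthetic visit-log generator and CSV/YAML I/O
* `R/metrics.R` — occupancy, fluxes, patient hours, survival,
  goodness of fit
* `R/estimate.R` — two-stage fit, `tidy()`/`glance()`
* `R/analysis.R`, `R/plots.R` — tails, elasticities, reports, plots
* `vignettes/ed-crowding-model.Rmd` — the model, its assumptions and
  numerical choices in detail
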