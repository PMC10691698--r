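---
title: "A stochastic population model of emergency-department crowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic population model of emergency-department crowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcrowd)
```

## The model

An emergency department (ED) is treated as a single well-mixed population:
patients arrive at a time-varying flux $f(t)$ (patients/hour) and each
patient present leaves with per-capita hazard $\beta(t)$ (1/hour), covering
both discharge and hospitalisation. The mean occupancy $\bar n(t)$ then
obeys the balance equation

$$\frac{d\bar n}{dt} = f(t) - \beta(t)\,\bar n(t),$$

whose solution relaxes, on the timescale $1/\beta \approx 4$ h, to a moving
equilibrium near $f(t)/\beta(t)$; with time-averaged rates the fixed point
is $n^\ast = \bar f / \bar\beta$. With the default exit rates
(Sunday 0.224, Monday–Thursday 0.244, Friday 0.280, Saturday 0.304 per
hour; day-weighted mean 0.2549) and a mean arrival flux of 14 patients/hour
this gives $n^\ast \approx 55$ patients and a typical length of stay of
$1/\bar\beta \approx 3.9$ h.

Crowding, however, is dominated by fluctuations, which enter through two
channels:

* **Demographic (individual-level) noise** from the discreteness and
  heterogeneity of patients. At the master-equation level this is the
  birth–death shot noise; in the diffusion limit it contributes
  $\sigma_1\sqrt{f + \beta n}\,\xi_1(t)$, with $\sigma_1 = 1$ for a pure
  Poisson process. $\sigma_1$ is left free so extra individual-level
  heterogeneity can inflate it.
* **Systematic (environment-level) noise** from staffing, equipment and
  procedural variability. It multiplies the exit rate of everyone present:
  $-\beta(t)\,\xi_2(t)\,n(t)$, magnitude $\sigma_2$.

The occupancy then follows the Langevin equation

$$\frac{dn}{dt} = f(t) - \beta(t)\bigl[1 + \xi_2(t)\bigr]\,n(t)
  + \sigma_1\sqrt{f(t) + \beta(t)n(t)}\;\xi_1(t),$$

where $\xi_1, \xi_2$ are independent zero-mean white noises with
$\langle\xi_i(t)\xi_i(t+\tau)\rangle = \sigma_i^2\delta(\tau)$.

## Time conventions

All weekly structure is anchored at **Sunday 07:00** (weekly hour 0).
Hourly bins are half-open $[h, h+1)$; a patient is present on
$[\text{arrival}, \text{departure})$, so departures at instant $t$ are not
counted at $t$. Shifts are morning 07–15, afternoon 15–23, night 23–07;
days switch at 07:00. The exit rate is piecewise constant over four day
groups — Sunday, midweek (Monday–Thursday), Friday, Saturday — matching
the Israeli workweek in which Friday–Saturday is the quiet weekend.

## Numerical integration

`simulate_langevin()` integrates the equation by Euler–Maruyama in the
Itô convention (the natural reading for an equation derived as a diffusion
approximation of the master equation). Each channel receives an
independent Gaussian increment of standard deviation $\sigma_i\sqrt{dt}$
per step. Two boundary safeguards keep trajectories physical: the
square-root argument is clamped at zero, and a post-step negative
occupancy is reflected to its absolute value. Since typical occupancy
($\approx 55$) is far from zero, the reflection fires essentially never at
the default parameters and introduces negligible bias.

The default step is $dt = 0.01$ h. The test suite verifies that halving
the step changes hourly ensemble means by well under 0.5%, and that the
noise-free integrator matches the closed-form mean-field solution to
better than 0.5% per hourly point.

`simulate_exact()` is the independent oracle: an event-driven Gillespie
simulation of the exact birth–death process (rates piecewise constant per
hour, with redraws at bin boundaries), valid for the demographic-only
model ($\sigma_1 = 1$, $\sigma_2 = 0$). For constant rates its stationary
law is Poisson($f/\beta$), and the tests require the Langevin stationary
histogram to agree with it to a Kullback–Leibler divergence below 0.02.

Stationary weekly ensembles (`simulate_stationary_week()`) start each
trajectory on the periodic mean-field orbit and discard a 24-hour warm-up
(about six relaxation times) before recording on-the-hour samples —
hourly-mark sampling mirrors how the occupancy statistics are recorded.
Ensemble spreads use the population STD convention (divide by $n$).

## The synthetic study

Real ED visit logs are proprietary, so `generate_visit_log()` produces
agent-level data with the same statistical structure:

* **Arrivals**: a nonhomogeneous Poisson process with the profile's hourly
  intensity, constant within each hour (the resolution at which arrival
  flux is defined).
* **Exits**: each patient carries hazard $\beta(t)$ updated hourly, with a
  shared multiplier $1 + \epsilon_k$, $\epsilon_k \sim N(0, \sigma_2)$,
  refreshed every hour and clamped below at zero — the agent-level
  counterpart of white systematic noise at 1-hour resolution, which
  affects everyone present equally.
* **Demographic inflation**: a Poisson process fixes $\sigma_1 = 1$, but
  the fitted value is 1.1. Independent hourly jitters on the arrival
  intensity (variance $(\sigma_1^2-1)/f$) and on the shared exit hazard
  (variance $(\sigma_1^2-1)/(\beta n)$) restore the missing variance so
  the diffusion-limit demographic variance is exactly
  $\sigma_1^2(f + \beta n)$. Channel-by-channel checks (flat profile,
  constant $\beta$) reproduce the target occupancy and arrival-count
  variances to within ~1.5%. $\sigma_1 < 1$ (anti-bunching) is not
  representable this way and is rejected.

Timestamps carry minute resolution; stays still open at the period end
are truncated there and flagged.

The **reference arrival profile** is calibrated, not copied: the weekly
flux is built from trapezoid day shapes (quiet night level, morning ramp,
daytime plateau, evening ramp) with a weekday shape on Sunday–Thursday
and a scaled copy on the weekend. `calibrate_profile()` matches the two
flux moments analytically (hourly flux is linear in the two levels) and
then picks the weekend scale by simulating small Langevin ensembles with
common random numbers, targeting the reference occupancy moments: flux mean
14 (STD 8) and hourly occupancy mean 55 (STD 27). Default breakpoints
place the ramp at 08:00–11:00, the plateau until 20:00 and the night level
from 01:00; exact peak timing is a calibration output, not a claim about
the source data.

What the generator deliberately omits: patient covariates, revisits, the
discharge/hospitalisation split, annual trends and seasonality,
low-frequency drifts, and catastrophe bursts. Passing tests therefore
show that the pipeline recovers the parameters of *this* generative
process, not that real data are free of those further structures.

## Two-stage estimation

Stage one (`fit_betas()`) fits the four day-group exit rates by least
squares between the mean-field weekly orbit (driven by the empirical
hourly arrival flux, with a periodic initial condition) and the observed
per-weekly-hour occupancy means — a simultaneous four-parameter fit,
since the orbit couples adjacent days through its initial condition.

Stage two (`noise_mle()`) estimates $(\sigma_1, \sigma_2)$ by grid search:
each candidate is scored by the mean squared error between the model's
hour-by-hour ensemble STD $S(\sigma, t_i)$ and the data's $S_i$ across the
168 weekly hours, which under a Gaussian observation model is equivalent
to maximum likelihood; the fitted observation variance is
$p^2 = \mathrm{MSE}(\sigma^\ast)$. The default grid is deliberately
two-pass: a coarse grid ($\sigma_1 \in [0.6, 1.6]$ step 0.1,
$\sigma_2 \in [0.05, 0.75]$ step 0.1) followed by one refinement at step
0.025 around the coarse argmin. A single dense grid at the final
resolution would cost three orders of magnitude more simulation for no
change in the argmin, because common random numbers (the same seed at
every grid point) make the MSE surface smooth enough that the coarse
argmin localises the optimum to one cell. An argmin on the grid boundary
raises a classed warning rather than an error, so the surface remains
inspectable.

Uncertainties follow the Gaussian profile construction: along each
parameter axis the likelihood is
$L(\sigma_i) = C\exp[-\tfrac{n}{2}\,\mathrm{MSE}(\sigma_i)/\mathrm{MSE}(\sigma^\ast)]$,
and a quadratic fit of the MSE profile near its minimum yields a Gaussian
whose STD is the reported half-width (for a quadratic profile
$\mathrm{MSE} = \mathrm{MSE}^\ast(1 + (\sigma - \sigma^\ast)^2/w^2)$ this
is exactly $w/\sqrt{n}$). The same construction provides the exit-rate
intervals from the curvature of their squared-error profile.

Two estimation caveats, visible on synthetic data:

* The MSE surface has a shallow valley trading $\sigma_1$ against
  $\sigma_2$ (both inflate hourly STDs, with different occupancy
  dependence), so $\sigma_1$ is recovered to about $\pm 0.1$ rather than
  to the grid resolution.
* The agent-level generator and the Langevin model are not bit-identical
  physics: hourly-held multiplicative jitter integrates slightly
  differently from white noise, and the hazard jitter has a small Jensen
  effect, so refitting regenerated data reproduces parameters to a few
  percent — the practical idempotence the tests assert — rather than to
  the (much narrower) curvature-based intervals, which describe
  within-model statistical error only.

## Overcrowding analysis

`tail_probability()` pools on-the-hour samples across the whole week (a
`shifts` filter is available) and reports the fraction above a threshold
with its binomial standard error. The thresholds 120 and 140 patients are
the ED-specific equivalents of the top two crowding classes (severe and
dangerous). `patient_hours_distribution()` and `relative_tail()` cover
the relative view, $x = C_\text{shift}/\langle C\rangle$ over the ten most
crowded weekly shifts (Sunday–Thursday, morning and afternoon).

`elasticity_scan()` perturbs one knob — uniform flux scaling, minutes
added to every day group's $1/\beta$, or scaling of $\sigma_2$ — and
reports $P(n > n_s)$ relative to baseline, with common random numbers
across deltas so the ratio curves are smooth. The scan reproduces the
model's central management insight: the mean occupancy responds linearly
to the arrival flux, but the overcrowding tail responds super-linearly
(a +10% flux roughly triples $P(n>120)$), and shaving minutes off the
length of stay is far more effective against the tail than damping the
systematic noise.

## Problem sizes and reproducibility

Headline quantities in `scripts/acceptance.R` use $10^4$ week
realizations per ensemble, a 200-week synthetic study, and the default
two-pass grid (500 realizations per coarse point, 800 per refinement
point). The test suite exercises the same code paths at smaller sizes
(1,200–4,000 realizations, 40–200 week studies, refinement step 0.05 in
the multi-seed loops) chosen so that Monte-Carlo error stays comfortably
inside each assertion's tolerance. Every stochastic function takes a
`seed` and is bit-reproducible given it; the compiled cores draw from R's
RNG stream, so `set.seed()` governs everything.

## Known limitations

The model has no waiting-time or bed-capacity structure, no annual
seasonality or long-term demand growth, no exogenous catastrophe bursts,
and no explicit staff dynamics; $\beta$ absorbs all service-side state.
The exact simulator covers the demographic channel only — multiplicative
environmental noise has no finite-rate birth–death counterpart here, so
Langevin ensembles are the primary engine whenever $\sigma_2 > 0$.
Colored (finite-correlation) noise and a Fokker–Planck solver are out of
scope; ensembles of realizations stand in for the latter.
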