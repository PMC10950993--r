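---
title: "A Moran model of tumour growth, resistance and treatment scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Moran model of tumour growth, resistance and treatment scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(morantx)
library(ggplot2)
```

`morantx` models a tumour as a fixed-size population of `N` cells of three
types — healthy (`h`), cancerous (`c`) and a drug-resistant mutant clone
(`m`) — evolving by a discrete-time Moran birth–death process. The package
exists to ask a scheduling question: when a resistant clone can arise by
driver mutation, how do maximum-tolerated-dose (MTD), early, dual, sustained
low-dose, and pharmacokinetically waning treatments compare, and what can be
calibrated from ordinary tumour-growth curves?

## The birth–death process

Each timestep is one cell division: one cell is chosen to reproduce with
probability proportional to its count times its fitness, and one cell is
independently chosen to die with probability proportional to its count alone;
the dying cell is replaced by the offspring, so `N` is constant. Writing
`W = N_h f_h + N_c f_c + N_m f_m`, the probability that, say, a cancer cell
replaces a healthy cell in one step is

$$P(N_c \to N_c + 1,\; N_h \to N_h - 1) \;=\;
  \frac{N_c f_c}{W}\cdot\frac{N_h}{N},$$

and similarly for every ordered pair of types; same-type birth/death pairs
produce no change. `transition_probabilities()` returns the full ten-event
categorical distribution, which always sums to one.

Driver mutation enters through a single probability `r_m`: each cancer-cell
birth is, with probability `r_m`, a mutant birth instead, so the marginal
mutation probability per step is `r_m N_c f_c / W`. There is no
back-mutation, healthy cells never mutate, and a single mutant clone stands
in for the tumour's resistant subpopulation. With `r_m = 0` the states
`N_c = 0` and `N_c = N` are absorbing; with `r_m > 0` only the all-healthy
and all-mutant states absorb.

```{r single-run}
p <- moran_params(f_c = 1.1, f_m = 3, r_m = 0.01)
tr <- simulate_moran(N = 1000, M = 20000, p,
                     init = moran_init(1000, cancer = 100), seed = 1)
autoplot(tr)
```

The trajectory above shows *stochastic tunneling*: the mutant clone, seeded
by rare mutation events out of the growing cancer, reaches fixation before
the original cancer does. Simulations start from 10% cancer cells unless
stated otherwise, the initial condition used throughout the growth and
tunneling experiments.

## Treatment as a fitness penalty

A treatment course reduces the reproductive fitness of the targeted cancer
clones (never of healthy cells, and never their death rate): while active, a
course with efficacy `eff_c` turns `f_c` into `f_c (1 - eff_c)`. Two
activity profiles are supported, per course:

* **constant** — full efficacy on a window `[t_start, t_start + t_length]`;
* **waning** — efficacy `eff · 2^{-(t - t_start)/t_{1/2}}` for all
  `t ≥ t_start`, the first-order pharmacokinetic decay of a drug with
  half-life `t_{1/2}`.

When several courses are active at once (repeated waning doses, overlapping
windows) their contributions add linearly per clone and saturate at
efficacy 1 — the combination rule of linear pharmacokinetics with effect
saturation. The paper-shaped regimen of weekly antibody doses is available
as `dose_regimen()`; `days_to_divisions()` maps clock time to divisions at
`N/8` divisions per hour (Ehrlich-like cells divide every ~8 h, so one
division takes `8/N` hours).

`preset_schedule()` builds the five named strategies compared in the
experiments: `mtd` (single high dose after mutants are expected, default
efficacies 0.8 on the cancer and 0.4 on the mutant clone, window 5000
divisions), `early_mtd` (the same course before mutants arise), `dual`
(first target the mutant, then the cancer), `sustained` (efficacy scaled by
1/5 — or 1/3 in the two-parameter scans — with the window stretched), and
`waning` (half-life 5000 divisions). The strategy-comparison fitnesses and
windows are reconstructions where the source figures leave them
unspecified; every one of them is an explicit argument.

```{r strategies, fig.height = 4.5}
strategies <- list(none = treatment_schedule(),
                   mtd = preset_schedule("mtd", t_start = 3000,
                                         t_length = 2500),
                   early = preset_schedule("early_mtd", early_start = 200,
                                           t_length = 2500))
rep <- compare_strategies(strategies, N = 200, M = 6000, p,
                          n_total = 50, seed = 1)
plot_strategies(rep)
tidy(rep)
```

Strategy arms share replicate seeds by default (a paired design), so
between-arm contrasts are not diluted by between-replicate noise.

## The expectation recursion

Averaging the event distribution at each state gives a deterministic
mean-field recursion over real-valued counts (`expected_trajectory()`):

$$\Delta E[N_h] = \frac{N_h f_h}{W} - \frac{N_h}{N},\qquad
  \Delta E[N_c] = (1 - r_m)\frac{N_c f_c}{W} - \frac{N_c}{N},\qquad
  \Delta E[N_m] = \frac{N_m f_m + r_m N_c f_c}{W} - \frac{N_m}{N}.$$

With `r_m = 0` and no mutants this collapses to the classical two-type form
`E[N_{c,n} | N_{c,n-1}] = N_{c,n-1} + N_{c,n-1} f_c / (N_{c,n-1}(f_c - f_h)
+ N f_h) - N_{c,n-1}/N`. It is exact for one step (a tested identity) but
not for the full trajectory: the mean field never absorbs, while the
stochastic process does. In practice it tracks the ensemble mean closely
when every nonzero initial count is at least ~10% of `N`; below that, the
ensemble mean is dragged down by replicates lost to early extinction, and
the returned object carries `valid_init = FALSE` as a warning. Counts are
propagated without rounding — the recursion is a mean, not a state.

```{r mean-field}
es <- simulate_ensemble(100, 300, moran_params(f_c = 1.5),
                        init = moran_init(100, cancer = 20),
                        n_total = 500, seed = 2)
ex <- expected_trajectory(100, 300, moran_params(f_c = 1.5),
                          init = moran_init(100, cancer = 20))
autoplot(es) +
  geom_line(data = ex, aes(division_index, n_cancer),
            linetype = 2, colour = "black")
```

## Experiments

* `estimate_tunneling()` reports the binomial proportion of replicates in
  which the mutant fixates within `M` divisions. At the study conditions
  (`N = 1000`, `M = 20000`, `f_c = 1.1`, `r_m = 0.01`, 10% initial cancer)
  the probability is ≈96.5% for `f_m = 3` and ≈0% for `f_m = 1.5`.
* `scan_fixation_regions()` maps fixation outcomes over an `(f_m, f_c)`
  grid; cells are classed by the majority outcome among fixating
  replicates. `fixation_boundary()` extracts the ratio `f_c/f_m` at which
  mutant fixation stops being the majority outcome — the 50%-tunneling
  contour, ≈0.6 at high fitnesses. The contour, rather than the raw edge of
  the classified region, is used because a single stray fixation among
  `n_total` replicates flips a cell's class without representing a winning
  region; the contour is stable in both `N` and `n_total`.
* `min_fitness_curve()` finds, per horizon `M`, the smallest `f_c` whose
  1000-replicate ensemble mean exceeds `0.5N` starting from one cancer
  cell. A lineage gains at most one cell per division, so horizons below
  `N/2` are infeasible; the feasibility asymptote for `N = 100` sits near
  67–70 divisions, the scale predicted by the harmonic sum
  `\(\sum_{k=1}^{N/2} N/(N-k) \approx 69.8\)` for an infinitely fit clone.
  The ensemble-mean reading of "exceeds 50%" follows the surrounding
  experiments; a single-run criterion would be the natural alternative and
  is deliberately not mixed in.
* `scan_treatment()` grids the mutation rate against the anti-mutant
  efficacy (`f_m = 1.6` by default) and reports how often the mutant clone
  reaches `0.5N` under a chosen strategy preset.

## Calibration to growth curves

Fitting follows a two-stage exhaustive grid search minimising the RMSE
between the expectation model's tumour burden `(N_c + N_m)/N` and observed
sizes, linearly interpolated at the observation times (`N/8` divisions per
hour; sizes are proportions of a user-chosen carrying capacity `N`, the
paper-style visual extrapolation of the data scale being outside the model):

1. `fit_growth()` scans `(f_c/f_h, f_m/f_h, r_m)` on the vehicle arm. The
   reference fitness grid is 1–2 in steps of 0.001; desk-scale defaults are
   coarser and every grid is an argument. `r_m` defaults to a logarithmic
   grid `10^{-9}–10^{-3}`, covering reported driver-mutation rates with
   headroom. Ties break to the first grid point in scan order.
2. `fit_treatment()` holds stage-1 parameters fixed and scans
   `(eff_c, eff_m)` for a regimen of superposed waning doses (reference
   grid 0–100% in 0.1% steps). When mutants are negligible over the
   observation window the RMSE surface is flat along `eff_m`; the fit
   flags this (`eff_m_identifiable = FALSE`) rather than reporting a
   spuriously precise value. Stage-1 fits likewise expose the RMSE profile
   over `(f_m, r_m)`, which on vehicle data alone forms a ridge — those two
   parameters trade off and are not separately identifiable.

`tidy()`, `glance()`, `augment()` and `autoplot()` follow broom/ggplot2
conventions; the full RMSE surface is kept on the fit object for
identifiability diagnostics.

## Synthetic data

`synth_growth_spec()` + `generate_growth_series()` emulate the shape of the
weekly-dosed antibody (trastuzumab-style) mouse experiment used for
calibration: twice-weekly tumour measurements over 35 days, four weekly
doses from day 0, drug half-life 5.8 days, 8-hour division time, and
default true parameters at the vehicle-fit values (`f_c/f_h = 1.033`,
`f_m/f_h = 1.289`, `r_m = 1.1×10^{-6}`, `eff_c = 0.052`). Measurement noise
is multiplicative Gaussian (`size·(1 + ε)`, `ε ~ N(0, σ²)`, truncated at 0)
with `σ = 0.05`, a conventional model for caliper error; the real
experiment's mouse-to-mouse random effects are deliberately not emulated.
Generated series come from the expectation model, not stochastic runs, so
round-trip tests of the fitting pipeline have an exact σ = 0 limit: fitting
noiseless output recovers on-grid truth with zero RMSE. Under σ = 0.05 and
the twice-weekly design, Monte-Carlo recovery of `f_c/f_h` is unbiased with
a spread (sd) of about 0.011 — the design, not the optimiser, limits the
precision. What passing these tests shows is that the pipeline inverts its
own model; it does not validate the model against real tumours.

## Numerical choices and problem sizes

* The stochastic engine and the recursion are implemented in C++ (Rcpp);
  each replicate consumes exactly two uniform draws per step from R's RNG,
  so results are reproducible from a single seed. Ensembles derive one
  logged sub-seed per replicate, making replicates independent and
  pairable across strategy arms.
* Absorbed trajectories early-exit and are padded to length `M + 1`, so
  ensemble statistics are defined at every index.
* Whether the reproducer can also be the dier is unspecified in the usual
  verbal description; self-replacement is allowed, which reproduces the
  product-form probabilities exactly. A cancer cell that reproduces with
  mutation while also dying yields `N_c − 1, N_m + 1`.
* Treatment efficacies are evaluated at the pre-step division index;
  constant windows include both endpoints.
* Documented problem sizes: tunneling and region scans run at `N = 1000`,
  `M = 20000` (the study conditions) with 1000 and 100 replicates
  respectively; unit tests use smaller populations (30–500) chosen so each
  property is resolved well inside Monte-Carlo error.

## Limitations

Space, cell cycle structure, resistance costs, and drug toxicity are all
outside the model; the population size is constant, so "growth" is always
relative composition against carrying capacity `N`. The mean-field
recursion misstates long-horizon behaviour near absorbing states, and
grid-search calibration provides no uncertainty quantification — the RMSE
surfaces are exported precisely so users can see the ridges where
parameters are not identifiable.
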