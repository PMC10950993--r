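#' Specify a synthetic tumour-growth experiment
#'
#' Describes a two-arm (vehicle / treated) growth experiment with the shape of
#' a weekly-dosed antibody study in mice: tumour burden sampled twice weekly
#' over the horizon, four weekly doses from day 0 with a 5.8-day drug
#' half-life, cells dividing every 8 hours (so `N/8` divisions per hour).
#' Default true parameters are the vehicle-fit values from that setting
#' (`f_c/f_h = 1.033`, `f_m/f_h = 1.289`, `r_m = 1.1e-6`, `eff_c = 0.052`)
#' and measurement noise is multiplicative normal with `sigma = 0.05`, a
#' conventional error model for caliper measurements.
#'
#' @param N Carrying capacity (Moran population size).
#' @param f_c,f_m,r_m True growth parameters (healthy fitness 1).
#' @param eff_c,eff_m True peak dose efficacies.
#' @param init_prop Initial tumour proportion of `N`.
#' @param horizon_days Length of the experiment.
#' @param sample_every_days Sampling interval (3.5 = twice weekly).
#' @param n_doses,dose_interval_days,first_dose_day,t_half_days Dose regimen.
#' @param sigma Multiplicative noise standard deviation (0 = noiseless).
#' @param seed Seed for the noise draws.
#' @return A `synth_spec` list.
#' @export
synth_growth_spec <- function(N = 1000, f_c = 1.033, f_m = 1.289,
                              r_m = 1.1e-6, eff_c = 0.052, eff_m = 0.052,
                              init_prop = 0.1, horizon_days = 35,
                              sample_every_days = 3.5, n_doses = 4,
                              dose_interval_days = 7, first_dose_day = 0,
                              t_half_days = 5.8, sigma = 0.05, seed = 1L) {
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (horizon_days <= 0) abort("`horizon_days` must be positive")
  last_dose <- first_dose_day + (n_doses - 1) * dose_interval_days
  if (n_doses > 0 && last_dose > horizon_days) {
    abort("dose times must lie within the horizon")
  }
  structure(list(N = N, f_c = f_c, f_m = f_m, r_m = r_m,
                 eff_c = eff_c, eff_m = eff_m, init_prop = init_prop,
                 horizon_days = horizon_days,
                 sample_every_days = sample_every_days,
                 n_doses = n_doses, dose_interval_days = dose_interval_days,
                 first_dose_day = first_dose_day, t_half_days = t_half_days,
                 sigma = sigma, seed = seed),
            class = "synth_spec")
}

#' Generate synthetic vehicle and treated growth series
#'
#' Vehicle sizes come from the expectation model without treatment; treated
#' sizes apply the waning, superposed dose regimen. Noise (if `sigma > 0`) is
#' multiplicative: `size_obs = size_true * (1 + e)`, `e ~ N(0, sigma^2)`,
#' truncated at zero. Sizes are proportions of `N`. The true parameters are
#' returned alongside for parameter-recovery tests.
#'
#' @param spec A [synth_growth_spec()].
#' @return List with `vehicle` and `treated` growth-series tibbles
#'   (`time_days`, `size`, `label`) and `truth` (the spec's true parameters).
#' @examples
#' out <- generate_growth_series(synth_growth_spec(N = 200, sigma = 0,
#'                                                 horizon_days = 14))
#' out$vehicle
#' @export
generate_growth_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  N <- spec$N
  times <- seq(0, spec$horizon_days, by = spec$sample_every_days)
  div <- days_to_divisions(times, N)
  M <- as.integer(ceiling(max(div))) + 1L
  params <- moran_params(f_c = spec$f_c, f_m = spec$f_m, r_m = spec$r_m)
  init <- c(N * (1 - spec$init_prop), N * spec$init_prop, 0)
  sample_arm <- function(schedule, label) {
    tr <- expected_trajectory(N, M, params, init = init, schedule = schedule)
    burden <- (tr$n_cancer + tr$n_mutant) / N
    tibble(time_days = times,
           size = approx(tr$division_index, burden, xout = div)$y,
           label = label)
  }
  regimen <- if (spec$n_doses > 0) {
    dose_regimen(N, eff_c = spec$eff_c, eff_m = spec$eff_m,
                 n_doses = spec$n_doses,
                 interval_days = spec$dose_interval_days,
                 first_dose_day = spec$first_dose_day,
                 t_half_days = spec$t_half_days)
  } else {
    treatment_schedule()
  }
  vehicle <- sample_arm(NULL, "vehicle")
  treated <- sample_arm(regimen, "treated")
  if (spec$sigma > 0) {
    set.seed(spec$seed)
    noisy <- function(x) pmax(x * (1 + rnorm(length(x), 0, spec$sigma)), 0)
    vehicle$size <- noisy(vehicle$size)
    treated$size <- noisy(treated$size)
  }
  list(vehicle = vehicle, treated = treated,
       truth = spec[c("N", "f_c", "f_m", "r_m", "eff_c", "eff_m",
                      "init_prop", "t_half_days")])
}
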