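validate_growth_series <- function(data, require_sorted = TRUE) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort("a growth series must be a non-empty data frame")
  }
  if (!all(c("time_days", "size") %in% names(data))) {
    abort("a growth series needs columns `time_days` and `size`")
  }
  if (require_sorted && is.unsorted(data$time_days, strictly = TRUE)) {
    abort("`time_days` must be strictly increasing")
  }
  if (any(data$size < 0)) abort("`size` must be non-negative")
  invisible(data)
}

# RMSE between a precomputed expected tumour-burden curve and the data,
# with the model linearly interpolated at the observation times.
rmse_at <- function(traj_burden, div_coords, obs) {
  pred <- approx(x = seq_along(traj_burden) - 1, y = traj_burden,
                 xout = div_coords)$y
  sqrt(mean((pred - obs)^2))
}

burden_curve <- function(N, M, f_c, f_m, r_m, init_prop, smat, f_h = 1) {
  init <- c(N * (1 - init_prop), N * init_prop, 0)
  traj <- expected_traj_cpp(N, M, init, f_h, f_c, f_m, r_m, smat)
  (traj[, 2] + traj[, 3]) / N
}

#' RMSE between the expectation model and a growth series
#'
#' Computes the expected tumour burden `(N_c + N_m) / N` under the recursion,
#' linearly interpolates it at the observation times (converted to divisions
#' at `N/8` divisions per hour), and returns the root-mean-square residual
#' against the observed sizes. Sizes are proportions of the carrying capacity
#' `N`.
#'
#' @param data Growth series: tibble with `time_days` (strictly increasing)
#'   and `size` (proportion of `N`).
#' @param params A [moran_params()] object.
#' @param N Carrying capacity (total cell count of the Moran model).
#' @param schedule Optional `treatment_schedule` applied during the run.
#' @param init_prop Initial tumour proportion; defaults to the first
#'   observation.
#' @param M Simulation horizon in divisions; defaults to (just past) the last
#'   observation. Observations beyond an explicit `M` are an error.
#' @param hours_per_division Time mapping (default `8/N`).
#' @return The RMSE (non-negative scalar).
#' @examples
#' obs <- tibble::tibble(time_days = c(0, 7, 14), size = c(0.1, 0.15, 0.22))
#' rmse_objective(obs, moran_params(f_c = 1.1), N = 200)
#' @export
rmse_objective <- function(data, params, N, schedule = NULL,
                           init_prop = NULL, M = NULL,
                           hours_per_division = 8 / N) {
  # RMSE is symmetric in record order, so sortedness is not required here
  validate_growth_series(data, require_sorted = FALSE)
  div <- days_to_divisions(data$time_days, N, hours_per_division)
  if (is.null(M)) M <- as.integer(ceiling(max(div))) + 1L
  if (max(div) > M) abort("observations lie beyond the simulated horizon M")
  init_prop <- init_prop %||% data$size[1]
  bc <- burden_curve(N, M, params$f_c, params$f_m, params$r_m, init_prop,
                     schedule_matrix(schedule), f_h = params$f_h)
  rmse_at(bc, div, data$size)
}

new_moran_fit <- function(stage, estimates, grid, data, N, init_prop, M,
                          hours_per_division, schedule_fn, diagnostics) {
  structure(list(stage = stage, estimates = estimates,
                 rmse = estimates$rmse, grid = grid, data = data, N = N,
                 init_prop = init_prop, M = M,
                 hours_per_division = hours_per_division,
                 schedule_fn = schedule_fn, diagnostics = diagnostics),
            class = "moran_fit")
}

#' Fit growth parameters to an untreated (vehicle) series
#'
#' Stage-1 calibration: an exhaustive grid search minimising the RMSE of the
#' expectation model against the vehicle growth series, scanning the fitness
#' ratios `f_c/f_h` and `f_m/f_h` and the mutation probability `r_m`. The
#' reference grid for fitness ratios is 1 to 2 in steps of 0.001; the default
#' here is a coarser desk-scale grid, and all grids are explicit arguments.
#' Ties are broken by the first grid point encountered in row order of
#' `expand_grid(f_c, f_m, r_m)`.
#'
#' @param data Vehicle growth series (`time_days`, `size` as proportion of
#'   `N`).
#' @param fc_ratio,fm_ratio Grids of fitness ratios (healthy fitness is 1).
#' @param r_m Grid of mutation probabilities (default: logarithmic
#'   `10^-9 ... 10^-3`, covering literature driver-mutation rates with
#'   headroom).
#' @inheritParams rmse_objective
#' @return A `moran_fit` with broom methods: [tidy()] (parameter estimates),
#'   [glance()] (minimum RMSE, grid size, identifiability flag), [augment()]
#'   (data with fitted values). `$grid` holds the full RMSE surface;
#'   `$diagnostics$ridge` profiles RMSE over `(f_m, r_m)` — on typical vehicle
#'   data these two parameters trade off along a ridge and are not separately
#'   identifiable.
#' @examples
#' synth <- generate_growth_series(synth_growth_spec(N = 200, sigma = 0,
#'                                                   horizon_days = 10))
#' fit <- fit_growth(synth$vehicle, fc_ratio = seq(1, 1.1, by = 0.001),
#'                   fm_ratio = 1.289, r_m = 1.1e-6, N = 200)
#' tidy(fit)
#' @export
fit_growth <- function(data, fc_ratio = seq(1, 2, by = 0.01),
                       fm_ratio = seq(1, 2, by = 0.05),
                       r_m = 10^seq(-9, -3), N = 1000,
                       init_prop = NULL, hours_per_division = 8 / N) {
  validate_growth_series(data)
  grid <- tidyr::expand_grid(f_c = fc_ratio, f_m = fm_ratio, r_m = r_m)
  if (nrow(grid) == 0L) abort("empty parameter grid")
  div <- days_to_divisions(data$time_days, N, hours_per_division)
  M <- as.integer(ceiling(max(div))) + 1L
  init_prop <- init_prop %||% data$size[1]
  smat <- schedule_matrix(NULL)
  grid$rmse <- purrr::pmap_dbl(grid[c("f_c", "f_m", "r_m")],
    function(f_c, f_m, r_m) {
      rmse_at(burden_curve(N, M, f_c, f_m, r_m, init_prop, smat), div,
              data$size)
    })
  best <- which.min(grid$rmse)  # first minimum = scan-order tie-break
  est <- grid[best, ]
  ridge <- grid |>
    group_by(.data$f_m, .data$r_m) |>
    summarise(rmse = min(.data$rmse), .groups = "drop")
  new_moran_fit("growth", est, grid, data, N, init_prop, M,
                hours_per_division, schedule_fn = NULL,
                diagnostics = list(ridge = ridge))
}

#' Fit treatment efficacies to a treated series
#'
#' Stage-2 calibration: holding the stage-1 growth parameters fixed, scans
#' the efficacy pair `(eff_c, eff_m)` of a regimen of repeated waning doses
#' (superposed, capped at 1) against the treated growth series. The reference
#' efficacy grid is 0 to 100% in steps of 0.1%; the default here is the
#' coarser 1% step. When the mutant clone is negligible over the observation
#' window the RMSE surface is flat along `eff_m`; this is detected and
#' reported as `eff_m_identifiable = FALSE` in [glance()].
#'
#' @param data Treated growth series (`time_days`, `size`).
#' @param growth_fit Stage-1 `moran_fit` from [fit_growth()] (required).
#' @param dose_times_days Administration times, days.
#' @param t_half_days Drug half-life in days (default 5.8).
#' @param eff_c,eff_m Efficacy grids.
#' @inheritParams rmse_objective
#' @return A `moran_fit` (stage `"treatment"`) with the RMSE surface in
#'   `$grid`.
#' @export
fit_treatment <- function(data, growth_fit,
                          dose_times_days = c(0, 7, 14, 21),
                          t_half_days = 5.8,
                          eff_c = seq(0, 1, by = 0.01),
                          eff_m = seq(0, 1, by = 0.01),
                          init_prop = NULL, hours_per_division = NULL) {
  if (!inherits(growth_fit, "moran_fit") || growth_fit$stage != "growth") {
    abort("`growth_fit` must be a stage-1 fit from fit_growth()")
  }
  validate_growth_series(data)
  N <- growth_fit$N
  hours_per_division <- hours_per_division %||% growth_fit$hours_per_division
  g <- growth_fit$estimates
  div <- days_to_divisions(data$time_days, N, hours_per_division)
  M <- as.integer(ceiling(max(div))) + 1L
  init_prop <- init_prop %||% data$size[1]
  dose_div <- days_to_divisions(dose_times_days, N, hours_per_division)
  th_div <- days_to_divisions(t_half_days, N, hours_per_division)
  sched_fn <- function(ec, em) {
    do.call(treatment_schedule, lapply(dose_div, function(ts) {
      treatment_course(eff_c = ec, eff_m = em, t_start = ts,
                       mode = "waning", t_half = th_div)
    }))
  }
  grid <- tidyr::expand_grid(eff_c = eff_c, eff_m = eff_m)
  if (nrow(grid) == 0L) abort("empty efficacy grid")
  # precompute the superposed unit-efficacy decay profile once; each grid
  # point then only rescales it inside the recursion
  tt <- 0:(M - 1)
  decay <- rowSums(vapply(dose_div, function(ts) {
    ifelse(tt >= ts, 2^(-(tt - ts) / th_div), 0)
  }, numeric(M)))
  init <- c(N * (1 - init_prop), N * init_prop, 0)
  grid$rmse <- purrr::pmap_dbl(grid, function(eff_c, eff_m) {
    bc <- expected_burden_scaled_cpp(N, M, init, 1, g$f_c, g$f_m, g$r_m,
                                     decay, eff_c, eff_m)
    rmse_at(bc, div, data$size)
  })
  best <- which.min(grid$rmse)
  est <- dplyr::bind_cols(grid[best, ],
                          g[c("f_c", "f_m", "r_m")])
  # flat-surface diagnostic: does eff_m move the fit at all at the best eff_c?
  slice_m <- grid$rmse[grid$eff_c == grid$eff_c[best]]
  eff_m_identifiable <- length(slice_m) > 1 &&
    diff(range(slice_m)) > 1e-8
  new_moran_fit("treatment", est, grid, data, N, init_prop, M,
                hours_per_division, schedule_fn = sched_fn,
                diagnostics = list(eff_m_identifiable = eff_m_identifiable,
                                   dose_times_days = dose_times_days,
                                   t_half_days = t_half_days))
}

fit_params <- function(x) {
  moran_params(f_c = x$estimates$f_c, f_m = x$estimates$f_m,
               r_m = x$estimates$r_m)
}

fit_schedule <- function(x) {
  if (x$stage == "growth") NULL
  else x$schedule_fn(x$estimates$eff_c, x$estimates$eff_m)
}

#' Fitted expected growth curve
#'
#' Evaluates the expectation model at the fitted parameters on a time grid.
#'
#' @param x A `moran_fit`.
#' @param times_days Times at which to evaluate (defaults to a fine grid over
#'   the data range).
#' @return Tibble with `time_days` and `size` (fitted tumour proportion).
#' @export
fitted_curve <- function(x, times_days = NULL) {
  times_days <- times_days %||%
    seq(min(x$data$time_days), max(x$data$time_days), length.out = 200)
  div <- days_to_divisions(times_days, x$N, x$hours_per_division)
  bc <- burden_curve(x$N, x$M, x$estimates$f_c, x$estimates$f_m,
                     x$estimates$r_m, x$init_prop,
                     schedule_matrix(fit_schedule(x)))
  tibble(time_days = times_days,
         size = approx(seq_along(bc) - 1, bc, xout = div)$y)
}

#' @export
print.moran_fit <- function(x, ...) {
  cat("<moran_fit> stage:", x$stage, " RMSE =", format(x$rmse), "\n")
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_growth fitted parameters, one row per term.
#' @param x A `moran_fit`.
#' @param ... Unused.
#' @export
tidy.moran_fit <- function(x, ...) {
  est <- x$estimates[setdiff(names(x$estimates), "rmse")]
  tibble(term = names(est), estimate = unname(unlist(est[1, ])))
}

#' @describeIn fit_growth one-row fit summary.
#' @export
glance.moran_fit <- function(x, ...) {
  tibble(stage = x$stage, rmse = x$rmse, n_grid = nrow(x$grid),
         n_obs = nrow(x$data),
         eff_m_identifiable = x$diagnostics$eff_m_identifiable %||% NA)
}

#' @describeIn fit_growth observations with fitted values and residuals.
#' @export
augment.moran_fit <- function(x, ...) {
  fc <- fitted_curve(x, times_days = x$data$time_days)
  mutate(as_tibble(x$data), .fitted = fc$size,
         .resid = .data$size - fc$size)
}
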