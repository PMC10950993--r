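#' One step of the conditional-expectation recursion
#'
#' The exact one-step conditional expectation of the event distribution,
#' propagated over real-valued counts. With `W = sum_i N_i f_i`:
#' \deqn{\Delta E[N_h] = N_h f_h / W - N_h / N}
#' \deqn{\Delta E[N_c] = (1 - r_m) N_c f_c / W - N_c / N}
#' \deqn{\Delta E[N_m] = (N_m f_m + r_m N_c f_c) / W - N_m / N}
#' With `r_m = 0` and no mutants this reduces to the classical two-type
#' recursion `E[N_c' | N_c] = N_c + N_c f_c / (N_c (f_c - f_h) + N f_h) -
#' N_c / N`.
#'
#' @param state Real-valued counts `(n_healthy, n_cancer, n_mutant)` summing
#'   to `N`.
#' @param params A [moran_params()] object (effective fitnesses allowed).
#' @return The expected counts after one division (named numeric vector).
#' @examples
#' expected_step(c(90, 10, 0), moran_params(f_c = 5))
#' @export
expected_step <- function(state, params) {
  state <- as_state(state)
  N <- sum(state)
  f <- c(params$f_h, params$f_c, params$f_m)
  W <- sum(state * f)
  if (W <= 0) {
    abort("degenerate selection: all effective fitness weights are zero")
  }
  rm_ <- params$r_m
  d <- c(state[1] * f[1] / W,
         (1 - rm_) * state[2] * f[2] / W,
         (state[3] * f[3] + rm_ * state[2] * f[2]) / W) - state / N
  as_state(state + d)
}

#' Deterministic expected trajectory
#'
#' Iterates [expected_step()] `M` times with schedule-driven effective
#' fitnesses, giving the mean-field surrogate for the ensemble-mean
#' trajectory. The surrogate tracks the ensemble mean closely when every
#' nonzero initial count is at least ~10% of `N`; below that threshold the
#' ensemble mean is pulled down by replicates lost to stochastic extinction
#' and the attribute `valid_init` is set to `FALSE` as a warning flag. The
#' mean-field never absorbs, so it also departs from the stochastic model at
#' very long horizons.
#'
#' @inheritParams simulate_moran
#' @param init Initial counts; real values are allowed.
#' @return An `expected_trajectory` tibble (`division_index`, real-valued
#'   `n_healthy`, `n_cancer`, `n_mutant`, optional `time_hours`), with
#'   attributes `N`, `params`, `schedule` and `valid_init`.
#' @examples
#' expected_trajectory(100, 10, moran_params(f_c = 5),
#'                     init = moran_init(100, cancer = 10))
#' @export
expected_trajectory <- function(N, M, params,
                                init = moran_init(N, round(0.1 * N)),
                                schedule = NULL, hours_per_division = NULL) {
  stopifnot(M >= 1, N > 0)
  init <- as_state(init)
  if (any(init < 0) || abs(sum(init) - N) > 1e-9 * N) {
    abort("initial counts must be non-negative and sum to N")
  }
  traj <- expected_traj_cpp(N, as.integer(M), as.numeric(init),
                            params$f_h, params$f_c, params$f_m, params$r_m,
                            schedule_matrix(schedule))
  out <- traj_tibble(traj, hours_per_division)
  structure(out,
            class = c("expected_trajectory", class(out)),
            N = N, params = params, schedule = schedule,
            valid_init = all(init == 0 | init >= 0.1 * N))
}
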