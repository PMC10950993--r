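event_table <- function() {
  tibble(
    event = c("cancer_birth_healthy_death", "healthy_birth_cancer_death",
              "mutant_birth_healthy_death", "mutant_birth_cancer_death",
              "healthy_birth_mutant_death", "cancer_birth_mutant_death",
              "mutation_healthy_death", "mutation_cancer_death",
              "mutation_mutant_death", "no_change"),
    d_healthy = c(-1, 1, -1, 0, 1, 0, -1, 0, 0, 0),
    d_cancer  = c(1, -1, 0, -1, 0, 1, 0, -1, 0, 0),
    d_mutant  = c(0, 0, 1, 1, -1, -1, 1, 1, 0, 0)
  )
}

#' One-step event distribution of the Moran process
#'
#' The full categorical distribution over the ten possible birth/death events
#' at a state. The birth weight of type *i* is `N_i f_i / W` with
#' `W = sum_j N_j f_j`; the death weight of type *i* is `N_i / N`; a fraction
#' `r_m` of the cancer-birth weight is diverted to mutant offspring (the
#' `mutation_*` events), and same-type birth/death pairs collapse into
#' `no_change`. The marginal probability of a mutation event is therefore
#' `r_m N_c f_c / W`.
#'
#' Fitnesses may be the treatment-modified effective values (possibly 0 for a
#' fully blocked clone); pass the output of [effective_fitness()] through
#' `params` for a treated step.
#'
#' @param state Counts `(n_healthy, n_cancer, n_mutant)`, e.g. from
#'   [moran_init()].
#' @param params A [moran_params()] object (fitnesses may be effective values;
#'   zero is allowed for treated clones, but not all weights may vanish).
#' @return Tibble with columns `event`, `d_healthy`, `d_cancer`, `d_mutant`,
#'   `probability`; the probabilities sum to 1.
#' @examples
#' transition_probabilities(moran_init(100, cancer = 10),
#'                          moran_params(f_c = 5))
#' @export
transition_probabilities <- function(state, params) {
  state <- check_state(state)
  N <- sum(state)
  f <- c(params$f_h, params$f_c, params$f_m)
  if (any(f < 0)) abort("fitnesses must be non-negative")
  W <- sum(state * f)
  if (W <= 0) {
    abort("degenerate selection: all effective fitness weights are zero")
  }
  b <- state * f / W          # birth weights (h, c, m)
  d <- state / N              # death weights
  rm_ <- params$r_m
  ev <- event_table()
  ev$probability <- c(
    (1 - rm_) * b[2] * d[1],  # cancer birth / healthy death
    b[1] * d[2],              # healthy birth / cancer death
    b[3] * d[1],              # mutant birth / healthy death
    b[3] * d[2],              # mutant birth / cancer death
    b[1] * d[3],              # healthy birth / mutant death
    (1 - rm_) * b[2] * d[3],  # cancer birth / mutant death
    rm_ * b[2] * d[1],        # mutation, healthy dies
    rm_ * b[2] * d[2],        # mutation, cancer dies
    rm_ * b[2] * d[3],        # mutation, mutant dies
    (1 - rm_) * b[2] * d[2] + b[1] * d[1] + b[3] * d[3]  # no change
  )
  ev
}

#' Advance the Moran process by one timestep
#'
#' Samples one event from [transition_probabilities()] and applies it: the
#' dying cell is replaced by one offspring of the reproducing type (a mutant
#' offspring on mutation events). Counts change by at most one per type and
#' always sum to `N`.
#'
#' @inheritParams transition_probabilities
#' @return The new state (named numeric vector of 3 counts).
#' @examples
#' set.seed(1)
#' moran_step(moran_init(100, cancer = 10), moran_params(f_c = 5))
#' @export
moran_step <- function(state, params) {
  pr <- transition_probabilities(state, params)
  k <- sample.int(nrow(pr), 1L, prob = pr$probability)
  as_state(c(state[1] + pr$d_healthy[k],
             state[2] + pr$d_cancer[k],
             state[3] + pr$d_mutant[k]))
}

traj_tibble <- function(traj, hours_per_division = NULL) {
  out <- tibble(division_index = 0:(nrow(traj) - 1L),
                n_healthy = traj[, 1], n_cancer = traj[, 2],
                n_mutant = traj[, 3])
  if (!is.null(hours_per_division)) {
    out <- mutate(out, time_hours = .data$division_index * hours_per_division,
                  .after = "division_index")
  }
  out
}

#' Simulate one replicate of the Moran process
#'
#' Runs `M` sequential timesteps from the initial state, re-evaluating the
#' effective fitnesses from the treatment schedule at every step. The run
#' early-exits once the state is absorbing (all-healthy, all-mutant, or
#' all-cancer with `r_m = 0`) and pads the trajectory with the absorbed state
#' so every trajectory has `M + 1` rows. Given the same seed, configuration
#' and parameters the result is reproducible exactly.
#'
#' @param N Population size (constant).
#' @param M Number of cell divisions (timesteps).
#' @param params A [moran_params()] object.
#' @param init Initial state, e.g. [moran_init()]; defaults to 10% cancer.
#' @param schedule Optional `treatment_schedule`.
#' @param seed Optional integer seed for this replicate.
#' @param hours_per_division If non-`NULL`, a `time_hours` column is added
#'   (`8/N` maps divisions to hours for Ehrlich-like cells).
#' @return A `moran_trajectory` tibble with one row per division index
#'   `0..M`; attributes `N`, `params`, `schedule`, `seed` and `absorbed_at`
#'   (first absorbing index, or `NA`).
#' @examples
#' tr <- simulate_moran(100, 500, moran_params(f_c = 5),
#'                      init = moran_init(100, cancer = 10), seed = 1)
#' tail(tr)
#' @export
simulate_moran <- function(N, M, params, init = moran_init(N, round(0.1 * N)),
                           schedule = NULL, seed = NULL,
                           hours_per_division = NULL) {
  stopifnot(M >= 1, N >= 1)
  init <- check_state(init, N)
  if (!is.null(seed)) set.seed(seed)
  res <- moran_sim_cpp(as.integer(N), as.integer(M), as.integer(init),
                       params$f_h, params$f_c, params$f_m, params$r_m,
                       schedule_matrix(schedule))
  out <- traj_tibble(res$traj, hours_per_division)
  structure(out,
            class = c("moran_trajectory", class(out)),
            N = N, params = params, schedule = schedule, seed = seed,
            absorbed_at = if (res$absorbed_at < 0) NA_integer_
                          else res$absorbed_at)
}

make_replicate_seeds <- function(seed, n_total) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_total)
}

#' Simulate an ensemble of replicates
#'
#' Runs `n_total` independent replicates, each from its own derived seed, and
#' summarises them: per-step mean and standard deviation of each type's count,
#' plus a per-replicate record of the final state, fixation outcome and
#' whether the mutant clone ever reached half the population.
#'
#' @inheritParams simulate_moran
#' @param n_total Number of replicates.
#' @param seed Base seed; replicate seeds are drawn from it and logged in the
#'   `replicates` table.
#' @param replicate_seeds Optional explicit vector of per-replicate seeds
#'   (used for paired strategy comparisons); overrides `seed`.
#' @return A `moran_ensemble` object: list with `summary` (tibble of per-step
#'   `mean_*`/`sd_*`), `replicates` (tibble with `replicate`, `seed`,
#'   `final_*`, `fixated_type`, `fixation_index`, `mutant_reached_half`),
#'   and the run configuration.
#' @examples
#' es <- simulate_ensemble(100, 200, moran_params(f_c = 1.5),
#'                         init = moran_init(100, cancer = 20),
#'                         n_total = 50, seed = 1)
#' glance(es)
#' @export
simulate_ensemble <- function(N, M, params,
                              init = moran_init(N, round(0.1 * N)),
                              schedule = NULL, n_total = 100, seed = NULL,
                              replicate_seeds = NULL,
                              hours_per_division = NULL) {
  stopifnot(n_total >= 1)
  init <- check_state(init, N)
  seeds <- replicate_seeds %||% make_replicate_seeds(seed, n_total)
  stopifnot(length(seeds) == n_total)
  smat <- schedule_matrix(schedule)
  sum1 <- matrix(0, M + 1, 3)
  sum2 <- matrix(0, M + 1, 3)
  half <- N / 2
  final_mat <- matrix(0L, n_total, 3)
  fixated <- character(n_total)
  fix_idx <- rep(NA_integer_, n_total)
  m_half <- logical(n_total)
  for (k in seq_len(n_total)) {
    set.seed(seeds[k])
    res <- moran_sim_cpp(as.integer(N), as.integer(M), as.integer(init),
                         params$f_h, params$f_c, params$f_m, params$r_m, smat)
    tr <- res$traj
    sum1 <- sum1 + tr
    sum2 <- sum2 + tr * tr
    fixes <- c(healthy = match(N, tr[, 1]), cancer = match(N, tr[, 2]),
               mutant = match(N, tr[, 3]))
    if (all(is.na(fixes))) {
      fixated[k] <- "none"
    } else {
      fixated[k] <- names(fixes)[which.min(fixes)]
      fix_idx[k] <- as.integer(min(fixes, na.rm = TRUE)) - 1L
    }
    final_mat[k, ] <- tr[M + 1, ]
    m_half[k] <- any(tr[, 3] >= half)
  }
  replicates <- tibble(
    replicate = seq_len(n_total), seed = seeds,
    final_h = final_mat[, 1], final_c = final_mat[, 2],
    final_m = final_mat[, 3], fixated_type = fixated,
    fixation_index = fix_idx, mutant_reached_half = m_half)
  mean_mat <- sum1 / n_total
  var_mat <- pmax(sum2 / n_total - mean_mat^2, 0)
  sd_mat <- if (n_total > 1) sqrt(var_mat * n_total / (n_total - 1)) else
    matrix(0, M + 1, 3)
  summary <- tibble(
    division_index = 0:M,
    mean_healthy = mean_mat[, 1], mean_cancer = mean_mat[, 2],
    mean_mutant = mean_mat[, 3],
    sd_healthy = sd_mat[, 1], sd_cancer = sd_mat[, 2], sd_mutant = sd_mat[, 3]
  )
  if (!is.null(hours_per_division)) {
    summary <- mutate(summary,
                      time_hours = .data$division_index * hours_per_division,
                      .after = "division_index")
  }
  structure(list(summary = summary, replicates = replicates,
                 N = N, M = M, params = params, schedule = schedule,
                 n_total = n_total, seed = seed),
            class = "moran_ensemble")
}

#' @export
print.moran_ensemble <- function(x, ...) {
  cat("<moran_ensemble> ", x$n_total, "replicates, N =", x$N, ", M =", x$M, "\n")
  print(glance(x))
  invisible(x)
}

#' @describeIn simulate_ensemble per-replicate final states as a tibble.
#' @param x A `moran_ensemble`.
#' @param ... Unused.
#' @export
tidy.moran_ensemble <- function(x, ...) x$replicates

#' @describeIn simulate_ensemble one-row summary: fixation proportions and
#'   mean final counts.
#' @export
glance.moran_ensemble <- function(x, ...) {
  r <- x$replicates
  tibble(n_total = x$n_total,
         prop_healthy_fix = mean(r$fixated_type == "healthy"),
         prop_cancer_fix = mean(r$fixated_type == "cancer"),
         prop_mutant_fix = mean(r$fixated_type == "mutant"),
         prop_mutant_half = mean(r$mutant_reached_half),
         mean_final_cancer = mean(r$final_c),
         mean_final_mutant = mean(r$final_m))
}
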