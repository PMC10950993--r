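#' Estimate the probability of stochastic tunneling
#'
#' Tunneling is the event that the mutant clone reaches fixation (`N_m = N`)
#' within `M` divisions, before the original cancer does. Runs `n_total`
#' replicates and reports the binomial estimate with its standard error and
#' the per-replicate outcome labels.
#'
#' @inheritParams simulate_ensemble
#' @return A `tunneling_result`: list with `estimate`, `se`, `n_total` and an
#'   `outcomes` tibble (labels `mutant-fixated`, `cancer-fixated`, `none`).
#' @examples
#' tn <- estimate_tunneling(100, 2000, moran_params(f_c = 1.1, f_m = 3,
#'                                                  r_m = 0.01),
#'                          n_total = 20, seed = 1)
#' tn$estimate
#' @export
estimate_tunneling <- function(N, M, params,
                               init = moran_init(N, round(0.1 * N)),
                               schedule = NULL, n_total = 1000, seed = NULL) {
  es <- simulate_ensemble(N, M, params, init = init, schedule = schedule,
                          n_total = n_total, seed = seed)
  r <- es$replicates
  label <- dplyr::case_match(r$fixated_type,
                             "mutant" ~ "mutant-fixated",
                             "cancer" ~ "cancer-fixated",
                             .default = "none")
  p <- mean(label == "mutant-fixated")
  structure(list(estimate = p,
                 se = sqrt(p * (1 - p) / n_total),
                 n_total = n_total,
                 outcomes = mutate(r, outcome = label)),
            class = "tunneling_result")
}

#' @export
print.tunneling_result <- function(x, ...) {
  cat(sprintf("<tunneling_result> P(mutant fixation) = %.4f (SE %.4f, n = %d)\n",
              x$estimate, x$se, x$n_total))
  invisible(x)
}

#' @export
glance.tunneling_result <- function(x, ...) {
  tibble(estimate = x$estimate, se = x$se, n_total = x$n_total)
}

#' Scan fixation regions over the (f_m, f_c) plane
#'
#' For every grid cell, runs `n_total` replicates and records the proportions
#' of replicates in which the mutant or the original cancer fixates within
#' `M` divisions. Cells are classified by the majority outcome among fixating
#' replicates (`"none"` when no replicate fixates either cancer type),
#' reproducing the region map whose mutant/cancer boundary lies near
#' `f_c / f_m ~ 0.6` at high fitnesses.
#'
#' @param fm_grid,fc_grid Strictly increasing grids of mutant / cancer
#'   fitness.
#' @inheritParams simulate_ensemble
#' @param r_m Driver-mutation probability (default 0.01).
#' @param f_h Healthy fitness.
#' @return Tibble with `f_m`, `f_c`, `prop_mutant_fix`, `prop_cancer_fix`,
#'   `prop_none`, `classification`.
#' @seealso [fixation_boundary()]
#' @export
scan_fixation_regions <- function(fm_grid, fc_grid, N, M,
                                  init = moran_init(N, round(0.1 * N)),
                                  r_m = 0.01, f_h = 1,
                                  n_total = 100, seed = NULL) {
  if (is.unsorted(fm_grid, strictly = TRUE) ||
      is.unsorted(fc_grid, strictly = TRUE)) {
    abort("grids must be strictly increasing")
  }
  grid <- tidyr::expand_grid(f_m = fm_grid, f_c = fc_grid)
  cell_seeds <- make_replicate_seeds(seed, nrow(grid))
  res <- purrr::pmap(list(grid$f_m, grid$f_c, cell_seeds),
    function(fm, fc, s) {
      es <- simulate_ensemble(N, M, moran_params(f_c = fc, f_m = fm,
                                                 f_h = f_h, r_m = r_m),
                              init = init, n_total = n_total, seed = s)
      g <- glance(es)
      tibble(prop_mutant_fix = g$prop_mutant_fix,
             prop_cancer_fix = g$prop_cancer_fix)
    })
  out <- dplyr::bind_cols(grid, bind_rows(res))
  mutate(out,
         prop_none = 1 - .data$prop_mutant_fix - .data$prop_cancer_fix,
         classification = dplyr::case_when(
           prop_mutant_fix == 0 & prop_cancer_fix == 0 ~ "none",
           prop_mutant_fix >= prop_cancer_fix ~ "mutant",
           TRUE ~ "cancer"))
}

#' Slope of the mutant/cancer fixation boundary
#'
#' Estimates the ratio `f_c / f_m` at which the mutant stops winning: below
#' the boundary the majority of replicates end in mutant fixation
#' (tunneling), above it the original cancer outcompetes the mutant — it
#' either fixates itself or holds the population so that the mutant cannot
#' fixate within the horizon. For each `f_m` column the boundary is the
#' linearly interpolated `f_c` at which the mutant-fixation proportion
#' crosses 0.5; the returned slope is the mean of the per-column ratios
#' `f_c_boundary / f_m`. This contour estimator is robust to isolated
#' fixations in the sparse tail of the region map, which flip the majority
#' classification of single cells without representing a winning region.
#'
#' @param scan Output of [scan_fixation_regions()].
#' @return One-row tibble with `slope` and `n_columns` (columns where the
#'   crossing is bracketed by the grid).
#' @export
fixation_boundary <- function(scan) {
  cols <- scan |>
    arrange(.data$f_m, .data$f_c) |>
    group_by(.data$f_m) |>
    summarise(boundary = {
      p <- .data$prop_mutant_fix
      k <- which(p[-length(p)] >= 0.5 & p[-1] < 0.5)
      if (length(k) == 0L) NA_real_
      else {
        k <- k[length(k)]
        approx(p[c(k, k + 1L)], .data$f_c[c(k, k + 1L)], xout = 0.5)$y
      }
    }, .groups = "drop") |>
    filter(!is.na(.data$boundary))
  if (nrow(cols) == 0L) {
    return(tibble(slope = NA_real_, n_columns = 0L))
  }
  tibble(slope = mean(cols$boundary / cols$f_m), n_columns = nrow(cols))
}

#' Minimum cancer fitness needed to exceed half the population
#'
#' For each number of divisions `M` in `M_grid`, finds the smallest fitness in
#' `fc_grid` for which the ensemble mean of the cancer count (over `n_total`
#' replicates, starting from a single cancer cell by default) exceeds `0.5 N`
#' by division `M`; `NA` marks infeasible horizons. Because a lineage can gain
#' at most one cell per division, horizons shorter than `N/2` divisions are
#' always infeasible, and the feasibility boundary has a vertical asymptote
#' slightly above `N/2`.
#'
#' @param M_grid Increasing vector of division horizons.
#' @param fc_grid Increasing vector of candidate cancer fitness values (include
#'   very large values to probe the asymptote).
#' @inheritParams simulate_ensemble
#' @return A `min_fitness_curve` tibble (`M`, `min_f_c`); attribute
#'   `first_feasible_M` holds the smallest division index (at any resolution,
#'   not just `M_grid`) at which any scanned fitness crosses `0.5 N`.
#' @seealso [min_feasible_divisions()]
#' @export
min_fitness_curve <- function(M_grid, fc_grid, N = 100,
                              init = moran_init(N, cancer = 1),
                              f_h = 1, n_total = 1000, seed = NULL) {
  M_max <- max(M_grid)
  fc_seeds <- make_replicate_seeds(seed, length(fc_grid))
  # mean cancer-count trajectory per candidate fitness
  mean_c <- vapply(seq_along(fc_grid), function(j) {
    es <- simulate_ensemble(N, M_max, moran_params(f_c = fc_grid[j], f_h = f_h),
                            init = init, n_total = n_total, seed = fc_seeds[j])
    es$summary$mean_cancer
  }, numeric(M_max + 1))
  crossed <- mean_c > 0.5 * N          # (M_max+1) x length(fc_grid)
  first_cross <- apply(crossed, 2, function(z) match(TRUE, z)) - 1L
  curve <- tibble(
    M = M_grid,
    min_f_c = vapply(M_grid, function(m) {
      ok <- which(!is.na(first_cross) & first_cross <= m)
      if (length(ok) == 0L) NA_real_ else min(fc_grid[ok])
    }, numeric(1))
  )
  structure(curve,
            class = c("min_fitness_curve", class(curve)),
            first_feasible_M = if (all(is.na(first_cross))) NA_integer_
                               else as.integer(min(first_cross, na.rm = TRUE)))
}

#' @describeIn min_fitness_curve the vertical asymptote: smallest number of
#'   divisions at which any fitness in `fc_grid` pushes the ensemble mean over
#'   `0.5 N`.
#' @export
min_feasible_divisions <- function(fc_grid, N = 100, M_max = 150,
                                   init = moran_init(N, cancer = 1),
                                   n_total = 1000, seed = NULL) {
  mf <- min_fitness_curve(M_grid = M_max, fc_grid = fc_grid, N = N,
                          init = init, n_total = n_total, seed = seed)
  attr(mf, "first_feasible_M")
}

#' Compare treatment strategies on common replicates
#'
#' Runs one ensemble per strategy. By default the same per-replicate seeds are
#' used across strategies (a paired comparison that removes between-replicate
#' noise from strategy contrasts); set `paired = FALSE` for independent seeds.
#'
#' @param strategies Named list of `treatment_schedule`s (e.g. from
#'   [preset_schedule()]); an empty schedule is the untreated arm.
#' @inheritParams simulate_ensemble
#' @param paired Share replicate seeds across strategies?
#' @return A `strategy_report`: list with `summaries` (long tibble of per-step
#'   means/sds by strategy), `finals` (per-replicate final proportions by
#'   strategy) and `thresholds` (per strategy: proportion of replicates with
#'   mutant >= 0.5N, and with healthy fixation).
#' @export
compare_strategies <- function(strategies, N, M, params,
                               init = moran_init(N, round(0.1 * N)),
                               n_total = 100, seed = NULL, paired = TRUE) {
  stopifnot(is.list(strategies), !is.null(names(strategies)))
  shared <- if (paired) make_replicate_seeds(seed, n_total) else NULL
  arm_seeds <- if (paired) NULL else make_replicate_seeds(seed, length(strategies))
  runs <- purrr::imap(strategies, function(sch, nm) {
    i <- match(nm, names(strategies))
    simulate_ensemble(N, M, params, init = init, schedule = sch,
                      n_total = n_total,
                      seed = if (paired) NULL else arm_seeds[i],
                      replicate_seeds = shared)
  })
  summaries <- purrr::imap(runs, function(es, nm) {
    mutate(es$summary, strategy = nm, .before = 1)
  }) |> bind_rows()
  finals <- purrr::imap(runs, function(es, nm) {
    mutate(es$replicates, strategy = nm, .before = 1,
           prop_h = .data$final_h / N, prop_c = .data$final_c / N,
           prop_m = .data$final_m / N)
  }) |> bind_rows()
  thresholds <- finals |>
    group_by(.data$strategy) |>
    summarise(prop_mutant_half = mean(.data$mutant_reached_half),
              prop_healthy_fix = mean(.data$fixated_type == "healthy"),
              mean_final_tumour = mean(.data$prop_c + .data$prop_m),
              .groups = "drop")
  structure(list(summaries = summaries, finals = finals,
                 thresholds = thresholds, N = N, M = M, params = params,
                 n_total = n_total, paired = paired, seed = seed),
            class = "strategy_report")
}

#' @export
print.strategy_report <- function(x, ...) {
  cat("<strategy_report> ", length(unique(x$summaries$strategy)),
      "strategies x", x$n_total, "replicates\n")
  print(x$thresholds)
  invisible(x)
}

#' @export
tidy.strategy_report <- function(x, ...) x$thresholds

#' Scan mutant treatment response over mutation rate and efficacy
#'
#' For each `(r_m, eff_m)` grid cell, reports the proportion of replicates in
#' which the mutant clone reaches at least half the population within `M`
#' divisions under the given strategy. By default the strategy is the MTD
#' preset with the cell's `eff_m`; pass `preset = "sustained"` (with
#' `eff_scale = 1/3`, `length_scale = 5`) for the sustained-dose variant.
#'
#' @param rm_grid,effm_grid Grids over the mutation probability and the
#'   efficacy against mutant cells.
#' @inheritParams simulate_ensemble
#' @param f_c,f_m,f_h Fitness values (`f_m` defaults to 1.6, the scan setting).
#' @param preset Strategy preset name passed to [preset_schedule()].
#' @param ... Further arguments to [preset_schedule()] (e.g. `eff_scale`).
#' @return Tibble with `r_m`, `eff_m`, `prop_mutant_half`.
#' @export
scan_treatment <- function(rm_grid, effm_grid, N, M,
                           init = moran_init(N, round(0.1 * N)),
                           f_c = 1.1, f_m = 1.6, f_h = 1,
                           preset = "mtd", n_total = 100, seed = NULL, ...) {
  grid <- tidyr::expand_grid(r_m = rm_grid, eff_m = effm_grid)
  cell_seeds <- make_replicate_seeds(seed, nrow(grid))
  prop <- purrr::pmap_dbl(list(grid$r_m, grid$eff_m, cell_seeds),
    function(rm_, em, s) {
      sch <- preset_schedule(preset, eff_m = em, ...)
      es <- simulate_ensemble(N, M,
                              moran_params(f_c = f_c, f_m = f_m, f_h = f_h,
                                           r_m = rm_),
                              init = init, schedule = sch,
                              n_total = n_total, seed = s)
      mean(es$replicates$mutant_reached_half)
    })
  mutate(grid, prop_mutant_half = prop)
}
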