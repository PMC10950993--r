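#' Define a treatment course
#'
#' A course reduces the effective fitness of the cancer and mutant clones while
#' active; healthy cells are never targeted. In `"constant"` mode the efficacy
#' is flat over a window `[t_start, t_start + t_length]`; in `"waning"` mode it
#' decays from its peak as `eff * 2^(-(t - t_start) / t_half)` for all
#' `t >= t_start`, mirroring first-order pharmacokinetic clearance with
#' half-life `t_half`. All times are measured in cell divisions (one Moran
#' timestep each); use [days_to_divisions()] to convert clock time.
#'
#' @param eff_c,eff_m Treatment efficacy against cancer / mutant cells in
#'   \[0, 1\]: 0 has no effect, 1 blocks reproduction completely.
#' @param t_start Division index at which the course starts.
#' @param t_length Window length in divisions (constant mode; ignored when
#'   waning).
#' @param mode `"constant"` or `"waning"`.
#' @param t_half Half-life in divisions (waning mode only).
#' @return A one-row `treatment_schedule` tibble.
#' @seealso [treatment_schedule()], [preset_schedule()], [effective_fitness()]
#' @examples
#' treatment_course(eff_c = 0.8, eff_m = 0.4, t_start = 5000, t_length = 3000)
#' @export
treatment_course <- function(eff_c = 0, eff_m = 0, t_start = 0,
                             t_length = NA_real_,
                             mode = c("constant", "waning"),
                             t_half = NA_real_) {
  mode <- match.arg(mode)
  for (e in c(eff_c, eff_m)) {
    if (!is.numeric(e) || is.na(e) || e < 0 || e > 1) {
      abort("efficacies must lie in [0, 1]")
    }
  }
  if (t_start < 0) abort("`t_start` must be non-negative")
  if (mode == "constant" && (is.na(t_length) || t_length <= 0)) {
    abort("constant-mode courses need `t_length` > 0")
  }
  if (mode == "waning" && (is.na(t_half) || t_half <= 0)) {
    abort("waning-mode courses need `t_half` > 0")
  }
  out <- tibble(mode = mode, t_start = t_start, t_length = t_length,
                t_half = t_half, eff_c = eff_c, eff_m = eff_m)
  class(out) <- c("treatment_schedule", class(out))
  out
}

#' Assemble a treatment schedule from courses
#'
#' A schedule is an ordered (by `t_start`) list of treatment courses, possibly
#' empty. When several courses are simultaneously active their efficacies add
#' linearly per clone and saturate at 1, the combination rule also used for
#' repeated waning doses ([schedule_efficacy()]).
#'
#' @param ... Courses built with [treatment_course()] (or tibbles with the same
#'   columns). No arguments gives the empty schedule (no treatment).
#' @return A `treatment_schedule` tibble sorted by `t_start`.
#' @examples
#' treatment_schedule(
#'   treatment_course(eff_m = 0.8, t_start = 5000, t_length = 2500),
#'   treatment_course(eff_c = 0.8, t_start = 7500, t_length = 2500)
#' )
#' treatment_schedule() # no treatment
#' @export
treatment_schedule <- function(...) {
  courses <- list(...)
  if (length(courses) == 0L) {
    out <- tibble(mode = character(), t_start = double(), t_length = double(),
                  t_half = double(), eff_c = double(), eff_m = double())
  } else {
    out <- arrange(bind_rows(courses), .data$t_start)
  }
  class(out) <- unique(c("treatment_schedule", class(out)))
  out
}

schedule_matrix <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0L) {
    return(matrix(numeric(), nrow = 0, ncol = 6))
  }
  cbind(ifelse(schedule$mode == "waning", 1, 0),
        schedule$t_start,
        ifelse(is.na(schedule$t_length), Inf, schedule$t_length),
        ifelse(is.na(schedule$t_half), Inf, schedule$t_half),
        schedule$eff_c, schedule$eff_m)
}

#' Instantaneous combined treatment efficacy
#'
#' Evaluates the per-clone efficacy of a schedule at the given times,
#' superposing all active courses: contributions add linearly (waning courses
#' contribute `eff * 2^(-(t - t_start)/t_half)`) and cap at 1, mirroring linear
#' pharmacokinetics with effect saturation. This is the rule used for
#' re-administered weekly doses in the Herceptin-style workflow.
#'
#' @param schedule A `treatment_schedule`.
#' @param t Vector of times in cell divisions (non-negative).
#' @return Tibble with columns `t`, `eff_c`, `eff_m`.
#' @examples
#' sch <- treatment_schedule(
#'   treatment_course(eff_c = 0.6, t_start = 0, mode = "waning", t_half = 100)
#' )
#' schedule_efficacy(sch, c(0, 100, 200))
#' @export
schedule_efficacy <- function(schedule, t) {
  if (any(t < 0)) abort("`t` must be non-negative")
  eff <- efficacy_profile_cpp(schedule_matrix(schedule), as.numeric(t))
  tibble(t = as.numeric(t), eff_c = eff[, 1], eff_m = eff[, 2])
}

#' Treatment-modified (effective) fitness
#'
#' Applies a schedule to baseline fitness parameters: while treatment is
#' active the targeted clone's fitness is `f * (1 - eff)`; healthy fitness is
#' never modified. Vectorized over `t`.
#'
#' @param params A [moran_params()] object.
#' @param schedule A `treatment_schedule` (possibly empty).
#' @param t Times in cell divisions (non-negative).
#' @return Tibble with columns `t`, `f_h`, `f_c`, `f_m`.
#' @examples
#' p <- moran_params(f_c = 1.1)
#' sch <- treatment_schedule(
#'   treatment_course(eff_c = 0.8, t_start = 10, t_length = 20)
#' )
#' effective_fitness(p, sch, t = c(5, 15, 40))
#' @export
effective_fitness <- function(params, schedule, t) {
  eff <- schedule_efficacy(schedule, t)
  tibble(t = eff$t,
         f_h = params$f_h,
         f_c = params$f_c * (1 - eff$eff_c),
         f_m = params$f_m * (1 - eff$eff_m))
}

#' Named treatment-strategy presets
#'
#' Builds the five treatment strategies compared in the strategy experiments:
#' \describe{
#'   \item{`"mtd"`}{a single high-efficacy constant window (maximum tolerated
#'     dose) applied after mutant clones are expected to have arisen.}
#'   \item{`"early_mtd"`}{the same course shifted to `early_start`, before
#'     mutants are expected to arise.}
#'   \item{`"dual"`}{two consecutive windows, the first targeting the mutant
#'     clone, the second targeting the original cancer.}
#'   \item{`"sustained"`}{the MTD with efficacy scaled down by `eff_scale` and
#'     window scaled up by `length_scale` (a low sustained dose).}
#'   \item{`"waning"`}{a single dose whose efficacy decays with half-life
#'     `t_half` from `t_start` onwards.}
#' }
#' Defaults follow the strategy-comparison setup: `t_start = 5000`,
#' `t_length = 5000`, efficacies 0.8 against the targeted cancer clone and 0.4
#' against the mutant, sustained scaling 1/5 (the treatment-scan variant uses
#' `eff_scale = 1/3`, `length_scale = 5`), waning half-life 5000 divisions.
#'
#' @param name One of `"mtd"`, `"early_mtd"`, `"dual"`, `"sustained"`,
#'   `"waning"`, `"none"`.
#' @param t_start Start of the course, divisions.
#' @param t_length Window length, divisions.
#' @param eff_c,eff_m Efficacies against cancer / mutant cells.
#' @param early_start Start used by `"early_mtd"`.
#' @param eff_scale,length_scale Sustained-dose scalings of efficacy and length.
#' @param t_half Waning half-life, divisions.
#' @return A `treatment_schedule`.
#' @examples
#' preset_schedule("mtd", t_start = 5000, t_length = 3000)
#' preset_schedule("sustained", eff_scale = 1/3, length_scale = 5)
#' @export
preset_schedule <- function(name = c("mtd", "early_mtd", "dual", "sustained",
                                     "waning", "none"),
                            t_start = 5000, t_length = 5000,
                            eff_c = 0.8, eff_m = 0.4,
                            early_start = 500,
                            eff_scale = 1 / 5, length_scale = 5,
                            t_half = 5000) {
  name <- match.arg(name)
  switch(name,
    none = treatment_schedule(),
    mtd = treatment_schedule(
      treatment_course(eff_c = eff_c, eff_m = eff_m,
                       t_start = t_start, t_length = t_length)),
    early_mtd = treatment_schedule(
      treatment_course(eff_c = eff_c, eff_m = eff_m,
                       t_start = early_start, t_length = t_length)),
    dual = treatment_schedule(
      treatment_course(eff_c = 0, eff_m = max(eff_c, eff_m),
                       t_start = t_start, t_length = t_length / 2),
      treatment_course(eff_c = max(eff_c, eff_m), eff_m = 0,
                       t_start = t_start + t_length / 2,
                       t_length = t_length / 2)),
    sustained = treatment_schedule(
      treatment_course(eff_c = eff_c * eff_scale, eff_m = eff_m * eff_scale,
                       t_start = t_start, t_length = t_length * length_scale)),
    waning = treatment_schedule(
      treatment_course(eff_c = eff_c, eff_m = eff_m,
                       t_start = t_start, mode = "waning", t_half = t_half))
  )
}

#' Repeated waning doses
#'
#' Builds a schedule of `n_doses` identical waning courses spaced
#' `interval_days` apart, the regimen shape of weekly antibody dosing.
#'
#' @param N Population size (sets the time mapping, `N/8` divisions per hour).
#' @param eff_c,eff_m Peak efficacy of each dose.
#' @param n_doses Number of doses.
#' @param interval_days Days between doses.
#' @param first_dose_day Day of the first dose.
#' @param t_half_days Drug half-life in days (default 5.8, the reported
#'   trastuzumab average).
#' @param hours_per_division Hours per cell division (default `8/N`).
#' @return A `treatment_schedule` of waning courses.
#' @examples
#' dose_regimen(N = 1000, eff_c = 0.052, n_doses = 4)
#' @export
dose_regimen <- function(N, eff_c, eff_m = eff_c, n_doses = 4,
                         interval_days = 7, first_dose_day = 0,
                         t_half_days = 5.8, hours_per_division = 8 / N) {
  starts <- first_dose_day + interval_days * seq_len(n_doses) - interval_days
  th <- days_to_divisions(t_half_days, N, hours_per_division)
  courses <- lapply(starts, function(d) {
    treatment_course(eff_c = eff_c, eff_m = eff_m,
                     t_start = days_to_divisions(d, N, hours_per_division),
                     mode = "waning", t_half = th)
  })
  do.call(treatment_schedule, courses)
}

#' Convert between clock time and cell divisions
#'
#' One Moran timestep is one cell division. For Ehrlich-like cells dividing
#' every 8 hours on average, the population performs `N/8` divisions per hour,
#' i.e. one division takes `8/N` hours.
#'
#' @param days,divisions Quantity to convert.
#' @param N Population size.
#' @param hours_per_division Hours per division (default `8/N`).
#' @return Numeric vector in the target unit.
#' @examples
#' days_to_divisions(7, N = 1000)  # one week of divisions
#' divisions_to_days(21000, N = 1000)
#' @export
days_to_divisions <- function(days, N, hours_per_division = 8 / N) {
  days * 24 / hours_per_division
}

#' @rdname days_to_divisions
#' @export
divisions_to_days <- function(divisions, N, hours_per_division = 8 / N) {
  divisions * hours_per_division / 24
}
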