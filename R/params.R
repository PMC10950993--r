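#' Fitness and mutation parameters for the Moran model
#'
#' Bundles the reproductive fitnesses of the three cell types and the driver
#' mutation probability. Fitness is a multiplicative weight on a cell's chance
#' of being selected to reproduce in a timestep; the healthy fitness is
#' conventionally 1 so that `f_c` and `f_m` read as ratios. `r_m` is the
#' probability that a cancer-cell birth produces a mutant offspring instead of
#' a cancer cell (no back-mutation, and healthy cells never mutate).
#'
#' @param f_c Cancer-cell fitness (> 0).
#' @param f_m Mutant-cell fitness (> 0); defaults to `f_c`.
#' @param f_h Healthy-cell fitness (> 0), conventionally 1.
#' @param r_m Driver-mutation probability per cancer birth, in \[0, 1\].
#' @return An object of class `moran_params`.
#' @examples
#' moran_params(f_c = 1.1, f_m = 3, r_m = 0.01)
#' @export
moran_params <- function(f_c = 1, f_m = f_c, f_h = 1, r_m = 0) {
  for (nm in c("f_c", "f_m", "f_h")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number", nm))
    }
  }
  if (!is.numeric(r_m) || length(r_m) != 1L || is.na(r_m) || r_m < 0 || r_m > 1) {
    abort("`r_m` must be a single probability in [0, 1]")
  }
  structure(list(f_h = f_h, f_c = f_c, f_m = f_m, r_m = r_m),
            class = "moran_params")
}

#' @export
print.moran_params <- function(x, ...) {
  cat("<moran_params>  f_h =", x$f_h, " f_c =", x$f_c,
      " f_m =", x$f_m, " r_m =", x$r_m, "\n")
  invisible(x)
}

#' Initial population state
#'
#' Convenience constructor for the count vector `(n_healthy, n_cancer,
#' n_mutant)` used by the simulators; the healthy count is whatever is left of
#' the fixed population size `N`.
#'
#' @param N Total (constant) population size.
#' @param cancer Initial number of cancer cells.
#' @param mutant Initial number of mutant cells.
#' @return Named integer vector of length 3 summing to `N`.
#' @examples
#' moran_init(100, cancer = 10)
#' @export
moran_init <- function(N, cancer = 0, mutant = 0) {
  state <- c(n_healthy = N - cancer - mutant,
             n_cancer = cancer, n_mutant = mutant)
  check_state(state, N)
  state
}

check_state <- function(state, N = sum(state)) {
  state <- as_state(state)
  if (any(is.na(state)) || any(state < 0) || any(state != round(state))) {
    abort("cell counts must be non-negative integers")
  }
  if (N <= 0) abort("invalid state: total population N must be positive")
  if (sum(state) != N) abort("cell counts must sum to N")
  invisible(state)
}

as_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (length(state) == 2L) state <- c(state, 0)
  if (length(state) != 3L) abort("a population state has 3 counts (h, c, m)")
  setNames(as.numeric(state), c("n_healthy", "n_cancer", "n_mutant"))
}
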