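# Random valid three-type states and parameter sets for property loops.
random_state <- function(N = sample(10:500, 1)) {
  cuts <- sort(sample(0:N, 2, replace = TRUE))
  moran_init(N, cancer = cuts[2] - cuts[1], mutant = N - cuts[2])
}

random_params <- function(r_m = stats::runif(1)) {
  moran_params(f_c = stats::runif(1, 0.1, 5), f_m = stats::runif(1, 0.1, 5),
               f_h = stats::runif(1, 0.1, 5), r_m = r_m)
}

# Closed-form fixation probability of a two-type Moran process with fitness
# ratio r = f_c / f_h starting from i cancer cells.
fixation_prob <- function(i, N, r) {
  if (r == 1) return(i / N)
  (1 - r^(-i)) / (1 - r^(-N))
}

# Expected count change implied by an event distribution (analytic mean).
event_mean <- function(pr, state) {
  unname(c(state[1] + sum(pr$probability * pr$d_healthy),
           state[2] + sum(pr$probability * pr$d_cancer),
           state[3] + sum(pr$probability * pr$d_mutant)))
}
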