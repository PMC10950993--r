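#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Schedule matrix columns: mode (0 = constant, 1 = waning), t_start, t_length,
// t_half, eff_c, eff_m. Times are in cell divisions. Contributions of all
// active courses add linearly per clone and saturate at efficacy 1.
static inline void efficacy_at(const NumericMatrix& sched, double t,
                               double& ec, double& em) {
  ec = 0.0; em = 0.0;
  for (int k = 0; k < sched.nrow(); ++k) {
    double w = 0.0;
    if (sched(k, 0) == 0.0) {
      if (t >= sched(k, 1) && t <= sched(k, 1) + sched(k, 2)) w = 1.0;
    } else {
      if (t >= sched(k, 1)) w = std::exp2(-(t - sched(k, 1)) / sched(k, 3));
    }
    ec += w * sched(k, 4);
    em += w * sched(k, 5);
  }
  if (ec > 1.0) ec = 1.0;
  if (em > 1.0) em = 1.0;
}

// [[Rcpp::export]]
NumericMatrix efficacy_profile_cpp(NumericMatrix sched, NumericVector t) {
  NumericMatrix out(t.size(), 2);
  for (int i = 0; i < t.size(); ++i) {
    double ec, em;
    efficacy_at(sched, t[i], ec, em);
    out(i, 0) = ec;
    out(i, 1) = em;
  }
  return out;
}

// One stochastic replicate. Each timestep draws a reproducer (fitness-weighted,
// with a fraction r_m of cancer-birth weight diverted to mutant offspring) and
// a dier (count-weighted, self-replacement allowed); the dier is replaced by
// the offspring. Early-exits on absorbing states and pads the trajectory.
// [[Rcpp::export]]
List moran_sim_cpp(int N, int M, IntegerVector init,
                   double fh, double fc, double fm, double rm,
                   NumericMatrix sched) {
  int nh = init[0], nc = init[1], nm = init[2];
  if (nh + nc + nm != N) stop("initial counts must sum to N");
  IntegerMatrix traj(M + 1, 3);
  traj(0, 0) = nh; traj(0, 1) = nc; traj(0, 2) = nm;
  bool has_sched = sched.nrow() > 0;
  int absorbed_at = -1;

  // a state is absorbing when no event other than no-change has positive prob
  bool absorbing = (nh == N) || (nm == N) || (nc == N && rm == 0.0);
  if (absorbing) absorbed_at = 0;

  int n = 1;
  for (; n <= M && absorbed_at < 0; ++n) {
    double t = n - 1;  // schedule evaluated at the pre-step division index
    double efc = fc, efm = fm;
    if (has_sched) {
      double ec, em;
      efficacy_at(sched, t, ec, em);
      efc = fc * (1.0 - ec);
      efm = fm * (1.0 - em);
    }
    double wh = nh * fh, wc = nc * efc, wm = nm * efm;
    double W = wh + wc + wm;
    if (W <= 0.0)
      stop("degenerate selection: all effective fitness weights are zero");

    double u = unif_rand() * W;
    int off;  // 0 healthy, 1 cancer, 2 mutant offspring
    if (u < wh) off = 0;
    else if (u < wh + (1.0 - rm) * wc) off = 1;
    else off = 2;  // mutant birth, or cancer birth diverted by mutation

    double v = unif_rand() * N;
    int die = (v < nh) ? 0 : ((v < nh + nc) ? 1 : 2);

    int cnt[3] = {nh, nc, nm};
    cnt[die] -= 1;
    cnt[off] += 1;
    nh = cnt[0]; nc = cnt[1]; nm = cnt[2];
    traj(n, 0) = nh; traj(n, 1) = nc; traj(n, 2) = nm;

    absorbing = (nh == N) || (nm == N) || (nc == N && rm == 0.0);
    if (absorbing) absorbed_at = n;
  }
  if (absorbed_at >= 0) {
    for (int j = absorbed_at + 1; j <= M; ++j) {
      traj(j, 0) = nh; traj(j, 1) = nc; traj(j, 2) = nm;
    }
  }
  return List::create(_["traj"] = traj,
                      _["absorbed_at"] = absorbed_at);
}

// Expectation recursion against a precomputed per-step dose-decay profile D:
// the instantaneous efficacy on clone i is min(1, eff_i * D[t]). Used by the
// efficacy grid search, where recomputing the exponential decays for every
// (eff_c, eff_m) pair would dominate the runtime.
// [[Rcpp::export]]
NumericVector expected_burden_scaled_cpp(double N, int M, NumericVector init,
                                         double fh, double fc, double fm,
                                         double rm, NumericVector decay,
                                         double eff_c, double eff_m) {
  double nh = init[0], nc = init[1], nm = init[2];
  NumericVector burden(M + 1);
  burden[0] = (nc + nm) / N;
  for (int n = 1; n <= M; ++n) {
    double d = decay[n - 1];
    double ec = eff_c * d, em = eff_m * d;
    if (ec > 1.0) ec = 1.0;
    if (em > 1.0) em = 1.0;
    double efc = fc * (1.0 - ec), efm = fm * (1.0 - em);
    double W = nh * fh + nc * efc + nm * efm;
    if (W <= 0.0)
      stop("degenerate selection: all effective fitness weights are zero");
    double dh = nh * fh / W - nh / N;
    double dc = (1.0 - rm) * nc * efc / W - nc / N;
    double dm = (nm * efm + rm * nc * efc) / W - nm / N;
    nh += dh; nc += dc; nm += dm;
    burden[n] = (nc + nm) / N;
  }
  return burden;
}

// Deterministic conditional-expectation recursion over real-valued counts.
// With W = sum_i N_i f_i the one-step increments are
//   dE[N_h] = N_h f_h / W - N_h / N
//   dE[N_c] = (1 - r_m) N_c f_c / W - N_c / N
//   dE[N_m] = (N_m f_m + r_m N_c f_c) / W - N_m / N
// which is the exact mean of the event distribution at each state.
// [[Rcpp::export]]
NumericMatrix expected_traj_cpp(double N, int M, NumericVector init,
                                double fh, double fc, double fm, double rm,
                                NumericMatrix sched) {
  double nh = init[0], nc = init[1], nm = init[2];
  NumericMatrix traj(M + 1, 3);
  traj(0, 0) = nh; traj(0, 1) = nc; traj(0, 2) = nm;
  bool has_sched = sched.nrow() > 0;
  for (int n = 1; n <= M; ++n) {
    double t = n - 1;
    double efc = fc, efm = fm;
    if (has_sched) {
      double ec, em;
      efficacy_at(sched, t, ec, em);
      efc = fc * (1.0 - ec);
      efm = fm * (1.0 - em);
    }
    double W = nh * fh + nc * efc + nm * efm;
    if (W <= 0.0)
      stop("degenerate selection: all effective fitness weights are zero");
    double dh = nh * fh / W - nh / N;
    double dc = (1.0 - rm) * nc * efc / W - nc / N;
    double dm = (nm * efm + rm * nc * efc) / W - nm / N;
    nh += dh; nc += dc; nm += dm;
    traj(n, 0) = nh; traj(n, 1) = nc; traj(n, 2) = nm;
  }
  return traj;
}
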