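#include <Rcpp.h>
using namespace Rcpp;

// Deterministic flow between bursts: mRNA decays exponentially, protein
// follows dP/dt = s1*M - d1*P with M(t) = M0*exp(-d0 t), solved in closed
// form. The removable singularity d0 == d1 uses the limit dt*exp(-d0 dt).
static inline void advance_state(double dt, int n, double stim,
                                 NumericVector &M, NumericVector &P,
                                 const NumericVector &s1,
                                 const NumericVector &d0,
                                 const NumericVector &d1) {
  if (dt <= 0.0) { P[0] = stim; return; }
  for (int i = 0; i < n; ++i) {
    double em = std::exp(-d0[i] * dt);
    double ep = std::exp(-d1[i] * dt);
    double coef;
    if (std::fabs(d0[i] - d1[i]) < 1e-12 * (d0[i] + d1[i]))
      coef = dt * em;
    else
      coef = (em - ep) / (d1[i] - d0[i]);
    P[i + 1] = P[i + 1] * ep + s1[i] * M[i] * coef;
    M[i] *= em;
  }
  P[0] = stim;
}

static inline double kon_rate(int i, int n, const NumericVector &P,
                              const NumericVector &k0, const NumericVector &k1,
                              const NumericVector &beta,
                              const NumericMatrix &theta) {
  double x = beta[i];
  for (int j = 0; j <= n; ++j) x += theta(i + 1, j) * P[j];
  return k0[i] + (k1[i] - k0[i]) / (1.0 + std::exp(-x));
}

// Exact simulation of one cell over [t0, t1] by thinning: candidate burst
// times are proposed at the constant majorising rate sum(k1), the gene is
// chosen proportionally to k1, and the candidate is accepted with
// probability kon(P(t))/k1 evaluated at the candidate time. Uses R's RNG.
// [[Rcpp::export(name = ".sim_cell_interval")]]
List sim_cell_interval(NumericVector M0, NumericVector P0, double stim,
                       double t0, double t1,
                       NumericVector k0, NumericVector k1, NumericVector bsm,
                       NumericVector s1, NumericVector d0, NumericVector d1,
                       NumericVector beta, NumericMatrix theta, bool record) {
  int n = M0.size();
  NumericVector M = clone(M0);
  NumericVector P = clone(P0);
  P[0] = stim;

  double K = 0.0;
  for (int i = 0; i < n; ++i) K += k1[i];

  std::vector<double> btimes, bsizes;
  std::vector<int> bgenes;

  double t = t0;
  if (K > 0.0) {
    for (;;) {
      double tc = t + exp_rand() / K;
      if (tc >= t1) break;
      advance_state(tc - t, n, stim, M, P, s1, d0, d1);
      t = tc;
      double u = unif_rand() * K, cum = 0.0;
      int g = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += k1[i];
        if (u <= cum) { g = i; break; }
      }
      double kon = kon_rate(g, n, P, k0, k1, beta, theta);
      if (unif_rand() * k1[g] < kon) {
        double size = exp_rand() * bsm[g];
        M[g] += size;
        if (record) {
          btimes.push_back(tc);
          bgenes.push_back(g + 1);  // 1-based gene index
          bsizes.push_back(size);
        }
      }
    }
  }
  advance_state(t1 - t, n, stim, M, P, s1, d0, d1);

  for (int i = 0; i < n; ++i)
    if (!R_finite(M[i]) || !R_finite(P[i + 1]))
      stop("non-finite cell state: check rate/unit configuration");

  return List::create(_["M"] = M, _["P"] = P, _["t"] = t1,
                      _["burst_times"] = wrap(btimes),
                      _["burst_genes"] = wrap(bgenes),
                      _["burst_sizes"] = wrap(bsizes));
}
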