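#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hyperbolic distance with overflow guard. For large radii the product of
// hyperbolic cosines overflows double precision; switch to the standard
// asymptotic form x ~ r1 + r2 + 2 ln sin(dtheta/2), clipped below at |r1 - r2|.
// At the crossover (sum of radii ~ 60) the two forms agree far below 1e-3.
static inline double hyp_dist(double r1, double r2, double dtheta,
                              double cr1, double sr1, double cr2, double sr2) {
  if (dtheta <= 0.0) return std::fabs(r1 - r2);
  if (r1 + r2 < 60.0) {
    double arg = cr1 * cr2 - sr1 * sr2 * std::cos(dtheta);
    if (arg < 1.0) arg = 1.0;
    return std::acosh(arg);
  }
  double x = r1 + r2 + 2.0 * std::log(std::sin(dtheta / 2.0));
  double lo = std::fabs(r1 - r2);
  return x < lo ? lo : x;
}

// Bernoulli edge sampling over all unordered pairs with the Fermi-Dirac
// connection probability p(x) = 1 / (1 + exp((x - R) / (2 Tbar))).
// Uses R's RNG so results are reproducible with set.seed().
// [[Rcpp::export]]
IntegerMatrix sample_edges_core(NumericVector r, NumericVector theta,
                                double disc_radius, double temperature) {
  int n = r.size();
  std::vector<double> cr(n), sr(n);
  for (int i = 0; i < n; ++i) {
    cr[i] = std::cosh(r[i]);
    sr[i] = std::sinh(r[i]);
  }
  std::vector<int> from, to;
  from.reserve(4 * n);
  to.reserve(4 * n);
  const double two_pi = 2.0 * M_PI;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = std::fabs(theta[i] - theta[j]);
      if (d > M_PI) d = two_pi - d;
      double x = hyp_dist(r[i], r[j], d, cr[i], sr[i], cr[j], sr[j]);
      double p = 1.0 / (1.0 + std::exp((x - disc_radius) / (2.0 * temperature)));
      if (unif_rand() < p) {
        from.push_back(i + 1);
        to.push_back(j + 1);
      }
    }
  }
  int m = from.size();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}

// Round payoffs pi_i = sum over neighbours j of the 2x2 game payoff to i,
// with the normalisation R = 1 (mutual cooperation) and P = 0 (mutual
// defection). CSR adjacency: ptr (length n+1, 0-based), nbr (0-based ids).
// [[Rcpp::export]]
NumericVector payoffs_core(IntegerVector ptr, IntegerVector nbr,
                           LogicalVector coop, double temptation, double sucker) {
  int n = ptr.size() - 1;
  NumericVector pay(n);
  for (int i = 0; i < n; ++i) {
    double p = 0.0;
    bool ci = coop[i];
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      bool cj = coop[nbr[e]];
      if (ci) p += cj ? 1.0 : sucker;
      else if (cj) p += temptation;
    }
    pay[i] = p;
  }
  return pay;
}

// Synchronous Fermi imitation dynamics. Each generation: accumulate round
// payoffs, every node picks one uniform-random neighbour and adopts its
// (pre-update) strategy with probability 1/(1+exp(-(pi_j - pi_i)/K)); all
// adoptions are applied simultaneously and payoffs are reset.
//
// Returns the cooperation density at generations 0..n_generations (absorbed
// trajectories padded with the absorbing value), the generation at which the
// population absorbed (-1 if never), the final strategy vector, and strategy
// snapshots at the requested (sorted, 1-based) generations.
// [[Rcpp::export]]
List fermi_run_core(IntegerVector ptr, IntegerVector nbr, LogicalVector coop0,
                    double temptation, double sucker, double noise,
                    int n_generations, IntegerVector snapshot_at,
                    bool early_exit = true) {
  int n = ptr.size() - 1;
  for (int i = 0; i < n; ++i) {
    if (ptr[i + 1] == ptr[i])
      stop("node %d has no neighbours; run the dynamics on the giant component", i + 1);
  }
  std::vector<char> cur(n), nxt(n);
  int ncoop = 0;
  for (int i = 0; i < n; ++i) {
    cur[i] = coop0[i] ? 1 : 0;
    ncoop += cur[i];
  }
  NumericVector density(n_generations + 1);
  density[0] = (double)ncoop / n;
  int n_snap = snapshot_at.size();
  LogicalMatrix snaps(n_snap, n);
  int snap_idx = 0;
  std::vector<double> pay(n);
  int absorbed_at = -1;
  if (ncoop == 0 || ncoop == n) absorbed_at = 0;

  for (int gen = 1; gen <= n_generations; ++gen) {
    if (absorbed_at < 0) {
      // payoff accumulation
      for (int i = 0; i < n; ++i) {
        double p = 0.0;
        bool ci = cur[i];
        for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
          bool cj = cur[nbr[e]];
          if (ci) p += cj ? 1.0 : sucker;
          else if (cj) p += temptation;
        }
        pay[i] = p;
      }
      // simultaneous imitation from the pre-update snapshot
      ncoop = 0;
      for (int i = 0; i < n; ++i) {
        int k = ptr[i + 1] - ptr[i];
        int pick = (int)(unif_rand() * k);
        if (pick >= k) pick = k - 1;
        int j = nbr[ptr[i] + pick];
        double P = 1.0 / (1.0 + std::exp(-(pay[j] - pay[i]) / noise));
        nxt[i] = (unif_rand() < P) ? cur[j] : cur[i];
        ncoop += nxt[i];
      }
      cur.swap(nxt);
      if (ncoop == 0 || ncoop == n) absorbed_at = gen;
    }
    density[gen] = (double)ncoop / n;
    while (snap_idx < n_snap && snapshot_at[snap_idx] == gen) {
      for (int i = 0; i < n; ++i) snaps(snap_idx, i) = (bool)cur[i];
      ++snap_idx;
    }
    if (early_exit && absorbed_at >= 0 && snap_idx >= n_snap) {
      // pad the remaining densities with the absorbing value
      for (int g = gen + 1; g <= n_generations; ++g) density[g] = density[gen];
      break;
    }
  }
  // snapshots requested beyond an early exit hold the absorbing state
  while (snap_idx < n_snap) {
    for (int i = 0; i < n; ++i) snaps(snap_idx, i) = (bool)cur[i];
    ++snap_idx;
  }
  LogicalVector final_strategy(n);
  for (int i = 0; i < n; ++i) final_strategy[i] = (bool)cur[i];
  return List::create(_["density"] = density,
                      _["absorbed_at"] = absorbed_at,
                      _["final_strategy"] = final_strategy,
                      _["snapshots"] = snaps);
}
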