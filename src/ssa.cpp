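#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation (Gillespie).
//
// rate:      per-reaction rate constants (length m).
// reactants: m x 2 matrix of 0-based species indices (-1 = unused slot);
//            propensity = rate * x[r1] * x[r2] (unit stoichiometries).
// stoich:    m x n_species net stoichiometry matrix.
// x0:        initial copy numbers.
//
// Uses R's RNG, so set.seed() in R makes trajectories reproducible.

static inline double propensity_of(int k, const IntegerMatrix& reactants,
                                   const NumericVector& rate,
                                   const std::vector<int>& x) {
  double a = rate[k];
  int r1 = reactants(k, 0), r2 = reactants(k, 1);
  if (r1 >= 0) a *= x[r1];
  if (r2 >= 0) a *= x[r2];
  return a;
}

// Simulate one trajectory, recording every event (times and reaction
// indices). Stops at t_end, at max_events, or when the state absorbs.
// [[Rcpp::export]]
List ssa_simulate_cpp(NumericVector rate, IntegerMatrix reactants,
                      IntegerMatrix stoich, IntegerVector x0, double t_end,
                      int max_events) {
  const int m = rate.size();
  const int ns = x0.size();
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<double> times;
  std::vector<int> which_rxn;
  double t = 0.0;
  bool absorbed = false;
  while (true) {
    double a0 = 0.0;
    double a[64];
    if (m > 64) stop("too many reactions");
    for (int k = 0; k < m; ++k) { a[k] = propensity_of(k, reactants, rate, x); a0 += a[k]; }
    if (a0 <= 0.0) { absorbed = true; break; }
    t += R::exp_rand() / a0;
    if (t > t_end) break;
    if ((int)times.size() >= max_events)
      stop("max_events exceeded before t_end; raise max_events or lower t_end");
    double u = unif_rand() * a0;
    int k = 0;
    double acc = a[0];
    while (acc < u && k < m - 1) { acc += a[++k]; }
    for (int s = 0; s < ns; ++s) x[s] += stoich(k, s);
    times.push_back(t);
    which_rxn.push_back(k + 1);
  }
  return List::create(_["times"] = wrap(times), _["reaction"] = wrap(which_rxn),
                      _["final_state"] = wrap(x), _["absorbed"] = absorbed);
}

// Accumulate the time-weighted occupancy histogram of one or two species
// over n_traj independent trajectories, excluding [0, burn_in). Counts
// beyond the histogram caps are clamped into the top bin (callers choose
// caps generously). Returns the unnormalised weight array and total time.
// [[Rcpp::export]]
List ssa_occupancy_cpp(NumericVector rate, IntegerMatrix reactants,
                       IntegerMatrix stoich, IntegerVector x0, double t_end,
                       double burn_in, IntegerVector species,
                       IntegerVector caps, int n_traj) {
  const int m = rate.size();
  const int ns = x0.size();
  const int nsp = species.size();
  if (nsp < 1 || nsp > 2) stop("species must have length 1 or 2");
  const int d1 = caps[0] + 1;
  const int d2 = (nsp == 2) ? caps[1] + 1 : 1;
  NumericVector w(d1 * d2);
  double total = 0.0;
  if (m > 64) stop("too many reactions");
  double a[64];
  for (int tr = 0; tr < n_traj; ++tr) {
    std::vector<int> x(x0.begin(), x0.end());
    double t = 0.0;
    while (t < t_end) {
      double a0 = 0.0;
      for (int k = 0; k < m; ++k) { a[k] = propensity_of(k, reactants, rate, x); a0 += a[k]; }
      double t_next;
      int k = -1;
      if (a0 <= 0.0) {
        t_next = t_end;  // absorbed: state holds to the end
      } else {
        t_next = t + R::exp_rand() / a0;
        if (t_next > t_end) t_next = t_end;
        else {
          double u = unif_rand() * a0;
          double acc = 0.0;
          k = 0; acc = a[0];
          while (acc < u && k < m - 1) { acc += a[++k]; }
        }
      }
      // accumulate dwell time within [burn_in, t_end]
      double lo = std::max(t, burn_in), hi = t_next;
      if (hi > lo) {
        int i1 = std::min(x[species[0]], (int)caps[0]);
        int i2 = (nsp == 2) ? std::min(x[species[1]], (int)caps[1]) : 0;
        w[i2 * d1 + i1] += hi - lo;
        total += hi - lo;
      }
      if (k >= 0) for (int s = 0; s < ns; ++s) x[s] += stoich(k, s);
      t = t_next;
      if (a0 <= 0.0) break;
    }
  }
  return List::create(_["weights"] = w, _["total_time"] = total,
                      _["dim"] = IntegerVector::create(d1, d2));
}
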