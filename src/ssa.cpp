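// Exact stochastic simulation (Gillespie direct method) for mass-action
// reaction systems with small copy numbers.  Reproducibility is handled by a
// counter-based PCG32 stream per simulated cell, derived from one master
// seed, so ensembles are deterministic and order-independent.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t stream) {
    // distinct, scrambled (state, increment) pairs per (seed, stream)
    uint64_t s0 = splitmix64(seed ^ (stream * 0xD2B74407B1CE6E93ULL));
    uint64_t s1 = splitmix64(s0 ^ stream);
    state = 0U;
    inc = (s1 << 1u) | 1u;
    next();
    state += s0;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform on the open interval (0,1); never 0 so log() is safe
  double unif() { return (next() + 0.5) * 2.3283064365386963e-10; }
};

struct System {
  int n_species;
  int n_reactions;
  std::vector<double> rate;
  std::vector< std::vector<int> > reactants; // 0-based indices, with multiplicity
  std::vector< std::vector< std::pair<int,int> > > stoich; // (species, delta)
};

static System make_system(NumericVector rates, List reactants, IntegerMatrix stoich) {
  System sys;
  sys.n_reactions = rates.size();
  sys.n_species = stoich.ncol();
  sys.rate.resize(sys.n_reactions);
  sys.reactants.resize(sys.n_reactions);
  sys.stoich.resize(sys.n_reactions);
  for (int j = 0; j < sys.n_reactions; ++j) {
    sys.rate[j] = rates[j];
    IntegerVector r = reactants[j];
    for (int m = 0; m < r.size(); ++m) sys.reactants[j].push_back(r[m]);
    for (int s = 0; s < sys.n_species; ++s)
      if (stoich(j, s) != 0) sys.stoich[j].push_back(std::make_pair(s, stoich(j, s)));
  }
  return sys;
}

static inline double propensity(const System &sys, int j, const std::vector<double> &x) {
  double a = sys.rate[j];
  const std::vector<int> &r = sys.reactants[j];
  for (size_t m = 0; m < r.size(); ++m) {
    a *= x[r[m]];
    if (a <= 0.0) return 0.0;
  }
  return a;
}

// advance the state in place until t_end; returns the time of the last event
static double run_to(const System &sys, std::vector<double> &x, double t0,
                     double t_end, Pcg32 &rng) {
  int R = sys.n_reactions;
  std::vector<double> a(R);
  double t = t0;
  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < R; ++j) { a[j] = propensity(sys, j, x); a0 += a[j]; }
    if (a0 <= 0.0) return t;  // absorbing state: hold until t_end
    double dt = -std::log(rng.unif()) / a0;
    if (t + dt > t_end) return t;
    t += dt;
    double u = rng.unif() * a0;
    double cum = 0.0;
    int j = R - 1;
    for (int k = 0; k < R; ++k) {
      cum += a[k];
      if (u <= cum) { j = k; break; }
    }
    for (size_t m = 0; m < sys.stoich[j].size(); ++m)
      x[sys.stoich[j][m].first] += sys.stoich[j][m].second;
  }
}

// [[Rcpp::export]]
List cpp_ssa_trajectory(NumericVector rates, List reactants, IntegerMatrix stoich,
                        NumericVector init, double t_end, double seed,
                        double stream, int max_events) {
  System sys = make_system(rates, reactants, stoich);
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);
  std::vector<double> x(init.begin(), init.end());
  std::vector<double> times;
  std::vector<double> states;
  times.push_back(0.0);
  states.insert(states.end(), x.begin(), x.end());

  int R = sys.n_reactions;
  std::vector<double> a(R);
  double t = 0.0;
  bool early = false;
  for (int ev = 0; ev < max_events; ++ev) {
    double a0 = 0.0;
    for (int j = 0; j < R; ++j) { a[j] = propensity(sys, j, x); a0 += a[j]; }
    if (a0 <= 0.0) { early = true; break; }
    double dt = -std::log(rng.unif()) / a0;
    if (t + dt > t_end) break;
    t += dt;
    double u = rng.unif() * a0;
    double cum = 0.0;
    int j = R - 1;
    for (int k = 0; k < R; ++k) {
      cum += a[k];
      if (u <= cum) { j = k; break; }
    }
    for (size_t m = 0; m < sys.stoich[j].size(); ++m)
      x[sys.stoich[j][m].first] += sys.stoich[j][m].second;
    times.push_back(t);
    states.insert(states.end(), x.begin(), x.end());
  }

  int n = times.size();
  NumericVector tv(times.begin(), times.end());
  NumericMatrix sm(n, sys.n_species);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < sys.n_species; ++s)
      sm(i, s) = states[(size_t)i * sys.n_species + s];
  return List::create(_["times"] = tv, _["states"] = sm,
                      _["ended_early"] = early, _["t_final"] = t);
}

// Ensemble of independent cells, each recorded at every requested snapshot
// time.  Returns a list of n_cells x n_species matrices, one per snapshot.
// [[Rcpp::export]]
List cpp_ssa_ensemble(NumericVector rates, List reactants, IntegerMatrix stoich,
                      NumericMatrix init, NumericVector t_snaps, double seed) {
  System sys = make_system(rates, reactants, stoich);
  int n_cells = init.nrow();
  int n_snap = t_snaps.size();
  std::vector<NumericMatrix> out;
  for (int k = 0; k < n_snap; ++k) out.push_back(NumericMatrix(n_cells, sys.n_species));

  for (int c = 0; c < n_cells; ++c) {
    Pcg32 rng((uint64_t)seed, (uint64_t)(c + 1));
    std::vector<double> x(sys.n_species);
    for (int s = 0; s < sys.n_species; ++s) x[s] = init(c, s);
    double t = 0.0;
    for (int k = 0; k < n_snap; ++k) {
      t = run_to(sys, x, t, t_snaps[k], rng);
      t = t_snaps[k];
      for (int s = 0; s < sys.n_species; ++s) out[k](c, s) = x[s];
    }
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  List res(n_snap);
  for (int k = 0; k < n_snap; ++k) res[k] = out[k];
  return res;
}
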