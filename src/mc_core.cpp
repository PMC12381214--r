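#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Package-owned counter-seeded RNG (splitmix64 seeding + xoshiro256**)
// so replicate substreams are bitwise reproducible across platforms,
// independent of R's RNG state.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
  inline void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

inline uint64_t replicate_seed(double master, int rep) {
  return (uint64_t)master * 0x9E3779B1ULL + (uint64_t)(rep + 1) * 0x85EBCA77ULL;
}

}  // namespace

// Constant-speed kinetic Monte Carlo over a precomputed force/time grid.
//
// force, dt: per-step force (pN) and step duration (s) along the pulling
//   grid (WLC force at evenly spaced molecular extensions, times from the
//   head-height trajectory).
// edge_from: state index (0 = N, 1 = I1, 2 = I2) each edge leaves from.
// edge_to:   destination state index, or -1 for unbinding.
// edge_pathway: 0/1/2 for rupture edges (P0/P1/P2), -1 for transitions.
// k0, dx: Bell parameters per edge; beta = 1/kBT in 1/(pN nm).
//
// Per step, every edge leaving the current state converts its off-rate
// k0*exp(beta*F*dx) into a per-interval probability 1 - exp(-k dt); the
// eligible events are shuffled and the first whose independent uniform
// draw falls below its probability executes. Replicates that exhaust the
// grid are censored (pathway NA).
// [[Rcpp::export]]
List mc_constant_speed_cpp(NumericVector force, NumericVector dt,
                           IntegerVector edge_from, IntegerVector edge_to,
                           IntegerVector edge_pathway,
                           NumericVector k0, NumericVector dx,
                           double beta, int n_rep, double seed) {
  const int n_step = force.size();
  const int n_edge = edge_from.size();
  // precompute per-step, per-edge event probabilities (shared by replicates)
  std::vector<double> P((size_t)n_step * n_edge);
  for (int e = 0; e < n_edge; ++e) {
    const double lk0 = std::log(k0[e]);
    for (int i = 0; i < n_step; ++i) {
      double lam = std::exp(lk0 + beta * force[i] * dx[e]) * dt[i];
      P[(size_t)i * n_edge + e] = (lam > 700.0) ? 1.0 : -std::expm1(-lam);
    }
  }
  // eligible edge lists per state
  std::vector<std::vector<int>> eligible(3);
  for (int e = 0; e < n_edge; ++e) eligible[edge_from[e]].push_back(e);

  NumericVector out_force(n_rep), out_time(n_rep);
  IntegerVector out_pathway(n_rep), out_step(n_rep), out_ntrans(n_rep);
  std::vector<double> t_cum(n_step);
  double acc = 0.0;
  for (int i = 0; i < n_step; ++i) { acc += dt[i]; t_cum[i] = acc; }

  std::vector<int> order;
  for (int r = 0; r < n_rep; ++r) {
    Xoshiro rng(replicate_seed(seed, r));
    int state = 0, ntrans = 0;
    bool done = false;
    for (int i = 0; i < n_step && !done; ++i) {
      const std::vector<int>& el = eligible[state];
      const int m = (int)el.size();
      if (m == 0) continue;
      order.assign(el.begin(), el.end());
      if (m > 1) rng.shuffle(order);
      for (int j = 0; j < m; ++j) {
        const int e = order[j];
        const double u = rng.unif();
        if (u < P[(size_t)i * n_edge + e]) {
          if (edge_to[e] < 0) {
            out_force[r] = force[i];
            out_time[r] = t_cum[i];
            out_pathway[r] = edge_pathway[e];
            out_step[r] = i + 1;  // 1-based for R
            out_ntrans[r] = ntrans;
            done = true;
          } else {
            state = edge_to[e];
            ++ntrans;
          }
          break;  // at most one event per step
        }
      }
    }
    if (!done) {  // censored: tether fully extended before rupture
      out_force[r] = NA_REAL;
      out_time[r] = NA_REAL;
      out_pathway[r] = NA_INTEGER;
      out_step[r] = NA_INTEGER;
      out_ntrans[r] = ntrans;
    }
  }
  return List::create(_["rupture_force"] = out_force,
                      _["time"] = out_time,
                      _["pathway"] = out_pathway,
                      _["step"] = out_step,
                      _["n_transitions"] = out_ntrans);
}

// Force-clamp kinetic Monte Carlo at one setpoint. Same shuffle-execute
// rule with a fixed interval dt; because the force (hence every event
// probability) is constant within a state, the waiting time in a state is
// geometric in the number of intervals and is sampled directly, with the
// executed event drawn from the exact shuffle-order distribution
// (enumerated over all permutations of the <= 3 eligible edges). This is
// distribution-identical to the per-interval loop and keeps 1e-4 s
// intervals affordable over 10 s clamps.
// [[Rcpp::export]]
List mc_clamp_cpp(double force, double dt, double t_max,
                  IntegerVector edge_from, IntegerVector edge_to,
                  IntegerVector edge_pathway,
                  NumericVector k0, NumericVector dx,
                  double beta, int n_rep, double seed) {
  const int n_edge = edge_from.size();
  const long max_steps = (long)std::floor(t_max / dt + 1e-9);

  std::vector<std::vector<int>> eligible(3);
  for (int e = 0; e < n_edge; ++e) eligible[edge_from[e]].push_back(e);

  // per-state: per-interval event probabilities, probability any event
  // fires, and the shuffle-order distribution over which edge fires
  std::vector<std::vector<double>> Pev(3), Pick(3);
  std::vector<double> Pany(3, 0.0);
  for (int s = 0; s < 3; ++s) {
    const std::vector<int>& el = eligible[s];
    const int m = (int)el.size();
    Pev[s].resize(m);
    double pnone = 1.0;
    for (int j = 0; j < m; ++j) {
      double lam = k0[el[j]] * std::exp(beta * force * dx[el[j]]) * dt;
      Pev[s][j] = (lam > 700.0) ? 1.0 : -std::expm1(-lam);
      pnone *= 1.0 - Pev[s][j];
    }
    Pany[s] = 1.0 - pnone;
    // enumerate permutations (m <= 3) for P(edge j fires | any fires)
    Pick[s].assign(m, 0.0);
    if (m >= 1 && Pany[s] > 0.0) {
      std::vector<int> idx(m);
      for (int j = 0; j < m; ++j) idx[j] = j;
      int nperm = 1;
      for (int j = 2; j <= m; ++j) nperm *= j;
      double wsum = 0.0;
      std::sort(idx.begin(), idx.end());
      do {
        double carry = 1.0;
        for (int j = 0; j < m; ++j) {
          Pick[s][idx[j]] += carry * Pev[s][idx[j]];
          carry *= 1.0 - Pev[s][idx[j]];
        }
        wsum += 1.0;
      } while (std::next_permutation(idx.begin(), idx.end()));
      for (int j = 0; j < m; ++j) Pick[s][j] /= wsum * Pany[s];
      (void)nperm;
    }
  }

  NumericVector out_life(n_rep);
  IntegerVector out_pathway(n_rep), out_ntrans(n_rep);
  LogicalVector out_censored(n_rep);

  for (int r = 0; r < n_rep; ++r) {
    Xoshiro rng(replicate_seed(seed, r));
    int state = 0, ntrans = 0;
    long step = 0;
    bool ruptured = false;
    int pathway = NA_INTEGER;
    while (step < max_steps) {
      const int m = (int)eligible[state].size();
      if (m == 0 || Pany[state] <= 0.0) { step = max_steps; break; }
      // geometric number of intervals until some event fires in this state
      double u = rng.unif();
      long wait;
      if (Pany[state] >= 1.0) {
        wait = 1;
      } else {
        wait = 1 + (long)std::floor(std::log1p(-u) / std::log1p(-Pany[state]));
        if (wait < 1) wait = 1;
      }
      step += wait;
      if (step > max_steps) { step = max_steps; break; }
      // which event fired
      double v = rng.unif(), cum = 0.0;
      int j = m - 1;
      for (int jj = 0; jj < m; ++jj) {
        cum += Pick[state][jj];
        if (v < cum) { j = jj; break; }
      }
      const int e = eligible[state][j];
      if (edge_to[e] < 0) {
        ruptured = true;
        pathway = edge_pathway[e];
        break;
      }
      state = edge_to[e];
      ++ntrans;
    }
    out_life[r] = ruptured ? step * dt : t_max;
    out_pathway[r] = pathway;
    out_ntrans[r] = ntrans;
    out_censored[r] = !ruptured;
  }
  return List::create(_["lifetime"] = out_life,
                      _["pathway"] = out_pathway,
                      _["n_transitions"] = out_ntrans,
                      _["censored"] = out_censored);
}
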