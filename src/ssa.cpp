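// Direct-method stochastic simulation of a mass-action reaction network.
//
// Propensities are indexed in a Fenwick (binary indexed) tree so that firing
// a reaction costs O(log R) for the draw plus O(d log R) for the dependency
// updates, where d is the out-degree of the fired reaction in the dependency
// graph. Time-varying volume (exponential cell growth) is handled by a
// piecewise-constant refresh of the bimolecular propensities on a fixed
// internal grid; scheduled events (phage genome additions) are applied at
// their exact times. The RNG is a self-contained mt19937_64 so that runs are
// reproducible bit-for-bit across platforms for a given 32-bit seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

class Fenwick {
 public:
  explicit Fenwick(int n) : n_(n), tree_(n + 1, 0.0), val_(n, 0.0) {}

  void set(int i, double v) {
    double delta = v - val_[i];
    val_[i] = v;
    for (int j = i + 1; j <= n_; j += j & (-j)) tree_[j] += delta;
  }

  double value(int i) const { return val_[i]; }

  double total() const {
    double s = 0.0;
    for (int j = n_; j > 0; j -= j & (-j)) s += tree_[j];
    return s;
  }

  // smallest index i with prefix_sum(0..i) >= target
  int search(double target) const {
    int pos = 0;
    int bit = 1;
    while ((bit << 1) <= n_) bit <<= 1;
    for (; bit > 0; bit >>= 1) {
      int next = pos + bit;
      if (next <= n_ && tree_[next] < target) {
        pos = next;
        target -= tree_[next];
      }
    }
    return pos;  // 0-based reaction index
  }

  // rebuild exactly from stored values (guards against drift; cheap, rare)
  void rebuild() {
    std::fill(tree_.begin(), tree_.end(), 0.0);
    for (int i = 0; i < n_; ++i) {
      double v = val_[i];
      for (int j = i + 1; j <= n_; j += j & (-j)) tree_[j] += v;
    }
  }

 private:
  int n_;
  std::vector<double> tree_;
  std::vector<double> val_;
};

struct ReactionKinetics {
  int order;    // 0, 1 or 2
  int s1;       // first reactant species (-1 if none)
  int s2;       // second reactant species (-1 if none)
  bool homo;    // order-2 with stoichiometry 2 on s1
  double k;     // rate constant (already includes any constant multiplier)
  int volexp;   // 0 or -1
};

inline double propensity_of(const ReactionKinetics& rk,
                            const std::vector<long>& x, double vol) {
  switch (rk.order) {
    case 0:
      return rk.k;
    case 1:
      return rk.k * static_cast<double>(x[rk.s1]);
    default: {  // order 2
      double scale = (rk.volexp == -1) ? rk.k / vol : rk.k;
      if (rk.homo) {
        double n = static_cast<double>(x[rk.s1]);
        return scale * n * (n - 1.0) * 0.5;
      }
      return scale * static_cast<double>(x[rk.s1]) *
             static_cast<double>(x[rk.s2]);
    }
  }
}

inline double runif01(std::mt19937_64& gen) {
  return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

}  // namespace

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(IntegerMatrix reactants, IntegerMatrix net_change,
              NumericVector rates, IntegerVector order, IntegerVector volexp,
              IntegerVector x0, double v0, double growth_g, bool volume_growth,
              double horizon, double dt_out, double refresh_dt,
              NumericVector event_times, IntegerMatrix event_changes,
              int seed, double max_steps) {
  const int S = reactants.nrow();
  const int R = reactants.ncol();
  if (net_change.nrow() != S || net_change.ncol() != R)
    stop("net_change dimensions do not match reactants");

  // --- kinetics tables -----------------------------------------------------
  std::vector<ReactionKinetics> kin(R);
  for (int j = 0; j < R; ++j) {
    ReactionKinetics rk;
    rk.order = order[j];
    rk.k = rates[j];
    rk.volexp = volexp[j];
    rk.s1 = rk.s2 = -1;
    rk.homo = false;
    int found = 0;
    for (int i = 0; i < S; ++i) {
      int st = reactants(i, j);
      if (st == 0) continue;
      if (st == 2) {
        rk.s1 = i;
        rk.homo = true;
        found += 2;
      } else if (st == 1) {
        if (rk.s1 < 0)
          rk.s1 = i;
        else
          rk.s2 = i;
        found += 1;
      } else {
        stop("reactant stoichiometry must be 0, 1 or 2");
      }
    }
    if (found != rk.order)
      stop("reaction %d: reactant stoichiometry inconsistent with order", j + 1);
    kin[j] = rk;
  }

  // --- dependency graph: fired reaction -> reactions to refresh ------------
  std::vector<std::vector<int>> reactions_using(S);
  for (int j = 0; j < R; ++j) {
    if (kin[j].s1 >= 0) reactions_using[kin[j].s1].push_back(j);
    if (kin[j].s2 >= 0 && kin[j].s2 != kin[j].s1)
      reactions_using[kin[j].s2].push_back(j);
  }
  // sparse net-change lists: species touched by each reaction, with deltas
  std::vector<std::vector<std::pair<int, int>>> change(R);
  for (int j = 0; j < R; ++j)
    for (int i = 0; i < S; ++i)
      if (net_change(i, j) != 0) change[j].emplace_back(i, net_change(i, j));

  std::vector<std::vector<int>> deps(R);
  {
    std::vector<int> mark(R, -1);
    for (int j = 0; j < R; ++j) {
      for (const auto& ci : change[j]) {
        for (int r : reactions_using[ci.first]) {
          if (mark[r] != j) {
            mark[r] = j;
            deps[j].push_back(r);
          }
        }
      }
    }
  }

  // --- state ---------------------------------------------------------------
  std::vector<long> x(S);
  for (int i = 0; i < S; ++i) {
    if (x0[i] < 0) stop("negative initial count");
    x[i] = x0[i];
  }

  const int n_out = static_cast<int>(std::floor(horizon / dt_out + 1e-9)) + 1;
  NumericMatrix counts(n_out, S);
  NumericVector out_times(n_out), out_vols(n_out);

  std::mt19937_64 gen(0x9E3779B97F4A7C15ULL ^
                      (static_cast<uint64_t>(static_cast<uint32_t>(seed)) *
                       0xBF58476D1CE4E5B9ULL + 1ULL));
  gen.discard(8);

  double t = 0.0;
  double vol = v0;
  const bool growing = volume_growth && growth_g > 0.0;

  Fenwick prop(R);
  std::vector<int> all_reactions(R);
  for (int j = 0; j < R; ++j) all_reactions[j] = j;

  auto refresh = [&](const std::vector<int>& which) {
    for (int j : which) {
      double a = propensity_of(kin[j], x, vol);
      if (a < 0.0 || !std::isfinite(a))
        stop("invalid propensity %g for reaction %d at t=%g", a, j + 1, t);
      prop.set(j, a);
    }
  };
  refresh(all_reactions);

  int ev = 0;
  const int n_ev = event_times.size();
  // skip/apply events scheduled at t <= 0 before the first sample
  while (ev < n_ev && event_times[ev] <= 0.0) {
    for (int i = 0; i < S; ++i) x[i] += event_changes(i, ev);
    ++ev;
  }
  refresh(all_reactions);

  int out_i = 0;
  auto record = [&]() {
    out_times[out_i] = out_i * dt_out;
    out_vols[out_i] = growing ? v0 * std::exp(growth_g * out_times[out_i]) : v0;
    for (int i = 0; i < S; ++i) counts(out_i, i) = static_cast<double>(x[i]);
    ++out_i;
  };
  record();  // t = 0

  double next_refresh = growing ? refresh_dt : R_PosInf;
  double steps = 0.0;
  long rebuild_counter = 0;

  while (out_i < n_out) {
    double next_out = out_i * dt_out;
    double next_ev = (ev < n_ev) ? event_times[ev] : R_PosInf;
    double boundary = std::min(std::min(next_out, next_ev), next_refresh);

    double a0 = prop.total();
    double t_fire = R_PosInf;
    if (a0 > 0.0) t_fire = t - std::log(runif01(gen)) / a0;

    if (t_fire < boundary) {
      // fire one reaction
      double target = runif01(gen) * a0;
      int j = prop.search(target);
      if (j >= R) j = R - 1;
      // guard against pathological rounding picking a zero-propensity slot
      while (j > 0 && prop.value(j) <= 0.0) --j;
      for (const auto& ci : change[j]) {
        x[ci.first] += ci.second;
        if (x[ci.first] < 0)
          stop("species %d driven negative by reaction %d at t=%g",
               ci.first + 1, j + 1, t_fire);
      }
      t = t_fire;
      refresh(deps[j]);
      steps += 1.0;
      if (steps > max_steps)
        stop("SSA exceeded max_steps=%g before horizon (t=%g); "
             "raise max_steps or check rates", max_steps, t);
      if (++rebuild_counter >= 100000) {
        rebuild_counter = 0;
        prop.rebuild();
      }
    } else {
      // advance to the boundary; memorylessness makes re-drawing exact
      t = boundary;
      if (boundary == next_refresh) {
        vol = v0 * std::exp(growth_g * t);
        refresh(all_reactions);
        next_refresh += refresh_dt;
      } else if (boundary == next_ev) {
        for (int i = 0; i < S; ++i) {
          int d = event_changes(i, ev);
          if (d != 0) {
            x[i] += d;
            if (x[i] < 0) stop("event %d drove species %d negative", ev + 1, i + 1);
          }
        }
        ++ev;
        if (growing) vol = v0 * std::exp(growth_g * t);
        refresh(all_reactions);
      } else {
        record();
      }
    }
  }

  return List::create(_["times"] = out_times, _["counts"] = counts,
                      _["volumes"] = out_vols, _["steps"] = steps);
}
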