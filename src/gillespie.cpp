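#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Elastic potential evaluated in C++ (mirrors the R definitions).
struct Potential {
  int kind;                 // 0 harmonic, 1 two_regime, 2 piecewise
  double kappa, x_a;
  std::vector<double> bp, cv, slope, energy;  // piecewise tables

  double force(double x) const {
    if (kind == 0) return kappa * x;
    if (kind == 1) return kappa * (x >= x_a ? x : x_a);
    int M = cv.size();
    int j = int(std::upper_bound(bp.begin(), bp.end(), x) - bp.begin()) - 1;
    if (j < 0) j = 0;
    if (j > M - 1) j = M - 1;
    return slope[j] + cv[j] * (x - bp[j]);
  }
  double energy_at(double x) const {
    if (kind == 0) return 0.5 * kappa * x * x;
    if (kind == 1) {
      if (x >= x_a) return 0.5 * kappa * x * x;
      return 0.5 * kappa * x_a * x_a + kappa * x_a * (x - x_a);
    }
    int M = cv.size();
    int j = int(std::upper_bound(bp.begin(), bp.end(), x) - bp.begin()) - 1;
    if (j < 0) j = 0;
    if (j > M - 1) j = M - 1;
    double dx = x - bp[j];
    return energy[j] + slope[j] * dx + 0.5 * cv[j] * dx * dx;
  }
};

static double clamp_exp(double e) {
  if (e > 700.0) e = 700.0;
  return std::exp(e);
}

// Filament shift that balances the elastic forces of the bound heads
// against the external load: sum U'(x_m + delta) = F_load. The total force
// is non-decreasing in delta (convex U), so bisection on an expanding
// bracket is globally convergent.
static double equilibrate(const std::vector<double> &strains,
                          const Potential &pot, double f_load) {
  auto total = [&](double d) {
    double s = 0.0;
    for (double x : strains) s += pot.force(x + d);
    return s - f_load;
  };
  double lo = -1.0, hi = 1.0;
  int guard = 0;
  while (total(lo) > 0 && guard++ < 200) lo *= 2.0;
  guard = 0;
  while (total(hi) < 0 && guard++ < 200) hi *= 2.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (total(mid) >= 0) hi = mid; else lo = mid;
    if (hi - lo < 1e-13) break;
  }
  return 0.5 * (lo + hi);
}

// Exact stochastic simulation (Gillespie) of N_m motors pulling a rigid
// common filament against a constant external load, with instantaneous
// mechanical re-equilibration after every reaction event. States are
// 1-based as in the R package: state 1 = detached ADP.Pi pool, states
// 2..nb+1 bound, state ns = detached ATP pool. Uses R's RNG (seed with
// set.seed before calling).
//
// att_x/att_cdf: tabulated inverse-CDF of the Boltzmann attachment strain
// (ignored for harmonic potentials, where the strain is exactly normal).
// [[Rcpp::export]]
List gillespie_run(int nb, NumericVector G, NumericVector d,
                   NumericVector alpha, NumericVector k0, double dG,
                   List pot_spec, int n_motors, double f_load, double t_end,
                   NumericVector att_x, NumericVector att_cdf,
                   int thin, int max_events) {
  const int ns = nb + 2;
  Potential pot;
  pot.kind = as<int>(pot_spec["kind"]);
  pot.kappa = as<double>(pot_spec["kappa"]);
  pot.x_a = as<double>(pot_spec["x_a"]);
  if (pot.kind == 2) {
    pot.bp = as<std::vector<double>>(pot_spec["breakpoints"]);
    pot.cv = as<std::vector<double>>(pot_spec["curvatures"]);
    pot.slope = as<std::vector<double>>(pot_spec["slope_knots"]);
    pot.energy = as<std::vector<double>>(pot_spec["energy_knots"]);
  }
  const double sd_harm = (pot.kind == 0) ? std::sqrt(1.0 / pot.kappa) : 0.0;

  // pool-level hydrolysis rates (identical strain partition functions)
  const double W_f = k0[ns - 1];
  const double W_r = W_f * std::exp(G[0] + dG - G[ns - 1]);
  // constant attachment / re-attachment / first-detach rates (the lever
  // positions of the detached states equal their bound neighbours)
  const double k_att = k0[0];
  const double k_att_rev = k0[0] * std::exp(G[1] - G[0]);
  const double k_det = k0[nb];
  const double k_det_rev = k0[nb] * std::exp(G[ns - 1] - G[nb]);

  auto draw_strain = [&](double dlev) {
    if (pot.kind == 0) return R::rnorm(dlev, sd_harm);
    double u = R::unif_rand();
    int n = att_cdf.size();
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (att_cdf[mid] < u) lo = mid; else hi = mid;
    }
    double w = (u - att_cdf[lo]) /
               std::max(att_cdf[hi] - att_cdf[lo], 1e-300);
    return dlev + att_x[lo] + w * (att_x[hi] - att_x[lo]);
  };

  std::vector<int> state(n_motors, 1);        // all start detached (pool 1)
  std::vector<double> strain(n_motors, 0.0);  // valid while bound
  double X = 0.0, t = 0.0;
  long n_atp = 0;
  int all_detached_episodes = 0;
  bool frozen = true;

  std::vector<double> rec_t, rec_X;
  std::vector<int> rec_atp, rec_bound;
  std::vector<double> prop(2 * n_motors);

  auto bound_strains = [&]() {
    std::vector<double> s;
    for (int m = 0; m < n_motors; ++m)
      if (state[m] >= 2 && state[m] <= nb + 1) s.push_back(strain[m]);
    return s;
  };
  auto re_equilibrate = [&]() {
    std::vector<double> s = bound_strains();
    if (s.empty()) {
      if (!frozen) { frozen = true; all_detached_episodes++; }
      return;
    }
    frozen = false;
    double delta = equilibrate(s, pot, f_load);
    X += delta;
    for (int m = 0; m < n_motors; ++m)
      if (state[m] >= 2 && state[m] <= nb + 1) strain[m] += delta;
  };

  long ev = 0;
  int rec_count = 0;
  rec_t.push_back(0.0); rec_X.push_back(0.0);
  rec_atp.push_back(0); rec_bound.push_back(0);
  bool truncated = false;

  while (t < t_end) {
    if (++ev > max_events) { truncated = true; break; }
    double A = 0.0;
    for (int m = 0; m < n_motors; ++m) {
      double pf = 0.0, pr = 0.0;
      int s = state[m];
      if (s == 1) { pf = k_att; pr = W_r; }
      else if (s == ns) { pf = W_f; pr = k_det_rev; }
      else {
        int tfwd = s;          // transition index s: state s -> s+1 (1-based)
        if (tfwd == nb + 1) pf = k_det;
        else {
          double dU = pot.energy_at(strain[m] + d[s - 1] - d[tfwd]) -
                      pot.energy_at(strain[m]);
          // strain[m] stored relative to the current lever position; the
          // coordinate x satisfies x - d[state] = strain
          pf = clamp_exp(std::log(k0[tfwd - 1]) - alpha[tfwd - 1] * dU);
        }
        int trev = s - 1;      // transition s-1: state s -> s-1
        if (trev == 1) pr = k_att_rev;
        else {
          double dU = pot.energy_at(strain[m]) -
                      pot.energy_at(strain[m] + d[s - 1] - d[trev - 1]);
          pr = clamp_exp(std::log(k0[trev - 1]) + (G[s - 1] - G[trev - 1]) +
                         (1.0 - alpha[trev - 1]) * dU);
        }
      }
      prop[2 * m] = pf;
      prop[2 * m + 1] = pr;
      A += pf + pr;
    }
    if (A <= 0) break;
    t += R::rexp(1.0) / A;
    if (t > t_end) break;
    double u = R::unif_rand() * A;
    int m = 0, dir = 0;
    for (m = 0; m < n_motors; ++m) {
      if (u < prop[2 * m]) { dir = +1; break; }
      u -= prop[2 * m];
      if (u < prop[2 * m + 1]) { dir = -1; break; }
      u -= prop[2 * m + 1];
    }
    if (m >= n_motors) m = n_motors - 1, dir = -1;  // numerical guard

    int s = state[m];
    if (dir > 0) {
      if (s == 1) {                       // attachment into the first bound
        state[m] = 2;
        strain[m] = draw_strain(0.0);     // Boltzmann around zero strain
      } else if (s == ns) {               // hydrolysis: completes a cycle
        state[m] = 1; n_atp++;
      } else if (s == nb + 1) {           // ATP-induced detachment
        state[m] = ns;
      } else {                            // bound working transition
        strain[m] += d[s - 1] - d[s];     // lever moves, coordinate x fixed
        state[m] = s + 1;
      }
    } else {
      if (s == 1) { state[m] = ns; n_atp--; }      // reverse hydrolysis
      else if (s == ns) {                          // re-attachment to rigor
        state[m] = nb + 1;
        strain[m] = draw_strain(0.0);
      } else if (s == 2) { state[m] = 1; }         // attachment reversed
      else {
        strain[m] += d[s - 1] - d[s - 2];
        state[m] = s - 1;
      }
    }
    re_equilibrate();
    if (++rec_count >= thin) {
      rec_count = 0;
      int nbound = 0;
      for (int mm = 0; mm < n_motors; ++mm)
        if (state[mm] >= 2 && state[mm] <= nb + 1) nbound++;
      rec_t.push_back(t); rec_X.push_back(X);
      rec_atp.push_back((int)n_atp); rec_bound.push_back(nbound);
    }
  }

  return List::create(
    _["time"] = rec_t, _["X"] = rec_X, _["n_ATP"] = rec_atp,
    _["bound"] = rec_bound, _["n_events"] = (double)ev,
    _["all_detached_episodes"] = all_detached_episodes,
    _["truncated"] = truncated, _["t_final"] = t);
}
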