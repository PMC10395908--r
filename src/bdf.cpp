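#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Solve A * X = B in place for a small dense system with ncol RHS columns.
// Gaussian elimination with partial pivoting; n is tiny (number of bound
// states), so no external linear algebra is needed.
static bool small_solve(std::vector<double> &A, std::vector<double> &B,
                        int n, int ncol) {
  for (int i = 0; i < n; ++i) {
    int piv = i;
    double amax = std::fabs(A[i * n + i]);
    for (int r = i + 1; r < n; ++r) {
      double a = std::fabs(A[r * n + i]);
      if (a > amax) { amax = a; piv = r; }
    }
    if (amax == 0.0 || !std::isfinite(amax)) return false;
    if (piv != i) {
      for (int c = 0; c < n; ++c) std::swap(A[i * n + c], A[piv * n + c]);
      for (int c = 0; c < ncol; ++c) std::swap(B[i * ncol + c], B[piv * ncol + c]);
    }
    for (int r = i + 1; r < n; ++r) {
      double f = A[r * n + i] / A[i * n + i];
      if (f == 0.0) continue;
      for (int c = i; c < n; ++c) A[r * n + c] -= f * A[i * n + c];
      for (int c = 0; c < ncol; ++c) B[r * ncol + c] -= f * B[i * ncol + c];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    for (int c = 0; c < ncol; ++c) {
      double s = B[i * ncol + c];
      for (int j = i + 1; j < n; ++j) s -= A[i * n + j] * B[j * ncol + c];
      B[i * ncol + c] = s / A[i * n + i];
    }
  }
  return true;
}

// Stationary bound-state densities by downward (descending-x) integration.
//
// The stationary master equations for the bound densities P_i(x) at sliding
// velocity v > 0 form a linear ODE system dP/dx = (A(x) P - b(x)) / v with
// boundary condition P -> 0 as x -> +infinity. Rows of kf/kr/rho follow the
// descending grid x[0] = x_max, x[n] = x[0] - n*h. Integration proceeds
// downward with a non-adaptive 3-step BDF scheme (implicit; startup with
// 1- and 2-step BDF), which is stable for the stiff decay rates that arise
// when rates greatly exceed v / h.
//
// Two basis problems are integrated simultaneously (unit occupancy in each
// of the two detached pools); the caller closes the system with the pool
// stationarity condition and normalization.
//
// kf, kr: nx x (nb+1) forward/reverse rates for transitions 1..nb+1.
// rho0, rhod: Boltzmann strain densities of the two detached pools.
// n_min: minimum number of steps before early termination is allowed
//        (covers all lever positions plus thermal tails).
// decay_tol: stop once the bound mass density has decayed below this
//        fraction of its running maximum.
// [[Rcpp::export]]
List bdf_integrate(int nb, NumericMatrix kf, NumericMatrix kr,
                   NumericVector rho0, NumericVector rhod,
                   double v, double h, int n_min, double decay_tol) {
  const int nx = kf.nrow();
  const int nt = nb + 1;            // strain-resolved transitions
  if (kr.nrow() != nx || kf.ncol() != nt || kr.ncol() != nt)
    stop("rate matrix dimensions inconsistent");
  if (v <= 0) stop("bdf_integrate requires v > 0");

  NumericMatrix Pa(nx, nb), Pb(nx, nb);
  std::vector<double> A(nb * nb), B(nb * 2);
  // BDF history: rows n-1, n-2, n-3 for each basis
  int n_used = nx;
  double max_sum = 0.0;
  bool truncated = false;

  for (int n = 1; n < nx; ++n) {
    // scheme order ramps up: BDF1, BDF2, then BDF3
    double beta, c0 = 0, c1 = 0, c2 = 0;
    if (n == 1)      { beta = 1.0;        c0 = 1.0; }
    else if (n == 2) { beta = 2.0 / 3.0;  c0 = 4.0 / 3.0;  c1 = -1.0 / 3.0; }
    else             { beta = 6.0 / 11.0; c0 = 18.0 / 11.0; c1 = -9.0 / 11.0;
                       c2 = 2.0 / 11.0; }
    const double g = beta * h / v;

    for (int i = 0; i < nb; ++i) {
      for (int j = 0; j < nb; ++j) A[i * nb + j] = 0.0;
      A[i * nb + i] = 1.0 + g * (kf(n, i + 1) + kr(n, i));
      if (i > 0)      A[i * nb + (i - 1)] = -g * kf(n, i);
      if (i < nb - 1) A[i * nb + (i + 1)] = -g * kr(n, i + 1);
      double ha = c0 * Pa(n - 1, i);
      double hb = c0 * Pb(n - 1, i);
      if (n >= 2) { ha += c1 * Pa(n - 2, i); hb += c1 * Pb(n - 2, i); }
      if (n >= 3) { ha += c2 * Pa(n - 3, i); hb += c2 * Pb(n - 3, i); }
      B[i * 2 + 0] = ha;
      B[i * 2 + 1] = hb;
    }
    // pool sources: attachment feeds the first bound state (basis a),
    // reverse detachment feeds the rigor state (basis b)
    B[0 * 2 + 0] += g * kf(n, 0) * rho0[n];
    B[(nb - 1) * 2 + 1] += g * kr(n, nb) * rhod[n];

    if (!small_solve(A, B, nb, 2))
      stop("singular/non-finite step matrix in BDF integration at step %d", n);

    double s = 0.0;
    for (int i = 0; i < nb; ++i) {
      double pa = B[i * 2 + 0], pb = B[i * 2 + 1];
      if (!std::isfinite(pa) || !std::isfinite(pb))
        stop("non-finite density in BDF integration at step %d", n);
      Pa(n, i) = pa;
      Pb(n, i) = pb;
      s += std::fabs(pa) + std::fabs(pb);
    }
    if (s > max_sum) max_sum = s;
    if (n >= n_min && max_sum > 0 && s < decay_tol * max_sum) {
      n_used = n + 1;
      truncated = true;
      break;
    }
  }

  return List::create(_["Pa"] = Pa, _["Pb"] = Pb, _["n_used"] = n_used,
                      _["truncated"] = truncated, _["max_sum"] = max_sum);
}
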