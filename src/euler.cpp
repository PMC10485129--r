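#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler core for the coupled two-factor tissue ODE system.
// The signal is recomputed from the current u levels every step, s = A u.
// Sparse rows of A (common for the contact kernels) are exploited via a
// CSR scan built once up front.
// [[Rcpp::export(name = ".eulerCore")]]
List eulerCore(NumericMatrix A, NumericVector u0, NumericVector v0,
               double ru, double rv, double gu, double gv,
               double eu, double ev, double es, double evs,
               double dt, double tol, double max_steps) {
  const int n = A.nrow();
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> s(n), du(n), dv(n);

  // CSR of nonzero kernel entries; dense row-major copy when the kernel is
  // dense enough that a branch-free vectorizable loop wins.
  std::vector<int> colidx, rowptr(n + 1, 0);
  std::vector<double> val;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double a = A(i, j);
      if (a != 0.0) { colidx.push_back(j); val.push_back(a); }
    }
    rowptr[i + 1] = (int) colidx.size();
  }
  const bool dense = colidx.size() > 0.25 * n * (double) n;
  std::vector<double> Arow;
  if (dense) {
    Arow.resize((size_t) n * n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) Arow[(size_t) i * n + j] = A(i, j);
  }
  // Concentrations far below any physical scale are flushed to exact zero:
  // they are dynamically dead and subnormal arithmetic is pathologically slow.
  const double FLUSH = 1e-30;

  long clipped = 0;
  bool converged = false;
  double steps = 0;
  while (steps < max_steps) {
    if (dense) {
      for (int i = 0; i < n; ++i) {
        const double *row = &Arow[(size_t) i * n];
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += row[j] * u[j];
        s[i] = acc;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = rowptr[i]; k < rowptr[i + 1]; ++k)
          acc += val[k] * u[colidx[k]];
        s[i] = acc;
      }
    }
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double act = 1.0 + es * evs * s[i];
      double den = 1.0 + ev * v[i] * act + eu * u[i] + es * s[i];
      du[i] = ru * (eu * u[i]) / den - gu * u[i];
      dv[i] = rv * (ev * v[i] * act) / den - gv * v[i];
      double m = std::max(std::fabs(du[i]), std::fabs(dv[i]));
      if (m > dmax) dmax = m;
    }
    if (dmax < tol) { converged = true; break; }
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      u[i] += dt * du[i];
      v[i] += dt * dv[i];
      if (u[i] < 0) { u[i] = 0; ++clipped; }
      if (v[i] < 0) { v[i] = 0; ++clipped; }
      if (u[i] < FLUSH) u[i] = 0;
      if (v[i] < FLUSH) v[i] = 0;
      if (!std::isfinite(u[i]) || !std::isfinite(v[i])) bad = true;
    }
    steps += 1;
    if (bad)
      stop("integration diverged (NaN/Inf) at step %d", (long) steps);
  }
  // final signal consistent with returned u
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = rowptr[i]; k < rowptr[i + 1]; ++k)
      acc += val[k] * u[colidx[k]];
    s[i] = acc;
  }
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["s"] = NumericVector(s.begin(), s.end()),
                      _["steps"] = steps, _["converged"] = converged,
                      _["clipped"] = (double) clipped);
}
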