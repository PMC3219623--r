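// Fixed-step RK4 integration of a bilinear neural state equation coupled to
// per-region balloon hemodynamics, with a static BOLD observation.
//
// States per region: x (neural), s (vasodilatory signal), f (inflow),
// v (venous volume), q (deoxyhemoglobin) -- five states per region.
// Inputs are held constant over each microtime step (zero-order hold).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct FlowWork {                 // preallocated scratch for the flow
  mat J;
  vec Cu, fsafe, vsafe, voa, E;
  explicit FlowWork(uword n) : J(n, n), Cu(n), fsafe(n), vsafe(n),
                               voa(n), E(n) {}
};

static inline void flow(const vec& x, const vec& s, const vec& f,
                        const vec& v, const vec& q, const vec& ut,
                        const mat& A, const cube& B, const mat& C,
                        const cube& D, bool hasB, bool hasD,
                        const vec& kappa, const vec& gamma_,
                        const vec& tau, const vec& ialpha, const vec& E0,
                        FlowWork& w,
                        vec& dx, vec& ds, vec& df, vec& dv, vec& dq) {
  w.Cu = C * ut;
  if (hasB || hasD) {
    w.J = A;
    if (hasB)
      for (uword j = 0; j < B.n_slices; ++j)
        if (ut(j) != 0.0) w.J += ut(j) * B.slice(j);
    if (hasD)
      for (uword k = 0; k < D.n_slices; ++k)
        if (x(k) != 0.0) w.J += x(k) * D.slice(k);
    dx = w.J * x + w.Cu;
  } else {
    dx = A * x + w.Cu;
  }
  ds = x - kappa % s - gamma_ % (f - 1.0);
  df = s;
  w.fsafe = clamp(f, 1e-6, datum::inf);
  w.vsafe = clamp(v, 1e-6, datum::inf);
  w.voa = exp(ialpha % log(w.vsafe));             // v^(1/alpha)
  w.E = 1.0 - exp(log(1.0 - E0) / w.fsafe);       // oxygen extraction
  dv = (f - w.voa) / tau;
  dq = (w.fsafe % w.E / E0 - w.voa % q / w.vsafe) / tau;
}

// [[Rcpp::export(name = ".dcm_rk4_cpp")]]
Rcpp::List dcm_rk4_cpp(const arma::mat& A, const arma::cube& B,
                       const arma::mat& C, const arma::cube& D,
                       bool hasB, bool hasD, const arma::mat& u, double dt,
                       const arma::vec& kappa, const arma::vec& gamma_,
                       const arma::vec& tau, const arma::vec& alpha,
                       const arma::vec& E0, const arma::vec& V0,
                       const arma::vec& gain, double blowup) {
  const uword n = A.n_rows, T = u.n_cols;
  vec ialpha = 1.0 / alpha;
  vec k1 = 7.0 * E0, k3 = 2.0 * E0 - 0.2;
  const double k2 = 2.0;

  mat states(5 * n, T), bold(n, T);
  FlowWork w(n);
  vec x(n, fill::zeros), s(n, fill::zeros), f(n, fill::ones),
      v(n, fill::ones), q(n, fill::ones);
  vec dx1(n), ds1(n), df1(n), dv1(n), dq1(n),
      dx2(n), ds2(n), df2(n), dv2(n), dq2(n),
      dx3(n), ds3(n), df3(n), dv3(n), dq3(n),
      dx4(n), ds4(n), df4(n), dv4(n), dq4(n);

  int bad_t = -1;
  for (uword t = 0; t < T; ++t) {
    states.rows(0, n - 1).col(t) = x;
    states.rows(n, 2 * n - 1).col(t) = s;
    states.rows(2 * n, 3 * n - 1).col(t) = f;
    states.rows(3 * n, 4 * n - 1).col(t) = v;
    states.rows(4 * n, 5 * n - 1).col(t) = q;
    bold.col(t) = 100.0 * gain % V0 %
      (k1 % (1.0 - q) + k2 * (1.0 - q / v) + k3 % (1.0 - v));

    if (!states.col(t).is_finite() || abs(x).max() > blowup ||
        abs(s).max() > blowup || abs(f).max() > blowup ||
        abs(v).max() > blowup || abs(q).max() > blowup) {
      bad_t = (int)t;
      break;
    }
    if (t + 1 == T) break;

    const vec ut = u.col(t);
    flow(x, s, f, v, q, ut, A, B, C, D, hasB, hasD,
         kappa, gamma_, tau, ialpha, E0, w, dx1, ds1, df1, dv1, dq1);
    flow(x + 0.5 * dt * dx1, s + 0.5 * dt * ds1, f + 0.5 * dt * df1,
         v + 0.5 * dt * dv1, q + 0.5 * dt * dq1, ut, A, B, C, D, hasB, hasD,
         kappa, gamma_, tau, ialpha, E0, w, dx2, ds2, df2, dv2, dq2);
    flow(x + 0.5 * dt * dx2, s + 0.5 * dt * ds2, f + 0.5 * dt * df2,
         v + 0.5 * dt * dv2, q + 0.5 * dt * dq2, ut, A, B, C, D, hasB, hasD,
         kappa, gamma_, tau, ialpha, E0, w, dx3, ds3, df3, dv3, dq3);
    flow(x + dt * dx3, s + dt * ds3, f + dt * df3,
         v + dt * dv3, q + dt * dq3, ut, A, B, C, D, hasB, hasD,
         kappa, gamma_, tau, ialpha, E0, w, dx4, ds4, df4, dv4, dq4);

    x += dt / 6.0 * (dx1 + 2.0 * dx2 + 2.0 * dx3 + dx4);
    s += dt / 6.0 * (ds1 + 2.0 * ds2 + 2.0 * ds3 + ds4);
    f += dt / 6.0 * (df1 + 2.0 * df2 + 2.0 * df3 + df4);
    v += dt / 6.0 * (dv1 + 2.0 * dv2 + 2.0 * dv3 + dv4);
    q += dt / 6.0 * (dq1 + 2.0 * dq2 + 2.0 * dq3 + dq4);
  }

  return Rcpp::List::create(Rcpp::Named("states") = states,
                            Rcpp::Named("bold") = bold,
                            Rcpp::Named("bad_t") = bad_t);
}
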