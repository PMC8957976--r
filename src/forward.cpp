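// Forward model: bilinear neural state equation with second-order
// (modulatory) couplings, integrated jointly with a balloon-Windkessel
// hemodynamic model by classical RK4 at a fixed micro-time step.
//
// State per region: y (neural), s (vasodilatory signal), f (inflow),
// v (venous volume), q (deoxyhemoglobin); f, v, q are normalized to a
// resting value of 1, y and s rest at 0. f, v and q are integrated in log
// space so they remain strictly positive for any finite trajectory.
//
// Inputs are held constant over each micro-time bin (zero-order hold),
// matching the binary boxcar drivers used upstream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// dy = A y + C u + sum_j y[mod_j] * g_j * e_{tgt_j} * y[src_j]
inline void neural_deriv(const arma::mat& A, const arma::vec& Cu,
                         const arma::imat& didx, const arma::vec& dgain,
                         const arma::vec& y, arma::vec& dy) {
  dy = A * y + Cu;
  for (arma::uword j = 0; j < dgain.n_elem; ++j) {
    // columns of didx: modulator, source, target (0-based)
    dy(didx(j, 2)) += y(didx(j, 0)) * dgain(j) * y(didx(j, 1));
  }
}

// hemodynamics with f, v, q carried in log space (zf = log f etc.), which
// keeps them strictly positive along any finite trajectory; returns false
// on non-finite state (divergence)
inline bool hemo_deriv(const arma::vec& y, const arma::vec& s,
                       const arma::vec& zf, const arma::vec& zv,
                       const arma::vec& zq, const arma::vec& kappa,
                       const arma::vec& gam, const arma::vec& tau,
                       const arma::vec& alpha, const arma::vec& rho,
                       arma::vec& ds, arma::vec& dzf, arma::vec& dzv,
                       arma::vec& dzq) {
  const arma::uword n = y.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    if (!std::isfinite(zf(i)) || !std::isfinite(zv(i)) ||
        !std::isfinite(zq(i)) || !std::isfinite(s(i))) return false;
    double f = std::exp(zf(i)), v = std::exp(zv(i)), q = std::exp(zq(i));
    double fv = std::pow(v, 1.0 / alpha(i));          // outflow f_out(v)
    double ef = 1.0 - std::pow(1.0 - rho(i), 1.0 / f); // O2 extraction
    ds(i) = y(i) - kappa(i) * s(i) - gam(i) * (f - 1.0);
    dzf(i) = s(i) / f;
    dzv(i) = (f - fv) / (tau(i) * v);
    dzq(i) = (f * ef / rho(i) - fv * q / v) / (tau(i) * q);
  }
  return true;
}

// zv, zq are log volume / log deoxyhemoglobin
inline void bold_row(const arma::vec& zv, const arma::vec& zq,
                     const arma::vec& rho, const arma::vec& V0,
                     arma::mat& out, arma::uword t) {
  for (arma::uword i = 0; i < zv.n_elem; ++i) {
    double v = std::exp(zv(i)), q = std::exp(zq(i));
    double k1 = 7.0 * rho(i), k2 = 2.0, k3 = 2.0 * rho(i) - 0.2;
    out(t, i) = V0(i) * (k1 * (1.0 - q) + k2 * (1.0 - q / v) +
                         k3 * (1.0 - v));
  }
}

} // namespace

// Joint neural + hemodynamic forward sweep.
// U: T x K input matrix at micro-time resolution; row t applies on
// [t*dt, (t+1)*dt). Output row t is the state at time t*dt (row 0 = rest).
// status: 0 ok, 1 neural divergence (|y| > y_bound), 2 hemodynamic
// divergence (f, v or q <= 0); step reports the offending micro-step.
// [[Rcpp::export]]
List dcm_forward_cpp(const arma::mat& A, const arma::mat& C,
                     const arma::imat& didx, const arma::vec& dgain,
                     const arma::mat& U, double dt, const arma::vec& kappa,
                     const arma::vec& gam, const arma::vec& tau,
                     const arma::vec& alpha, const arma::vec& rho,
                     const arma::vec& V0, double y_bound, bool want_bold) {
  const arma::uword T = U.n_rows, n = A.n_rows;
  arma::mat neural(T, n), bold;
  if (want_bold) bold.set_size(T, n);

  // hemodynamic states in log space: rest is zf = zv = zq = 0 (f = v = q = 1)
  arma::vec y(n, arma::fill::zeros), s(n, arma::fill::zeros);
  arma::vec f(n, arma::fill::zeros), v(n, arma::fill::zeros),
      q(n, arma::fill::zeros);
  arma::vec k1(n), k2(n), k3(n), k4(n); // neural RK stages
  arma::vec ds1(n), df1(n), dv1(n), dq1(n), ds2(n), df2(n), dv2(n), dq2(n),
      ds3(n), df3(n), dv3(n), dq3(n), ds4(n), df4(n), dv4(n), dq4(n);
  arma::vec y2(n), s2(n), f2(n), v2(n), q2(n);

  int status = 0;
  arma::uword step = 0;

  for (arma::uword t = 0; t < T; ++t) {
    neural.row(t) = y.t();
    if (want_bold) bold_row(v, q, rho, V0, bold, t);
    if (t + 1 == T) break;

    arma::vec Cu = C * U.row(t).t();
    bool ok = true;

    // RK4 on the joint state, input held constant; hemodynamics are
    // carried along only when BOLD output is requested
    neural_deriv(A, Cu, didx, dgain, y, k1);
    if (want_bold) {
      ok = hemo_deriv(y, s, f, v, q, kappa, gam, tau, alpha, rho, ds1, df1,
                      dv1, dq1);
    }
    if (ok) {
      y2 = y + 0.5 * dt * k1;
      neural_deriv(A, Cu, didx, dgain, y2, k2);
      if (want_bold) {
        s2 = s + 0.5 * dt * ds1; f2 = f + 0.5 * dt * df1;
        v2 = v + 0.5 * dt * dv1; q2 = q + 0.5 * dt * dq1;
        ok = hemo_deriv(y2, s2, f2, v2, q2, kappa, gam, tau, alpha, rho,
                        ds2, df2, dv2, dq2);
      }
    }
    if (ok) {
      y2 = y + 0.5 * dt * k2;
      neural_deriv(A, Cu, didx, dgain, y2, k3);
      if (want_bold) {
        s2 = s + 0.5 * dt * ds2; f2 = f + 0.5 * dt * df2;
        v2 = v + 0.5 * dt * dv2; q2 = q + 0.5 * dt * dq2;
        ok = hemo_deriv(y2, s2, f2, v2, q2, kappa, gam, tau, alpha, rho,
                        ds3, df3, dv3, dq3);
      }
    }
    if (ok) {
      y2 = y + dt * k3;
      neural_deriv(A, Cu, didx, dgain, y2, k4);
      if (want_bold) {
        s2 = s + dt * ds3; f2 = f + dt * df3;
        v2 = v + dt * dv3; q2 = q + dt * dq3;
        ok = hemo_deriv(y2, s2, f2, v2, q2, kappa, gam, tau, alpha, rho,
                        ds4, df4, dv4, dq4);
      }
    }
    if (!ok) { status = 2; step = t + 1; break; }

    y += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (want_bold) {
      s += (dt / 6.0) * (ds1 + 2.0 * ds2 + 2.0 * ds3 + ds4);
      f += (dt / 6.0) * (df1 + 2.0 * df2 + 2.0 * df3 + df4);
      v += (dt / 6.0) * (dv1 + 2.0 * dv2 + 2.0 * dv3 + dv4);
      q += (dt / 6.0) * (dq1 + 2.0 * dq2 + 2.0 * dq3 + dq4);
    }

    if (!y.is_finite() || arma::abs(y).max() > y_bound) {
      status = 1; step = t + 1; break;
    }
    if (want_bold &&
        (!s.is_finite() || !f.is_finite() || !v.is_finite() ||
         !q.is_finite())) {
      status = 2; step = t + 1; break;
    }
  }

  List out = List::create(_["neural"] = neural, _["status"] = status,
                          _["step"] = (double)step);
  if (want_bold) out["bold"] = bold;
  return out;
}

// Hemodynamics driven by a precomputed neural trajectory (rows at micro
// times t*dt); neural input is linearly interpolated within each step so
// the RK4 half-steps see a consistent drive.
// [[Rcpp::export]]
List bold_from_neural_cpp(const arma::mat& Y, double dt,
                          const arma::vec& kappa, const arma::vec& gam,
                          const arma::vec& tau, const arma::vec& alpha,
                          const arma::vec& rho, const arma::vec& V0) {
  const arma::uword T = Y.n_rows, n = Y.n_cols;
  arma::mat bold(T, n);
  // log-space hemodynamic states, rest at 0
  arma::vec s(n, arma::fill::zeros), f(n, arma::fill::zeros),
      v(n, arma::fill::zeros), q(n, arma::fill::zeros);
  arma::vec ds1(n), df1(n), dv1(n), dq1(n), ds2(n), df2(n), dv2(n), dq2(n),
      ds3(n), df3(n), dv3(n), dq3(n), ds4(n), df4(n), dv4(n), dq4(n);
  arma::vec s2(n), f2(n), v2(n), q2(n), ya(n), ym(n), yb(n);

  int status = 0;
  arma::uword step = 0;

  for (arma::uword t = 0; t < T; ++t) {
    bold_row(v, q, rho, V0, bold, t);
    if (t + 1 == T) break;
    ya = Y.row(t).t();
    yb = Y.row(t + 1).t();
    ym = 0.5 * (ya + yb);

    bool ok = hemo_deriv(ya, s, f, v, q, kappa, gam, tau, alpha, rho, ds1,
                         df1, dv1, dq1);
    if (ok) {
      s2 = s + 0.5 * dt * ds1; f2 = f + 0.5 * dt * df1;
      v2 = v + 0.5 * dt * dv1; q2 = q + 0.5 * dt * dq1;
      ok = hemo_deriv(ym, s2, f2, v2, q2, kappa, gam, tau, alpha, rho, ds2,
                      df2, dv2, dq2);
    }
    if (ok) {
      s2 = s + 0.5 * dt * ds2; f2 = f + 0.5 * dt * df2;
      v2 = v + 0.5 * dt * dv2; q2 = q + 0.5 * dt * dq2;
      ok = hemo_deriv(ym, s2, f2, v2, q2, kappa, gam, tau, alpha, rho, ds3,
                      df3, dv3, dq3);
    }
    if (ok) {
      s2 = s + dt * ds3; f2 = f + dt * df3;
      v2 = v + dt * dv3; q2 = q + dt * dq3;
      ok = hemo_deriv(yb, s2, f2, v2, q2, kappa, gam, tau, alpha, rho, ds4,
                      df4, dv4, dq4);
    }
    if (!ok) { status = 2; step = t + 1; break; }

    s += (dt / 6.0) * (ds1 + 2.0 * ds2 + 2.0 * ds3 + ds4);
    f += (dt / 6.0) * (df1 + 2.0 * df2 + 2.0 * df3 + df4);
    v += (dt / 6.0) * (dv1 + 2.0 * dv2 + 2.0 * dv3 + dv4);
    q += (dt / 6.0) * (dq1 + 2.0 * dq2 + 2.0 * dq3 + dq4);

    if (!s.is_finite() || !f.is_finite() || !v.is_finite() ||
        !q.is_finite()) {
      status = 2; step = t + 1; break;
    }
  }

  return List::create(_["bold"] = bold, _["status"] = status,
                      _["step"] = (double)step);
}
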