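#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 advance of the three-variable delayed system
//
//   dx/dt = f_x(y(t - tau_e)) + k_rz * z(t - tau_r) - (k_rx + k_dx) * x
//   dy/dt = f_a(x(t - tau_a)) * (y0 - y) - f_b(x(t - tau_b)) * y
//   dz/dt = k_rx * x - (k_rz + k_dz) * z
//
// with generalized Hill controls f_d(u) = k_d0 + k_d (u/K_d)^h / (1 + (u/K_d)^h).
// Lagged values are read back from the stored solution record via 4-point
// (cubic) Lagrange interpolation on the uniform step grid; a zero delay falls
// back to the current stage state, so the scheme degenerates to classical RK4
// on the reduced ODE. The pre-history is a constant triple.

struct Pars {
  double k_a0, k_a, K_a, h_a, y0;
  double k_b0, k_b, K_b, h_b;
  double k_x0, k_x, K_x, h_x;
  double k_dx, k_rx, k_dz, k_rz;
};

static inline double hill(double u, double k0, double k, double K, double h) {
  double r = std::pow(u / K, h);
  if (!std::isfinite(r)) return k0 + k;   // saturation limit for huge u
  return k0 + k * r / (1.0 + r);
}

// Interpolated lookup of one component at time s (s > 0) from nodes 0..front.
// Stencil is clamped to the computed front; delays are validated upstream to
// be 0 or >= 4h so the stencil never truly extrapolates.
static inline double lag_lookup(const std::vector<double>& rec, double s,
                                double h, int front, double hist_val) {
  if (s <= 1e-12) return hist_val;
  double u = s / h;
  int j0 = (int)std::floor(u) - 1;
  if (j0 < 0) j0 = 0;
  if (j0 > front - 3) j0 = front - 3;
  double p = u - j0;
  double w0 = -(p - 1.0) * (p - 2.0) * (p - 3.0) / 6.0;
  double w1 = p * (p - 2.0) * (p - 3.0) / 2.0;
  double w2 = -p * (p - 1.0) * (p - 3.0) / 2.0;
  double w3 = p * (p - 1.0) * (p - 2.0) / 6.0;
  return w0 * rec[j0] + w1 * rec[j0 + 1] + w2 * rec[j0 + 2] + w3 * rec[j0 + 3];
}

struct Lags {
  double xa, xb, ye, zr;
};

static inline void rhs(const Pars& P, double sx, double sy, double sz,
                       const Lags& L, double* d) {
  d[0] = hill(L.ye, P.k_x0, P.k_x, P.K_x, P.h_x) + P.k_rz * L.zr -
         (P.k_rx + P.k_dx) * sx;
  d[1] = hill(L.xa, P.k_a0, P.k_a, P.K_a, P.h_a) * (P.y0 - sy) -
         hill(L.xb, P.k_b0, P.k_b, P.K_b, P.h_b) * sy;
  d[2] = P.k_rx * sx - (P.k_rz + P.k_dz) * sz;
}

// [[Rcpp::export(name = ".dde_rk4_cpp")]]
List dde_rk4_cpp(NumericVector par, NumericVector tau, NumericVector hist,
                 double h, double t_end, int stride, double neg_tol) {
  Pars P;
  P.k_a0 = par[0];  P.k_a = par[1];  P.K_a = par[2];  P.h_a = par[3];
  P.y0  = par[4];   P.k_b0 = par[5]; P.k_b = par[6];  P.K_b = par[7];
  P.h_b = par[8];   P.k_x0 = par[9]; P.k_x = par[10]; P.K_x = par[11];
  P.h_x = par[12];  P.k_dx = par[13]; P.k_rx = par[14];
  P.k_dz = par[15]; P.k_rz = par[16];

  const double ta = tau[0], tb = tau[1], tr = tau[2], te = tau[3];
  const double hx0 = hist[0], hy0 = hist[1], hz0 = hist[2];

  const long n = (long)std::llround(t_end / h);
  if (n < 4) stop("integration span too short for the chosen step");
  for (int i = 0; i < 4; ++i) {
    if (tau[i] > 0.0 && tau[i] < 4.0 * h)
      stop("each positive delay must be at least 4 steps long; reduce h");
  }

  std::vector<double> X(n + 1), Y(n + 1), Z(n + 1);
  X[0] = hx0; Y[0] = hy0; Z[0] = hz0;

  const double c[4] = {0.0, 0.5, 0.5, 1.0};
  double k[4][3], d[3], st[3];

  for (long i = 0; i < n; ++i) {
    const double t = i * h;
    const double x = X[i], y = Y[i], z = Z[i];
    for (int s = 0; s < 4; ++s) {
      const double ts = t + c[s] * h;
      if (s == 0) {
        st[0] = x; st[1] = y; st[2] = z;
      } else {
        const double a = c[s] * h;
        st[0] = x + a * k[s - 1][0];
        st[1] = y + a * k[s - 1][1];
        st[2] = z + a * k[s - 1][2];
      }
      Lags L;
      L.xa = (ta == 0.0) ? st[0] : lag_lookup(X, ts - ta, h, (int)i, hx0);
      L.xb = (tb == 0.0) ? st[0] : lag_lookup(X, ts - tb, h, (int)i, hx0);
      L.ye = (te == 0.0) ? st[1] : lag_lookup(Y, ts - te, h, (int)i, hy0);
      L.zr = (tr == 0.0) ? st[2] : lag_lookup(Z, ts - tr, h, (int)i, hz0);
      rhs(P, st[0], st[1], st[2], L, d);
      k[s][0] = d[0]; k[s][1] = d[1]; k[s][2] = d[2];
    }
    X[i + 1] = x + h / 6.0 * (k[0][0] + 2.0 * k[1][0] + 2.0 * k[2][0] + k[3][0]);
    Y[i + 1] = y + h / 6.0 * (k[0][1] + 2.0 * k[1][1] + 2.0 * k[2][1] + k[3][1]);
    Z[i + 1] = z + h / 6.0 * (k[0][2] + 2.0 * k[1][2] + 2.0 * k[2][2] + k[3][2]);
    if (!std::isfinite(X[i + 1]) || !std::isfinite(Y[i + 1]) ||
        !std::isfinite(Z[i + 1]))
      stop("integration diverged (non-finite state) at t = %.4f", t + h);
    if (X[i + 1] < -neg_tol || Y[i + 1] < -neg_tol || Z[i + 1] < -neg_tol)
      stop("state left the nonnegative orthant at t = %.4f", t + h);
  }

  const long m = n / stride + 1;
  NumericVector tt(m), xo(m), yo(m), zo(m);
  for (long j = 0; j < m; ++j) {
    const long i = j * stride;
    tt[j] = i * h; xo[j] = X[i]; yo[j] = Y[i]; zo[j] = Z[i];
  }
  return List::create(_["t"] = tt, _["x"] = xo, _["y"] = yo, _["z"] = zo);
}
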