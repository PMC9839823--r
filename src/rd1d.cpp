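// Compiled core for the 1D Lagrangian reaction-diffusion solver.
//
// State layout: per grid node i the block (u_1, ..., u_m, mu), so
// y[i*(m+1) + c] with c < m a species and c == m the local dilation mu.
// The semi-discrete system is
//   du_s/dt = (D_s / dX^2) * L_s(u, mu)  - u_s * S(t, u) + f_s(u)
//   dmu/dt  = mu * S(t, u)
// where L_s is the metric-weighted second-difference stencil
//   (1/(2 mu_i)) [ (1/mu_i)(u_{i+1}+u_{i-1}-2u_i)
//                + (1/mu_{i+1})(u_{i+1}-u_i) + (1/mu_{i-1})(u_{i-1}-u_i) ]
// with Neumann boundaries by ghost-node reflection for both u and mu.
//
// Time integration: adaptive L-stable SDIRK3 (Alexander's 3-stage,
// stiffly accurate, gamma the root of g^3 - 3g^2 + 3g/2 - 1/6) with an
// embedded 2nd-order error estimate, modified Newton iterations and a
// banded finite-difference Jacobian factorized by LAPACK dgbtrf.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
# define FCONE
#endif
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Model {
  int m;              // number of species
  int N;              // number of grid nodes
  double dX;          // Lagrangian grid spacing (uniform within an epoch)
  std::vector<double> D;
  int kcode;          // 1 schnak, 2 GM, 3 FHN, 4 logistic, 5 bistable, 0 custom
  double kp[4];       // a, b, c, i0 as applicable
  int gcode;          // 1 const, 2 prescribed_t, 3 linear, 4 tanh,
                      // 5 quadratic_ratio, 6 difference, 0 custom
  double gp[3];
  SEXP kfn;           // R callback f(t, U[m x N]) -> m x N, or R_NilValue
  SEXP gfn;           // R callback S(t, U[m x N]) -> N,     or R_NilValue
};

inline void kinetics_eval(const Model& M, const double* u, double* f) {
  const double* p = M.kp;
  switch (M.kcode) {
  case 1:  // Schnakenberg: a - u + u^2 v, b - u^2 v
    f[0] = p[0] - u[0] + u[0] * u[0] * u[1];
    f[1] = p[1] - u[0] * u[0] * u[1];
    break;
  case 2:  // Gierer-Meinhardt (activator form): a + u^2/v - b u, u^2 - c v
    f[0] = p[0] + u[0] * u[0] / u[1] - p[1] * u[0];
    f[1] = u[0] * u[0] - p[2] * u[1];
    break;
  case 3:  // FitzHugh-Nagumo
    f[0] = p[2] * (u[0] - u[0] * u[0] * u[0] / 3.0 + u[1] - p[3]);
    f[1] = (p[0] - u[0] - p[1] * u[1]) / p[2];
    break;
  case 4: f[0] = u[0] * (1.0 - u[0]); break;
  case 5: f[0] = u[0] * (1.0 - u[0] * u[0]); break;
  default: for (int s = 0; s < M.m; ++s) f[s] = 0.0;
  }
}

inline double growth_eval(const Model& M, double t, const double* u) {
  const double* p = M.gp;
  switch (M.gcode) {
  case 1: return p[0];
  case 3: return p[0] + p[1] * u[0];
  case 4: return p[0] * (1.0 + std::tanh(p[2] * (u[0] - p[1])));
  case 5: return p[0] * ((u[0] / p[1]) * (u[0] / p[1]) - 1.0);
  case 6: return p[0] * (u[0] - p[1] * u[1]);
  default: return 0.0;  // custom / prescribed handled via callback
  }
}

// Full right-hand side. Custom kinetics / growth laws go through a single
// vectorized R callback per evaluation.
void rhs(const Model& M, double t, const double* y, double* dy) {
  const int m = M.m, N = M.N, B = m + 1;
  const double idX2 = 1.0 / (M.dX * M.dX);

  std::vector<double> fcustom, scustom;
  const bool kin_custom = (M.kcode == 0) && (M.kfn != R_NilValue);
  const bool gr_custom = (M.gcode == 0 || M.gcode == 2) && (M.gfn != R_NilValue);
  if (kin_custom || gr_custom) {
    NumericMatrix U(m, N);
    for (int i = 0; i < N; ++i)
      for (int s = 0; s < m; ++s) U(s, i) = y[i * B + s];
    if (kin_custom) {
      Function fk(M.kfn);
      NumericMatrix F = fk(t, U);
      fcustom.assign(F.begin(), F.end());
    }
    if (gr_custom) {
      Function fg(M.gfn);
      NumericVector S = fg(t, U);
      scustom.assign(S.begin(), S.end());
    }
  }

  double fbuf[2];
  for (int i = 0; i < N; ++i) {
    const int im = (i == 0) ? 1 : i - 1;
    const int ip = (i == N - 1) ? N - 2 : i + 1;
    const double mu  = y[i * B + m];
    const double mum = y[im * B + m];
    const double mup = y[ip * B + m];
    const double* u = y + i * B;

    double S = gr_custom ? scustom[i] : growth_eval(M, t, u);
    if (kin_custom) {
      for (int s = 0; s < m; ++s) fbuf[s] = fcustom[i * m + s];
    } else {
      kinetics_eval(M, u, fbuf);
    }

    for (int s = 0; s < m; ++s) {
      const double uc = u[s];
      const double um = y[im * B + s];
      const double up = y[ip * B + s];
      const double lap = (1.0 / (2.0 * mu)) *
        ((up + um - 2.0 * uc) / mu + (up - uc) / mup + (um - uc) / mum);
      dy[i * B + s] = M.D[s] * lap * idX2 - uc * S + fbuf[s];
    }
    dy[i * B + m] = mu * S;
  }
}

// Banded LAPACK helpers ------------------------------------------------

struct BandMat {
  int n, kl, ku, ldab;
  std::vector<double> ab;
  std::vector<int> ipiv;
  BandMat(int n_, int kl_, int ku_)
    : n(n_), kl(kl_), ku(ku_), ldab(2 * kl_ + ku_ + 1),
      ab((size_t)ldab * n_), ipiv(n_) {}
  // store A(i,j), 0-based
  inline double& at(int i, int j) { return ab[(size_t)ldab * j + kl + ku + i - j]; }
  void zero() { std::fill(ab.begin(), ab.end(), 0.0); }
  bool factor() {
    int info = 0;
    F77_CALL(dgbtrf)(&n, &n, &kl, &ku, ab.data(), &ldab, ipiv.data(), &info);
    return info == 0;
  }
  void solve(double* b) {
    int info = 0, nrhs = 1;
    F77_CALL(dgbtrs)("N", &n, &kl, &ku, &nrhs, ab.data(), &ldab,
                     ipiv.data(), b, &n, &info FCONE);
  }
};

// Banded finite-difference Jacobian of the RHS, column grouping with
// stride kl + ku + 1.
void banded_fd_jacobian(const Model& M, double t, const double* y,
                        const double* f0, int n, int bw,
                        std::vector<double>& jac /* ldj = 2bw+1 packed */) {
  const int stride = 2 * bw + 1;
  std::vector<double> yp(y, y + n), fp(n);
  std::fill(jac.begin(), jac.end(), 0.0);
  for (int g = 0; g < stride && g < n; ++g) {
    std::vector<double> h(n, 0.0);
    for (int j = g; j < n; j += stride) {
      h[j] = 1e-7 * std::max(1.0, std::fabs(y[j]));
      yp[j] = y[j] + h[j];
    }
    rhs(M, t, yp.data(), fp.data());
    for (int j = g; j < n; j += stride) {
      const int ilo = std::max(0, j - bw), ihi = std::min(n - 1, j + bw);
      for (int i = ilo; i <= ihi; ++i)
        jac[(size_t)stride * j + bw + i - j] = (fp[i] - f0[i]) / h[j];
      yp[j] = y[j];
    }
  }
}

inline double wrms(const std::vector<double>& e, const std::vector<double>& w) {
  double s = 0.0;
  for (size_t i = 0; i < e.size(); ++i) { double q = e[i] / w[i]; s += q * q; }
  return std::sqrt(s / e.size());
}

} // namespace

//' @name rd1d_rhs_cpp
//' @title Compiled right-hand side of the 1D Lagrangian system (internal)
//' @keywords internal
// [[Rcpp::export]]
NumericVector rd1d_rhs_cpp(double t, NumericVector y, int m, double dX,
                           NumericVector D, int kcode, NumericVector kpar,
                           int gcode, NumericVector gpar,
                           SEXP kfn, SEXP gfn) {
  Model M;
  M.m = m; M.N = y.size() / (m + 1); M.dX = dX;
  M.D.assign(D.begin(), D.end());
  M.kcode = kcode; M.gcode = gcode;
  for (int i = 0; i < 4; ++i) M.kp[i] = (i < kpar.size()) ? kpar[i] : 0.0;
  for (int i = 0; i < 3; ++i) M.gp[i] = (i < gpar.size()) ? gpar[i] : 0.0;
  M.kfn = kfn; M.gfn = gfn;
  NumericVector dy(y.size());
  rhs(M, t, y.begin(), dy.begin());
  return dy;
}

//' @name rd1d_integrate_cpp
//' @title Adaptive SDIRK3 integration of the 1D Lagrangian system (internal)
//' @keywords internal
// [[Rcpp::export]]
List rd1d_integrate_cpp(NumericVector y0, double t0, double t1, int m,
                        double dX, NumericVector D, int kcode,
                        NumericVector kpar, int gcode, NumericVector gpar,
                        SEXP kfn, SEXP gfn, double rtol, double atol,
                        double h0, double hmax, int max_steps) {
  Model M;
  M.m = m; M.N = y0.size() / (m + 1); M.dX = dX;
  M.D.assign(D.begin(), D.end());
  M.kcode = kcode; M.gcode = gcode;
  for (int i = 0; i < 4; ++i) M.kp[i] = (i < kpar.size()) ? kpar[i] : 0.0;
  for (int i = 0; i < 3; ++i) M.gp[i] = (i < gpar.size()) ? gpar[i] : 0.0;
  M.kfn = kfn; M.gfn = gfn;

  const int n = y0.size();
  const int B = m + 1;
  const int bw = 2 * B - 1;          // Jacobian half-bandwidth
  const int jstride = 2 * bw + 1;

  // Alexander's SDIRK3
  const double g = 0.43586652150845899941601945;
  const double c2 = (1.0 + g) / 2.0;
  const double a21 = (1.0 - g) / 2.0;
  const double b1 = -(6.0 * g * g - 16.0 * g + 1.0) / 4.0;
  const double b2 = (6.0 * g * g - 20.0 * g + 5.0) / 4.0;
  const double b3 = g;
  // embedded order-2 weights (bh3 = 0)
  const double bh2 = (1.0 - 2.0 * g) / (1.0 - g);
  const double bh1 = 1.0 - bh2;

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> f0(n), w(n), err(n);
  std::vector<double> k1(n), k2(n), k3(n), Y(n), rc(n), G(n), dlt(n);
  std::vector<double> jac((size_t)jstride * n);
  BandMat A(n, bw, bw);

  double t = t0;
  double h = (h0 > 0) ? h0 : std::min((t1 - t0) * 1e-3, 1e-2);
  if (hmax <= 0) hmax = t1 - t0;
  h = std::min(h, hmax);
  long nsteps = 0, nreject = 0, nfeval = 0, njac = 0;

  while (t < t1 - 1e-14 * std::max(1.0, std::fabs(t1))) {
    if (++nsteps > max_steps)
      stop("rd1d integrator: step budget exceeded at t = %g (h = %g)", t, h);
    if (t + h > t1) h = t1 - t;

    rhs(M, t, y.data(), f0.data()); ++nfeval;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(f0[i]))
        stop("rd1d integrator: non-finite RHS at t = %g (component %d)", t, i + 1);
      w[i] = atol + rtol * std::fabs(y[i]);
    }
    banded_fd_jacobian(M, t, y.data(), f0.data(), n, bw, jac);
    nfeval += std::min(jstride, n); ++njac;

    bool step_done = false;
    while (!step_done) {
      // assemble and factor I - h*g*J
      A.zero();
      for (int j = 0; j < n; ++j) {
        const int ilo = std::max(0, j - bw), ihi = std::min(n - 1, j + bw);
        for (int i = ilo; i <= ihi; ++i)
          A.at(i, j) = ((i == j) ? 1.0 : 0.0) -
            h * g * jac[(size_t)jstride * j + bw + i - j];
      }
      if (!A.factor()) { h *= 0.5; ++nreject; continue; }

      // stage solver: solve Y = rc + h*g*F(tc, Y) by modified Newton
      auto stage = [&](double tc, const std::vector<double>& rcv,
                       std::vector<double>& Yv, std::vector<double>& kv,
                       const double* pred) -> bool {
        for (int i = 0; i < n; ++i) Yv[i] = pred ? pred[i] : rcv[i];
        for (int it = 0; it < 10; ++it) {
          rhs(M, tc, Yv.data(), G.data()); ++nfeval;
          for (int i = 0; i < n; ++i) {
            if (!std::isfinite(G[i])) return false;
            dlt[i] = rcv[i] + h * g * G[i] - Yv[i];
          }
          A.solve(dlt.data());
          for (int i = 0; i < n; ++i) Yv[i] += dlt[i];
          if (wrms(dlt, w) < 1e-2) {
            rhs(M, tc, Yv.data(), G.data()); ++nfeval;
            for (int i = 0; i < n; ++i) kv[i] = G[i];
            return true;
          }
        }
        return false;
      };

      bool ok = true;
      // stage 1
      for (int i = 0; i < n; ++i) rc[i] = y[i];
      {
        std::vector<double> pred(n);
        for (int i = 0; i < n; ++i) pred[i] = y[i] + h * g * f0[i];
        ok = stage(t + g * h, rc, Y, k1, pred.data());
      }
      // stage 2
      if (ok) {
        for (int i = 0; i < n; ++i) rc[i] = y[i] + h * a21 * k1[i];
        ok = stage(t + c2 * h, rc, Y, k2, Y.data());
      }
      // stage 3 (stiffly accurate: Y is y_{n+1})
      if (ok) {
        for (int i = 0; i < n; ++i) rc[i] = y[i] + h * (b1 * k1[i] + b2 * k2[i]);
        ok = stage(t + h, rc, Y, k3, Y.data());
      }

      if (!ok) { h *= 0.5; ++nreject;
        if (h < 1e-14 * std::max(1.0, std::fabs(t)))
          stop("rd1d integrator: step size underflow at t = %g "
               "(Newton failure)", t);
        continue; }

      // embedded error, smoothed by one implicit solve (L-stable filter)
      for (int i = 0; i < n; ++i)
        err[i] = h * ((b1 - bh1) * k1[i] + (b2 - bh2) * k2[i] + b3 * k3[i]);
      A.solve(err.data());
      const double enorm = wrms(err, w);

      if (enorm <= 1.0) {
        t += h;
        y = Y;
        for (int i = 0; i < M.N; ++i)
          if (y[i * B + m] <= 0.0)
            stop("rd1d integrator: mu <= 0 at t = %g, node %d "
                 "(domain map degenerate)", t, i + 1);
        step_done = true;
        double fac = 0.9 * std::pow(std::max(enorm, 1e-10), -1.0 / 3.0);
        h *= std::min(5.0, std::max(0.2, fac));
        h = std::min(h, hmax);
      } else {
        ++nreject;
        double fac = 0.9 * std::pow(enorm, -1.0 / 3.0);
        h *= std::min(0.9, std::max(0.1, fac));
        if (h < 1e-14 * std::max(1.0, std::fabs(t)))
          stop("rd1d integrator: step size underflow at t = %g "
               "(error control)", t);
      }
    }
  }

  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["t"] = t, _["nsteps"] = (double)nsteps,
                      _["nreject"] = (double)nreject,
                      _["nfeval"] = (double)nfeval,
                      _["njac"] = (double)njac,
                      _["hlast"] = h);
}

// Counter-based normal variates -----------------------------------------
//
// splitmix64 keyed by (seed, stream, counter) with Box-Muller, so initial
// condition noise at a given node index is independent of grid resolution.

namespace {
inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
inline double u01(std::uint64_t z) {
  return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
}

//' @name counter_normals_cpp
//' @title Counter-based standard normal variates (internal)
//' @keywords internal
// [[Rcpp::export]]
NumericVector counter_normals_cpp(int seed, int stream, int n) {
  NumericVector out(n);
  const std::uint64_t base =
    (static_cast<std::uint64_t>(static_cast<std::uint32_t>(seed)) << 32) ^
    (static_cast<std::uint64_t>(static_cast<std::uint32_t>(stream)) << 1) ^
    0xD1B54A32D192ED03ULL;
  for (int i = 0; i < n; ++i) {
    std::uint64_t k = base + 0x100000001ULL * static_cast<std::uint64_t>(i);
    double u1 = u01(splitmix64(k));
    double u2 = u01(splitmix64(k ^ 0x6A09E667F3BCC909ULL));
    out[i] = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  return out;
}
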