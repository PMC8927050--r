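// Core numerics for the 1D moving-boundary gel model on the mapped domain
// X in [0,1]: quasi-static polymer-velocity BVP, Crank-Nicolson transport of
// the polymer fraction and cell density, forward-Euler boundary motion.
//
// The velocity equation is
//   (2+kp) ts/L^2 d/dX( th dvp/dX )
//   + (2es+ks) th/L^2 d/dX( ts d/dX( th vp / ts ) )
//   - xi th vp - th ts f''(th)/L dth/dX + ts/L d/dX(th G) = 0,
// with vp(0)=0 and, at X=1,
//   (2+kp) th/L dvp/dX + (2es+ks) th/L d/dX(th vp/ts)
//   + th G + mu_s - mu_s^e + R vp = 0.
// Nested derivatives are expanded by the product rule; central second-order
// stencils are used in the interior, one-sided second-order stencils for
// derivatives of th at X=1, and the boundary condition eliminates a ghost
// value of vp beyond X=1, keeping the system tridiagonal.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct ModelPars {
  double C1;      // 2 + kappa_p
  double C2;      // 2 eta_s + kappa_s
  double xi, R, D, N, chi, tau0, lambda;
};

static ModelPars as_pars(const List& p) {
  ModelPars m;
  m.C1 = 2.0 + as<double>(p["kappa_p"]);
  m.C2 = 2.0 * as<double>(p["eta_s"]) + as<double>(p["kappa_s"]);
  m.xi = as<double>(p["xi"]);
  m.R = as<double>(p["R"]);
  m.D = as<double>(p["D"]);
  m.N = as<double>(p["N"]);
  m.chi = as<double>(p["chi"]);
  m.tau0 = as<double>(p["tau0"]);
  m.lambda = as<double>(p["lambda"]);
  return m;
}

static inline double fpp(double th, const ModelPars& m) {
  return 1.0 / (m.N * th) + 1.0 / (1.0 - th) - 2.0 * m.chi;
}
// mu_s - mu_s^e (the standard free energies cancel)
static inline double mus_diff(double th, const ModelPars& m) {
  return std::log(1.0 - th) + th * (1.0 - 1.0 / m.N) + m.chi * th * th;
}
static inline double Gfun(double n, const ModelPars& m) {
  double d = 1.0 + m.lambda * n * n;
  return m.tau0 * n * n / d;
}
static inline double dGfun(double n, const ModelPars& m) {
  double d = 1.0 + m.lambda * n * n;
  return 2.0 * m.tau0 * n / (d * d);
}

// Thomas algorithm; a = sub, b = diag, c = super, d = rhs (overwritten).
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    if (!std::isfinite(w)) stop("tridiagonal solve failed at row %d", i);
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

// Spatial derivative arrays for a field with symmetry at X=0 (zero slope)
// and one-sided second-order differences at X=1.
static void deriv_arrays(const std::vector<double>& f, double dX,
                         std::vector<double>& d1, std::vector<double>& d2) {
  int M = (int)f.size();
  d1[0] = 0.0;
  d2[0] = 2.0 * (f[1] - f[0]) / (dX * dX); // ghost f[-1] = f[1]
  for (int i = 1; i < M - 1; ++i) {
    d1[i] = (f[i + 1] - f[i - 1]) / (2.0 * dX);
    d2[i] = (f[i + 1] - 2.0 * f[i] + f[i - 1]) / (dX * dX);
  }
  d1[M - 1] = (3.0 * f[M - 1] - 4.0 * f[M - 2] + f[M - 3]) / (2.0 * dX);
  d2[M - 1] = (2.0 * f[M - 1] - 5.0 * f[M - 2] + 4.0 * f[M - 3] - f[M - 4]) /
              (dX * dX);
}

static void velocity_solve(const std::vector<double>& th,
                           const std::vector<double>& n, double L, double dX,
                           const ModelPars& m, std::vector<double>& vp) {
  int M = (int)th.size();
  if (M < 4) stop("grid must have at least 4 nodes");
  for (int i = 0; i < M; ++i)
    if (th[i] <= 0.0 || th[i] >= 1.0)
      stop("theta_p out of (0,1) at node %d; clamp before solving", i + 1);

  std::vector<double> dth(M), d2th(M), dn(M), d2n(M);
  deriv_arrays(th, dX, dth, d2th);
  deriv_arrays(n, dX, dn, d2n);

  double L2 = L * L;
  std::vector<double> sub(M, 0.0), dia(M, 0.0), sup(M, 0.0), rhs(M, 0.0);

  // X = 0: strong no-slip/symmetry
  dia[0] = 1.0;
  rhs[0] = 0.0;

  for (int i = 1; i < M; ++i) {
    double a = th[i], b = 1.0 - th[i];
    double ap = dth[i], app = d2th[i];
    double P = (m.C1 * a * b + m.C2 * a * a) / L2;
    double Q = (m.C1 * b * ap + m.C2 * a * ap * (2.0 - a) / b) / L2;
    double S = m.C2 * a * (app / b + ap * ap / (b * b)) / L2 - m.xi * a;
    double G = Gfun(n[i], m);
    double dThG = ap * G + a * dGfun(n[i], m) * dn[i];
    double R_i = a * b * fpp(a, m) * ap / L - b * dThG / L;

    if (i < M - 1) {
      sub[i] = P / (dX * dX) - Q / (2.0 * dX);
      dia[i] = -2.0 * P / (dX * dX) + S;
      sup[i] = P / (dX * dX) + Q / (2.0 * dX);
      rhs[i] = R_i;
    } else {
      // ghost node beyond X=1 eliminated via the stress boundary condition
      double cb = a / b;
      double cbp = ap / (b * b);
      double B1 = (a / L) * (m.C1 + m.C2 * cb);
      double B2 = (a / L) * m.C2 * cbp + m.R;
      double B3 = a * G + mus_diff(a, m);
      double pc = P / (dX * dX);
      double qc = Q / (2.0 * dX);
      sub[i] = 2.0 * pc;
      dia[i] = -2.0 * pc + S - (pc + qc) * (2.0 * dX * B2 / B1);
      sup[i] = 0.0;
      rhs[i] = R_i + (pc + qc) * (2.0 * dX * B3 / B1);
    }
  }
  thomas(sub, dia, sup, rhs, vp);
}

// One Crank-Nicolson transport step for a field q on the mapped domain:
//   dq/dT + (1/L) d/dX(q u) + (Ldot/L) q = (Dc/L^2) d2q/dX2,
// where u = vp - X Ldot (u vanishes at both ends). Conservative half-node
// fluxes with half-cells at the boundaries make the spatial operator
// telescoping, so the trapezoidal mass L * integral(q) is conserved to the
// accuracy of the time coupling. No-flux diffusion boundaries.
static void cn_transport(std::vector<double>& q, const std::vector<double>& u,
                         double L, double Ldot, double dT, double dX,
                         double Dc) {
  int M = (int)q.size();
  std::vector<double> Asub(M, 0.0), Adia(M, 0.0), Asup(M, 0.0);
  double LdX = L * dX;
  double dil = Ldot / L;
  double dcoef = Dc / (L * L * dX * dX);

  // advective half-node velocities
  std::vector<double> uh(M - 1);
  for (int i = 0; i < M - 1; ++i) uh[i] = 0.5 * (u[i] + u[i + 1]);

  Adia[0] = uh[0] / LdX + dil + 2.0 * dcoef;
  Asup[0] = uh[0] / LdX - 2.0 * dcoef;
  for (int i = 1; i < M - 1; ++i) {
    Asub[i] = -uh[i - 1] / (2.0 * LdX) - dcoef;
    Adia[i] = (uh[i] - uh[i - 1]) / (2.0 * LdX) + dil + 2.0 * dcoef;
    Asup[i] = uh[i] / (2.0 * LdX) - dcoef;
  }
  Asub[M - 1] = -uh[M - 2] / LdX - 2.0 * dcoef;
  Adia[M - 1] = -uh[M - 2] / LdX + dil + 2.0 * dcoef;

  std::vector<double> sub(M), dia(M), sup(M), rhs(M), out(M);
  double h = 0.5 * dT;
  for (int i = 0; i < M; ++i) {
    sub[i] = h * Asub[i];
    dia[i] = 1.0 + h * Adia[i];
    sup[i] = h * Asup[i];
    double r = q[i] - h * Adia[i] * q[i];
    if (i > 0) r -= h * Asub[i] * q[i - 1];
    if (i < M - 1) r -= h * Asup[i] * q[i + 1];
    rhs[i] = r;
  }
  thomas(sub, dia, sup, rhs, out);
  q = out;
}

// [[Rcpp::export(name = ".gel_velocity_cpp")]]
NumericVector gel_velocity_cpp(NumericVector theta, NumericVector n, double L,
                               double dX, List params) {
  ModelPars m = as_pars(params);
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> nn(n.begin(), n.end());
  std::vector<double> vp(th.size());
  velocity_solve(th, nn, L, dX, m, vp);
  return NumericVector(vp.begin(), vp.end());
}

struct StepResult {
  int clamped;
};

static StepResult do_step(std::vector<double>& th, std::vector<double>& n,
                          double& L, double dX, double dT, const ModelPars& m,
                          double clamp_eps, std::vector<double>& vp) {
  int M = (int)th.size();
  velocity_solve(th, n, L, dX, m, vp);
  double Ldot = vp[M - 1];

  std::vector<double> u(M);
  for (int i = 0; i < M; ++i) {
    double X = (double)i / (double)(M - 1);
    u[i] = vp[i] - X * Ldot;
  }
  u[0] = 0.0;
  u[M - 1] = 0.0;

  cn_transport(th, u, L, Ldot, dT, dX, 0.0);
  cn_transport(n, u, L, Ldot, dT, dX, m.D);
  L += dT * Ldot;
  if (L <= 0.0) stop("gel length became non-positive");

  StepResult res;
  res.clamped = 0;
  for (int i = 0; i < M; ++i) {
    if (th[i] < clamp_eps) { th[i] = clamp_eps; ++res.clamped; }
    if (th[i] > 1.0 - clamp_eps) { th[i] = 1.0 - clamp_eps; ++res.clamped; }
    if (n[i] < 0.0) n[i] = 0.0;
  }
  return res;
}

// [[Rcpp::export(name = ".gel_step_cpp")]]
List gel_step_cpp(NumericVector theta, NumericVector n, double L, double dX,
                  double dT, List params, double clamp_eps) {
  ModelPars m = as_pars(params);
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> nn(n.begin(), n.end());
  std::vector<double> vp(th.size());
  StepResult r = do_step(th, nn, L, dX, dT, m, clamp_eps, vp);
  return List::create(_["theta_p"] = NumericVector(th.begin(), th.end()),
                      _["n"] = NumericVector(nn.begin(), nn.end()),
                      _["L"] = L, _["Ldot"] = vp[th.size() - 1],
                      _["v_p"] = NumericVector(vp.begin(), vp.end()),
                      _["clamped"] = r.clamped);
}

// [[Rcpp::export(name = ".gel_simulate_cpp")]]
List gel_simulate_cpp(NumericVector theta0, NumericVector n0, double dX,
                      double dT, double t_end, List params,
                      NumericVector snapshot_times, double steady_tol,
                      int steady_consec, double clamp_eps,
                      double dissolve_theta, int series_every) {
  ModelPars m = as_pars(params);
  int M = theta0.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> nn(n0.begin(), n0.end());
  std::vector<double> vp(M);
  double L = 1.0, T = 0.0;

  long n_steps = (long)std::ceil(t_end / dT - 1e-9);
  int n_snap = snapshot_times.size();

  std::vector<double> snapT, snapL;
  std::vector<std::vector<double> > snapTh, snapN, snapV;
  std::vector<double> serT, serL, serTh0, serTh1, serN0, serN1, serMaxV;

  // initial velocity for the T=0 snapshot/series entry
  velocity_solve(th, nn, L, dX, m, vp);
  double maxv0 = 0.0;
  for (int i = 0; i < M; ++i) maxv0 = std::max(maxv0, std::fabs(vp[i]));
  snapT.push_back(0.0); snapL.push_back(L);
  snapTh.push_back(th); snapN.push_back(nn); snapV.push_back(vp);
  serT.push_back(0.0); serL.push_back(L);
  serTh0.push_back(th[0]); serTh1.push_back(th[M - 1]);
  serN0.push_back(nn[0]); serN1.push_back(nn[M - 1]); serMaxV.push_back(maxv0);

  int next_snap = 0;
  while (next_snap < n_snap && snapshot_times[next_snap] <= 1e-12) ++next_snap;

  std::string termination = "t_end";
  long total_clamped = 0;
  int steady_count = 0;
  long step_no = 0;

  for (step_no = 1; step_no <= n_steps; ++step_no) {
    StepResult r = do_step(th, nn, L, dX, dT, m, clamp_eps, vp);
    total_clamped += r.clamped;
    T = step_no * dT;

    double maxv = 0.0, maxth = 0.0;
    for (int i = 0; i < M; ++i) {
      maxv = std::max(maxv, std::fabs(vp[i]));
      maxth = std::max(maxth, th[i]);
    }

    bool want_snap = next_snap < n_snap && T >= snapshot_times[next_snap] - 1e-12;
    bool want_series = (step_no % series_every) == 0;

    if (want_series || want_snap) {
      serT.push_back(T); serL.push_back(L);
      serTh0.push_back(th[0]); serTh1.push_back(th[M - 1]);
      serN0.push_back(nn[0]); serN1.push_back(nn[M - 1]);
      serMaxV.push_back(maxv);
    }
    if (want_snap) {
      snapT.push_back(T); snapL.push_back(L);
      snapTh.push_back(th); snapN.push_back(nn); snapV.push_back(vp);
      while (next_snap < n_snap && T >= snapshot_times[next_snap] - 1e-12)
        ++next_snap;
    }

    if (maxv < steady_tol) {
      if (++steady_count >= steady_consec) { termination = "steady"; break; }
    } else steady_count = 0;

    if (maxth < dissolve_theta) { termination = "dissolved"; break; }
    if ((step_no & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // final state snapshot (always recorded)
  if (snapT.empty() || std::fabs(snapT.back() - T) > 1e-12) {
    snapT.push_back(T); snapL.push_back(L);
    snapTh.push_back(th); snapN.push_back(nn); snapV.push_back(vp);
    serT.push_back(T); serL.push_back(L);
    serTh0.push_back(th[0]); serTh1.push_back(th[M - 1]);
    serN0.push_back(nn[0]); serN1.push_back(nn[M - 1]);
    double mv = 0.0;
    for (int i = 0; i < M; ++i) mv = std::max(mv, std::fabs(vp[i]));
    serMaxV.push_back(mv);
  }

  int S = (int)snapT.size();
  NumericMatrix thMat(M, S), nMat(M, S), vMat(M, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < M; ++i) {
      thMat(i, s) = snapTh[s][i];
      nMat(i, s) = snapN[s][i];
      vMat(i, s) = snapV[s][i];
    }

  return List::create(
      _["T"] = NumericVector(snapT.begin(), snapT.end()),
      _["L"] = NumericVector(snapL.begin(), snapL.end()),
      _["theta_p"] = thMat, _["n"] = nMat, _["v_p"] = vMat,
      _["series"] = List::create(
          _["T"] = NumericVector(serT.begin(), serT.end()),
          _["L"] = NumericVector(serL.begin(), serL.end()),
          _["theta_p0"] = NumericVector(serTh0.begin(), serTh0.end()),
          _["theta_p1"] = NumericVector(serTh1.begin(), serTh1.end()),
          _["n0"] = NumericVector(serN0.begin(), serN0.end()),
          _["n1"] = NumericVector(serN1.begin(), serN1.end()),
          _["max_vp"] = NumericVector(serMaxV.begin(), serMaxV.end())),
      _["termination"] = termination, _["clamped"] = (double)total_clamped,
      _["steps"] = (double)std::min(step_no, n_steps));
}
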