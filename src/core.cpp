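// Closed-loop 0D-1D hemodynamics core.
//
// Units are fixed internally: pressure mmHg, volume ml, flow ml/s, length cm,
// time s, density g/cm^3.  The factor MMHG converts mmHg to dyn/cm^2 wherever
// pressure enters the momentum balance or the wave speed.
//
// 1D segments: finite-volume Richtmyer (two-step Lax-Wendroff) update of
// (A, Q) with a pressure-gradient source evaluated from face states, Poiseuille
// friction (semi-implicit), and a Kelvin-Voigt wall-viscosity correction
// applied as an implicit diffusion on Q (operator splitting).  Boundary and
// junction faces are closed with Riemann-invariant (characteristic) solves, so
// the discrete mass balance telescopes exactly: the volume change of a segment
// equals dt * (Q_in_face - Q_out_face).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const double MMHG = 1333.22;  // dyn/cm^2 per mmHg

// ---------------------------------------------------------------- tube law

inline double p_elastic(double A, double A0, double beta) {
  return beta / A0 * (std::sqrt(A) - std::sqrt(A0));
}
inline double dp_dA(double A, double A0, double beta) {
  return beta / (2.0 * A0 * std::sqrt(A));
}
inline double wave_c(double A, double A0, double beta, double rho) {
  return std::sqrt(MMHG * A * dp_dA(A, A0, beta) / rho);
}

// [[Rcpp::export]]
NumericVector cpp_tube_law(NumericVector A, NumericVector dA_dt,
                           NumericVector A0, NumericVector beta,
                           NumericVector gamma, double pext) {
  int n = A.size();
  NumericVector P(n);
  for (int i = 0; i < n; ++i) {
    if (A[i] <= 0) stop("tube law: non-positive area");
    P[i] = pext + p_elastic(A[i], A0[i], beta[i]) + gamma[i] * dA_dt[i];
  }
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_wave_speed(NumericVector A, NumericVector A0,
                             NumericVector beta, double rho) {
  int n = A.size();
  NumericVector c(n);
  for (int i = 0; i < n; ++i) c[i] = wave_c(A[i], A0[i], beta[i], rho);
  return c;
}

// ------------------------------------------------- characteristic closures

// Outgoing invariants W1 = u + 4c (forward), W2 = u - 4c (backward).

// Terminal impedance: find face A with u = W1 - 4 c(A) and
// A u = (P(A) + pext - P_down) / Z.  Newton with bisection safeguard.
static double solve_terminal(double W1, double A0, double beta, double pext,
                             double Z, double Pdown, double rho, double Aguess) {
  double A = Aguess > 0 ? Aguess : A0;
  for (int it = 0; it < 60; ++it) {
    double c = wave_c(A, A0, beta, rho);
    double u = W1 - 4.0 * c;
    double f = A * u - (p_elastic(A, A0, beta) + pext - Pdown) / Z;
    double df = (u - c) - dp_dA(A, A0, beta) / Z;
    double dA = f / df;
    if (!std::isfinite(dA)) break;
    double Anew = A - dA;
    if (Anew <= 0.05 * A0) Anew = 0.5 * (A + 0.05 * A0);
    if (std::fabs(Anew - A) < 1e-14 * A0) { A = Anew; return A; }
    A = Anew;
  }
  // bisection fallback on g(A) = A u - (P - Pdown)/Z
  double lo = 0.01 * A0, hi = 6.0 * A0;
  auto g = [&](double a) {
    double c = wave_c(a, A0, beta, rho);
    return a * (W1 - 4.0 * c) - (p_elastic(a, A0, beta) + pext - Pdown) / Z;
  };
  double glo = g(lo);
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi), gm = g(mid);
    if (glo * gm <= 0) hi = mid; else { lo = mid; glo = gm; }
  }
  return 0.5 * (lo + hi);
}

// Prescribed inflow at an inlet face: find A with Qin/A - 4 c(A) = W2.
static double solve_inflow(double W2, double Qin, double A0, double beta,
                           double rho, double Aguess) {
  double A = Aguess > 0 ? Aguess : A0;
  for (int it = 0; it < 60; ++it) {
    double c = wave_c(A, A0, beta, rho);
    double f = Qin / A - 4.0 * c - W2;
    double df = -Qin / (A * A) - c / A;
    double Anew = A - f / df;
    if (!std::isfinite(Anew) || Anew <= 0.05 * A0) Anew = 0.5 * (A + 0.05 * A0);
    if (std::fabs(Anew - A) < 1e-14 * A0) return Anew;
    A = Anew;
  }
  return A;
}

// Closed end: u = 0 so 4 c(A) = |W_out|.
static double area_from_c(double c, double A0, double beta, double rho) {
  // c^2 = MMHG * beta sqrt(A) / (2 rho A0)
  double s = c * c * 2.0 * rho * A0 / (MMHG * beta);  // = sqrt(A)
  return s * s;
}

// Aortic root fed through an open valve: solve the inlet area such that the
// valve law Q = xi^2 (P_lv - P_root)/Rv and the incoming characteristic
// u = W2 + 4 c(A) hold simultaneously (implicit valve-root coupling; the
// explicit staggered update is unstable when Rv is below the root
// characteristic impedance).
// Semi-implicit RL flow through the open valve:
//   Q_new = (Q_old + dt (P_lv - P_root(A)) / L) / (1 + dt R_eff / L)
// combined with the incoming characteristic u = W2 + 4 c(A).
static double solve_root_valve(double W2, double Plv, double Rv_eff, double L,
                               double Qold, double dt,
                               double A0, double beta, double pext,
                               double rho, double Aguess) {
  double a = 1.0 / (1.0 + dt * Rv_eff / L);
  double k = a * dt / L;
  double A = Aguess > 0 ? Aguess : A0;
  for (int it = 0; it < 80; ++it) {
    double c = wave_c(A, A0, beta, rho);
    double u = W2 + 4.0 * c;
    double f = A * u - a * Qold - k * (Plv - (p_elastic(A, A0, beta) + pext));
    double df = (u + c) + k * dp_dA(A, A0, beta);
    double An = A - f / df;
    if (!std::isfinite(An) || An <= 0.05 * A0) An = 0.5 * (A + 0.05 * A0);
    if (std::fabs(An - A) < 1e-14 * A0) return An;
    A = An;
  }
  return A;
}

// [[Rcpp::export]]
List cpp_solve_terminal(double W1, double A0, double beta, double pext,
                        double Z, double Pdown, double rho, double Aguess) {
  double A = solve_terminal(W1, A0, beta, pext, Z, Pdown, rho, Aguess);
  double c = wave_c(A, A0, beta, rho);
  double u = W1 - 4.0 * c;
  return List::create(_["A"] = A, _["u"] = u, _["Q"] = A * u,
                      _["P"] = pext + p_elastic(A, A0, beta));
}

// [[Rcpp::export]]
List cpp_solve_inflow(double W2, double Qin, double A0, double beta,
                      double pext, double rho, double Aguess) {
  double A = solve_inflow(W2, Qin, A0, beta, rho, Aguess);
  return List::create(_["A"] = A, _["u"] = Qin / A, _["Q"] = Qin,
                      _["P"] = pext + p_elastic(A, A0, beta));
}

// Junction: one parent outlet, nd daughter inlets.  Unknowns A_p, A_d[i].
// Equations: total-pressure continuity parent-daughter (nd) + mass (1).
// Newton with analytic Jacobian, Gaussian elimination (n <= 6).
struct JunSide { double W, A0, beta, pext, A; };

static bool solve_junction_core(JunSide& par, std::vector<JunSide>& dau,
                                double rho, double tol, int maxit,
                                double* res_mass, double* res_ptot) {
  int nd = dau.size();
  int n = nd + 1;
  std::vector<double> R(n), J(n * n), dx(n);
  for (int it = 0; it < maxit; ++it) {
    double cp = wave_c(par.A, par.A0, par.beta, rho);
    double up = par.W - 4.0 * cp;  // parent outlet: W1
    double Ptp = p_elastic(par.A, par.A0, par.beta) + par.pext +
                 0.5 * rho * up * up / MMHG;
    double dup = -cp / par.A;
    double dPtp = dp_dA(par.A, par.A0, par.beta) + rho * up * dup / MMHG;

    double mass = par.A * up;
    std::fill(J.begin(), J.end(), 0.0);
    for (int d = 0; d < nd; ++d) {
      double cd = wave_c(dau[d].A, dau[d].A0, dau[d].beta, rho);
      double ud = dau[d].W + 4.0 * cd;  // daughter inlet: W2
      double Ptd = p_elastic(dau[d].A, dau[d].A0, dau[d].beta) + dau[d].pext +
                   0.5 * rho * ud * ud / MMHG;
      double dud = cd / dau[d].A;
      double dPtd = dp_dA(dau[d].A, dau[d].A0, dau[d].beta) + rho * ud * dud / MMHG;
      mass -= dau[d].A * ud;
      R[d] = Ptp - Ptd;
      J[d * n + 0] = dPtp;
      J[d * n + (d + 1)] = -dPtd;
      J[nd * n + (d + 1)] = -(ud + cd);
    }
    R[nd] = mass;
    J[nd * n + 0] = up - cp;

    double rp_max = 0;
    for (int d = 0; d < nd; ++d) rp_max = std::max(rp_max, std::fabs(R[d]));
    // the mass residual is a difference of terms ~ A |W|: its attainable
    // floor scales with that magnitude (roundoff), still far below the
    // 1e-10 ml/s contract for physiological states
    double mass_scale = std::fabs(par.A) * std::fabs(par.W);
    for (int d = 0; d < nd; ++d)
      mass_scale += std::fabs(dau[d].A) * std::fabs(dau[d].W);
    bool conv = std::fabs(R[nd]) < std::max(tol, 1e-15 * mass_scale) &&
                rp_max < 1e-9;
    if (conv) {
      if (res_mass) *res_mass = std::fabs(R[nd]);
      if (res_ptot) { *res_ptot = 0; for (int d = 0; d < nd; ++d)
          *res_ptot = std::max(*res_ptot, std::fabs(R[d])); }
      return true;
    }
    // solve J dx = R (partial pivoting)
    std::vector<double> M(J); std::vector<double> b(R);
    std::vector<int> piv(n);
    for (int i = 0; i < n; ++i) piv[i] = i;
    for (int k = 0; k < n; ++k) {
      int p = k; double best = std::fabs(M[k * n + k]);
      for (int r = k + 1; r < n; ++r)
        if (std::fabs(M[r * n + k]) > best) { best = std::fabs(M[r * n + k]); p = r; }
      if (best < 1e-300) return false;
      if (p != k) { for (int c = 0; c < n; ++c) std::swap(M[k * n + c], M[p * n + c]);
                    std::swap(b[k], b[p]); }
      for (int r = k + 1; r < n; ++r) {
        double f = M[r * n + k] / M[k * n + k];
        for (int c = k; c < n; ++c) M[r * n + c] -= f * M[k * n + c];
        b[r] -= f * b[k];
      }
    }
    for (int k = n - 1; k >= 0; --k) {
      double s = b[k];
      for (int c = k + 1; c < n; ++c) s -= M[k * n + c] * dx[c];
      dx[k] = s / M[k * n + k];
    }
    double Anew = par.A - dx[0];
    par.A = (Anew > 0.05 * par.A0) ? Anew : 0.5 * (par.A + 0.05 * par.A0);
    for (int d = 0; d < nd; ++d) {
      Anew = dau[d].A - dx[d + 1];
      dau[d].A = (Anew > 0.05 * dau[d].A0) ? Anew : 0.5 * (dau[d].A + 0.05 * dau[d].A0);
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_solve_junction(double W1p, double A0p, double betap, double pextp,
                        NumericVector W2d, NumericVector A0d, NumericVector betad,
                        NumericVector pextd, double rho,
                        double Ap_guess, NumericVector Ad_guess) {
  JunSide par{W1p, A0p, betap, pextp, Ap_guess > 0 ? Ap_guess : A0p};
  std::vector<JunSide> dau;
  for (int d = 0; d < W2d.size(); ++d)
    dau.push_back({W2d[d], A0d[d], betad[d], pextd[d],
                   Ad_guess[d] > 0 ? Ad_guess[d] : A0d[d]});
  double rm = NA_REAL, rp = NA_REAL;
  bool ok = solve_junction_core(par, dau, rho, 1e-12, 50, &rm, &rp);
  if (!ok) stop("junction solve: Newton failed to converge in 50 iterations");
  double cp = wave_c(par.A, par.A0, par.beta, rho);
  double up = par.W - 4.0 * cp;
  NumericVector Ad(dau.size()), ud(dau.size()), Qd(dau.size());
  for (size_t d = 0; d < dau.size(); ++d) {
    double cd = wave_c(dau[d].A, dau[d].A0, dau[d].beta, rho);
    Ad[d] = dau[d].A; ud[d] = dau[d].W + 4.0 * cd; Qd[d] = Ad[d] * ud[d];
  }
  return List::create(_["A_parent"] = par.A, _["u_parent"] = up,
                      _["Q_parent"] = par.A * up, _["A_daughters"] = Ad,
                      _["u_daughters"] = ud, _["Q_daughters"] = Qd,
                      _["residual_mass"] = rm, _["residual_ptot"] = rp);
}

// ------------------------------------------------------------- 1D segment

struct Seg {
  int n;                      // cells
  double dx, kf, gamma, pext, rho;
  std::vector<double> A, Q;                 // cell states
  std::vector<double> A0c, betac;           // cell parameters
  std::vector<double> A0f, betaf;           // face parameters (n+1)
  // scratch
  std::vector<double> Ah, Qh, Ph, adv;      // face half states (n+1)
  std::vector<double> Pc, Sc;               // cell pressure, cell source

  void init_scratch() {
    Ah.assign(n + 1, 0); Qh.assign(n + 1, 0); Ph.assign(n + 1, 0);
    adv.assign(n + 1, 0); Pc.assign(n, 0); Sc.assign(n, 0);
  }

  double volume() const {
    double v = 0; for (int i = 0; i < n; ++i) v += A[i];
    return v * dx;
  }

  // Outgoing invariant at a boundary face, interpolated at the foot of the
  // characteristic that reaches the face at mid-step (distance |lambda| dt/2
  // inside the domain; nearest cell centre sits dx/2 from the face).
  double W_out(bool outlet, double dt) const {
    int i = outlet ? n - 1 : 0;
    int j = outlet ? std::max(0, n - 2) : std::min(n - 1, 1);
    double c = wave_c(A[i], A0c[i], betac[i], rho);
    double u = Q[i] / A[i];
    double lam = outlet ? (u + c) : (c - u);   // speed towards the face
    double Wi = outlet ? (u + 4.0 * c) : (u - 4.0 * c);
    double cj = wave_c(A[j], A0c[j], betac[j], rho);
    double uj = Q[j] / A[j];
    double Wj = outlet ? (uj + 4.0 * cj) : (uj - 4.0 * cj);
    double d = std::max(0.0, lam) * dt * 0.5;
    double frac = (d - 0.5 * dx) / dx;
    if (frac < 0) frac = 0;
    if (frac > 1) frac = 1;
    return Wi + frac * (Wj - Wi);
  }

  // interior faces 1..n-1 -> half states; boundary faces set by caller
  void half_states(double dt) {
    for (int i = 0; i < n; ++i) {
      if (A[i] <= 0) throw std::runtime_error("collapse");
      Pc[i] = pext + p_elastic(A[i], A0c[i], betac[i]);
    }
    for (int i = 0; i < n; ++i) {
      double dP;
      if (i == 0)            dP = (Pc[1] - Pc[0]) / dx;
      else if (i == n - 1)   dP = (Pc[n - 1] - Pc[n - 2]) / dx;
      else                   dP = (Pc[i + 1] - Pc[i - 1]) / (2.0 * dx);
      Sc[i] = -(MMHG / rho) * A[i] * dP - kf * Q[i] / A[i];
    }
    for (int f = 1; f < n; ++f) {
      int L = f - 1, R = f;
      double advL = Q[L] * Q[L] / A[L], advR = Q[R] * Q[R] / A[R];
      Ah[f] = 0.5 * (A[L] + A[R]) - 0.5 * dt / dx * (Q[R] - Q[L]);
      Qh[f] = 0.5 * (Q[L] + Q[R]) - 0.5 * dt / dx * (advR - advL)
              + 0.25 * dt * (Sc[L] + Sc[R]);
      if (Ah[f] <= 0) throw std::runtime_error("collapse");
      Ph[f] = pext + p_elastic(Ah[f], A0f[f], betaf[f]);
      adv[f] = Qh[f] * Qh[f] / Ah[f];
    }
    // sensor-scaled dissipation: upwind-type diffusive flux proportional to
    // the normalized curvature of A, active only at steep/oscillatory
    // fronts; negligible on smooth pulses (keeps second-order accuracy) and
    // conservative (pure flux modification)
    const double kappa = 8.0;
    auto curv = [&](int i) {
      if (i < 1 || i > n - 2) return 0.0;
      return std::fabs(A[i + 1] - 2.0 * A[i] + A[i - 1]) /
             (A[i + 1] + 2.0 * A[i] + A[i - 1]);
    };
    for (int f = 1; f < n; ++f) {
      int L = f - 1, R = f;
      double sen = std::max(curv(L), curv(R));
      if (sen <= 1e-8) continue;
      double cL = wave_c(A[L], A0c[L], betac[L], rho);
      double cR = wave_c(A[R], A0c[R], betac[R], rho);
      double lam = std::max(std::fabs(Q[L] / A[L]) + cL,
                            std::fabs(Q[R] / A[R]) + cR);
      double nu = kappa * sen * lam;
      Qh[f] -= nu * (A[R] - A[L]);
      adv[f] -= nu * (Q[R] - Q[L]);
    }
  }

  void set_face(int f, double Aface, double Qface) {
    Ah[f] = Aface; Qh[f] = Qface;
    Ph[f] = pext + p_elastic(Aface, A0f[f], betaf[f]);
    adv[f] = Qface * Qface / Aface;
  }

  void update(double dt) {
    for (int i = 0; i < n; ++i) {
      double Anew = A[i] - dt / dx * (Qh[i + 1] - Qh[i]);
      double Abar = 0.5 * (Ah[i] + Ah[i + 1]);
      double rhs = Q[i] - dt / dx * (adv[i + 1] - adv[i])
                   - dt * (MMHG / rho) * Abar * (Ph[i + 1] - Ph[i]) / dx;
      double Qnew = rhs / (1.0 + dt * kf / Anew);
      if (Anew <= 0 || !std::isfinite(Anew)) throw std::runtime_error("collapse");
      A[i] = Anew; Q[i] = Qnew;
    }
    if (gamma > 0) viscous_correction(dt);
  }

  // implicit (I - dt D d2/dx2) Qnew = Q, zero-gradient ends (Thomas)
  void viscous_correction(double dt) {
    std::vector<double> a(n), b(n), c(n), d(n);
    for (int i = 0; i < n; ++i) {
      double D = MMHG * A[i] * gamma / rho;
      double r = dt * D / (dx * dx);
      a[i] = -r; b[i] = 1 + 2 * r; c[i] = -r; d[i] = Q[i];
    }
    b[0] += a[0]; a[0] = 0;          // zero-gradient
    b[n - 1] += c[n - 1]; c[n - 1] = 0;
    for (int i = 1; i < n; ++i) {
      double m = a[i] / b[i - 1];
      b[i] -= m * c[i - 1]; d[i] -= m * d[i - 1];
    }
    Q[n - 1] = d[n - 1] / b[n - 1];
    for (int i = n - 2; i >= 0; --i) Q[i] = (d[i] - c[i] * Q[i + 1]) / b[i];
  }

  double max_speed() const {
    double m = 0;
    for (int i = 0; i < n; ++i) {
      double c = wave_c(A[i], A0c[i], betac[i], rho);
      m = std::max(m, std::fabs(Q[i] / A[i]) + c);
    }
    return m;
  }
};

static Seg seg_from_list(const List& s) {
  Seg g;
  g.n = as<int>(s["n"]); g.dx = as<double>(s["dx"]);
  g.kf = as<double>(s["kf"]); g.gamma = as<double>(s["gamma"]);
  g.pext = as<double>(s["pext"]); g.rho = as<double>(s["rho"]);
  g.A = as<std::vector<double>>(s["A"]);
  g.Q = as<std::vector<double>>(s["Q"]);
  g.A0c = as<std::vector<double>>(s["A0c"]);
  g.betac = as<std::vector<double>>(s["betac"]);
  g.A0f = as<std::vector<double>>(s["A0f"]);
  g.betaf = as<std::vector<double>>(s["betaf"]);
  g.init_scratch();
  return g;
}

// Standalone single-segment driver used by the solver-level operations and
// their tests.  bc codes: 0 closed, 1 prescribed Q, 2 non-reflecting,
// 3 impedance Z to fixed P_down, 4 prescribed P.
// bcval vectors are sampled per step (recycled if length 1).
// [[Rcpp::export]]
List cpp_advance_segment(List seg, int nsteps, double dt,
                         int bc_in, NumericVector bcval_in,
                         int bc_out, NumericVector bcval_out,
                         double Z_out, double Pdown_out,
                         int sample_cell, int sample_stride) {
  Seg g = seg_from_list(seg);
  std::vector<double> ts, As, Qs, Ps, vol, qin_face, qout_face;
  double t = 0;
  // non-reflecting BCs hold the incoming invariant at its initial value
  double W2_ref = g.Q[0] / g.A[0] -
                  4.0 * wave_c(g.A[0], g.A0c[0], g.betac[0], g.rho);
  double W1_ref = g.Q[g.n - 1] / g.A[g.n - 1] +
                  4.0 * wave_c(g.A[g.n - 1], g.A0c[g.n - 1], g.betac[g.n - 1], g.rho);
  auto bcv = [&](NumericVector& v, int k) {
    return v.size() == 1 ? v[0] : v[k % v.size()];
  };
  for (int k = 0; k < nsteps; ++k) {
    double ms = g.max_speed();
    if (dt > g.dx / ms * (1.0 + 1e-12))
      stop("CFL violation: dt=%g exceeds dx/(|u|+c)=%g at step %d", dt, g.dx / ms, k);
    try {
      g.half_states(dt);
      // inlet face 0
      double W2 = g.W_out(false, dt);
      double A0 = g.A0f[0], be = g.betaf[0];
      double Af, Qf;
      if (bc_in == 0) { double c = -W2 / 4.0; Af = area_from_c(c, A0, be, g.rho); Qf = 0; }
      else if (bc_in == 1) {
        double Qin = bcv(bcval_in, k);
        Af = solve_inflow(W2, Qin, A0, be, g.rho, g.A[0]); Qf = Qin;
      } else if (bc_in == 2) {
        double u = 0.5 * (W1_ref + W2), c = (W1_ref - W2) / 8.0;
        Af = area_from_c(c, A0, be, g.rho); Qf = Af * u;
      } else { // prescribed P
        double P = bcv(bcval_in, k);
        double s = std::sqrt(A0) + P * A0 / be; Af = s * s;
        double c = wave_c(Af, A0, be, g.rho);
        double u = W2 + 4.0 * c; Qf = Af * u;
      }
      g.set_face(0, Af, Qf);
      // outlet face n
      double W1 = g.W_out(true, dt);
      A0 = g.A0f[g.n]; be = g.betaf[g.n];
      if (bc_out == 0) { double c = W1 / 4.0; Af = area_from_c(c, A0, be, g.rho); Qf = 0; }
      else if (bc_out == 1) {
        double Qout = bcv(bcval_out, k);
        // outlet with prescribed Q: u - ? use W1: find A with Qout/A + 4c = W1
        double A = g.A[g.n - 1];
        for (int it = 0; it < 60; ++it) {
          double c = wave_c(A, A0, be, g.rho);
          double f = Qout / A + 4.0 * c - W1;
          double df = -Qout / (A * A) + c / A;
          double An = A - f / df;
          if (!std::isfinite(An) || An <= 0.05 * A0) An = 0.5 * (A + 0.05 * A0);
          if (std::fabs(An - A) < 1e-14 * A0) { A = An; break; }
          A = An;
        }
        Af = A; Qf = Qout;
      } else if (bc_out == 2) {
        double u = 0.5 * (W1 + W2_ref), c = (W1 - W2_ref) / 8.0;
        Af = area_from_c(c, A0, be, g.rho); Qf = Af * u;
      } else { // impedance
        Af = solve_terminal(W1, A0, be, g.pext, Z_out, Pdown_out, g.rho, g.A[g.n - 1]);
        double c = wave_c(Af, A0, be, g.rho);
        Qf = Af * (W1 - 4.0 * c);
      }
      g.set_face(g.n, Af, Qf);
      qin_face.push_back(g.Qh[0]); qout_face.push_back(g.Qh[g.n]);
      g.update(dt);
    } catch (std::runtime_error& e) {
      stop("segment collapse (A <= 0) at t=%g", t);
    }
    t += dt;
    if (k % sample_stride == 0) {
      ts.push_back(t);
      int i = sample_cell;
      As.push_back(g.A[i]); Qs.push_back(g.Q[i]);
      Ps.push_back(g.pext + p_elastic(g.A[i], g.A0c[i], g.betac[i]));
      vol.push_back(g.volume());
    }
  }
  return List::create(_["A"] = g.A, _["Q"] = g.Q,
                      _["t"] = ts, _["A_s"] = As, _["Q_s"] = Qs, _["P_s"] = Ps,
                      _["volume"] = vol,
                      _["q_in"] = qin_face, _["q_out"] = qout_face,
                      _["final_volume"] = g.volume());
}

// --------------------------------------------------------------- elastance

// Normalized activation: raised-cosine rise to 1 at peak*dur, fall to 0 at
// dur, zero elsewhere; phase and durations are fractions of RR.
inline double activation(double phase, double onset, double dur, double peak) {
  double s = phase - onset;
  s -= std::floor(s);          // wrap to [0,1)
  if (s >= dur) return 0.0;
  double x = s / dur;
  if (x <= peak) return 0.5 * (1.0 - std::cos(M_PI * x / peak));
  return 0.5 * (1.0 + std::cos(M_PI * (x - peak) / (1.0 - peak)));
}

// [[Rcpp::export]]
NumericVector cpp_activation(NumericVector phase, double onset, double dur,
                             double peak) {
  NumericVector e(phase.size());
  for (int i = 0; i < phase.size(); ++i)
    e[i] = activation(phase[i], onset, dur, peak);
  return e;
}

// ------------------------------------------------------------------ valve

struct Valve {
  double xi, omega;                 // opening in [0,1] and its rate
  double kp, kf, km, kv, Rv;
  void step(double dP, double Q, double dt) {
    double open_lever = std::cos(0.5 * M_PI * xi);
    double torque = kp * dP * open_lever + km * Q * open_lever
                    - kv * std::max(-Q, 0.0) * xi;
    omega = (omega + dt * torque) / (1.0 + dt * kf);
    xi += dt * omega;
    if (xi < 0) { xi = 0; if (omega < 0) omega = 0; }
    if (xi > 1) { xi = 1; if (omega > 0) omega = 0; }
  }
  double flow(double dP) const { return xi * xi * dP / Rv; }
};

// [[Rcpp::export]]
List cpp_valve_step(double xi, double omega, double dP, double Q, double dt,
                    double kp, double kf, double km, double kv, double Rv) {
  Valve v{xi, omega, kp, kf, km, kv, Rv};
  v.step(dP, Q, dt);
  return List::create(_["opening"] = v.xi, _["omega"] = v.omega,
                      _["flow"] = v.flow(dP));
}

// ------------------------------------------------------------ closed loop

// Node kinds: 0 compartment (V = V0 + C P), 1 heart chamber
// (P = E(t) (V - V0)), 2 fixed-pressure reservoir.
// Edge kinds: 0 resistive, 1 RL, 2 valve, 3 rectifier.
// Edge "to" == -1 denotes the 1D aortic root face (only for the aortic valve).

struct Brx {
  bool enabled;
  double setpoint, hr_base, tau_aff, S;
  double G_hr, G_e, G_r, G_v0, G_c;
  double tau_hr, tau_e, tau_r, tau_v0, tau_c;
  double p_filt, m_hr, m_e, m_r, m_v0, m_c;
  void step(double p_aff, double dt) {
    if (!enabled) return;
    p_filt += dt * (p_aff - p_filt) / tau_aff;
    double z = std::tanh((setpoint - p_filt) / S);
    m_hr += dt * ((1.0 + G_hr * z) - m_hr) / tau_hr;
    m_e  += dt * ((1.0 + G_e  * z) - m_e ) / tau_e;
    m_r  += dt * ((1.0 + G_r  * z) - m_r ) / tau_r;
    m_v0 += dt * ((1.0 - G_v0 * z) - m_v0) / tau_v0;
    m_c  += dt * ((1.0 - G_c  * z) - m_c ) / tau_c;
  }
};

// [[Rcpp::export]]
List cpp_run(List net, List ctrl) {
  // ---- parse 0D nodes
  IntegerVector node_kind = net["node_kind"];
  NumericVector node_C = net["node_C"], node_V0 = net["node_V0"];
  NumericVector node_V = clone(as<NumericVector>(net["node_V"]));
  NumericVector node_Pfix = net["node_Pfix"];
  LogicalVector node_venous = net["node_venous"];
  IntegerVector node_chamber = net["node_chamber"];  // index into chamber params, -1
  int nnode = node_kind.size();

  // chambers
  NumericVector ch_Emin = net["ch_Emin"], ch_Eamp = net["ch_Eamp"];
  NumericVector ch_onset = net["ch_onset"], ch_dur = net["ch_dur"], ch_peak = net["ch_peak"];
  LogicalVector ch_ventricle = net["ch_ventricle"];
  NumericVector ch_Rs = net["ch_Rs"];          // internal (source) resistance
  IntegerVector node_outvalve = net["node_outvalve"];  // outflow valve edge, -1

  // edges
  IntegerVector e_from = net["edge_from"], e_to = net["edge_to"], e_kind = net["edge_kind"];
  NumericVector e_R = net["edge_R"], e_L = net["edge_L"];
  NumericVector e_Q = clone(as<NumericVector>(net["edge_Q"]));
  IntegerVector e_valve = net["edge_valve"];
  LogicalVector e_peri = net["edge_peripheral"];
  int nedge = e_from.size();

  // valves
  NumericVector v_xi = clone(as<NumericVector>(net["valve_xi"]));
  NumericVector v_om = clone(as<NumericVector>(net["valve_omega"]));
  NumericVector v_kp = net["valve_kp"], v_kf = net["valve_kf"], v_km = net["valve_km"],
                v_kv = net["valve_kv"], v_Rv = net["valve_Rv"], v_L = net["valve_L"];
  int nvalve = v_xi.size();

  // 1D segments
  List segs = net["segments"];
  int nseg = segs.size();
  std::vector<Seg> S(nseg);
  for (int s = 0; s < nseg; ++s) S[s] = seg_from_list(segs[s]);

  // junctions
  IntegerVector j_parent = net["jun_parent"];
  List j_dau = net["jun_daughters"];
  int njun = j_parent.size();
  // map: which segment inlets are junction-fed
  std::vector<int> inlet_is_junction(nseg, -1);
  for (int j = 0; j < njun; ++j) {
    IntegerVector dd = j_dau[j];
    for (int k = 0; k < dd.size(); ++k) inlet_is_junction[dd[k]] = j;
  }

  // terminals
  IntegerVector t_seg = net["term_seg"], t_node = net["term_node"];
  NumericVector t_Z = net["term_Z"];
  int nterm = t_seg.size();
  std::vector<int> outlet_is_terminal(nseg, -1);
  for (int k = 0; k < nterm; ++k) outlet_is_terminal[t_seg[k]] = k;

  int root_seg = as<int>(net["root_seg"]);       // -1 if no 1D tree
  int root_mode = as<int>(net["root_mode"]);     // 0 valve-fed, 1 prescribed-Q, 2 closed
  NumericVector root_qin = net["root_qin"];      // phase-sampled inflow, mode 1
  int av_edge = as<int>(net["av_edge"]);         // edge whose "to" is the root, -1

  // baroreflex
  List bl = net["baroreflex"];
  Brx brx;
  brx.enabled = as<bool>(bl["enabled"]);
  brx.setpoint = as<double>(bl["setpoint"]); brx.hr_base = as<double>(bl["hr_baseline"]);
  brx.tau_aff = as<double>(bl["tau_afferent"]); brx.S = as<double>(bl["slope"]);
  brx.G_hr = as<double>(bl["gain_hr"]); brx.G_e = as<double>(bl["gain_e"]);
  brx.G_r = as<double>(bl["gain_r"]); brx.G_v0 = as<double>(bl["gain_v0"]);
  brx.G_c = as<double>(bl["gain_c"]);
  brx.tau_hr = as<double>(bl["tau_hr"]); brx.tau_e = as<double>(bl["tau_e"]);
  brx.tau_r = as<double>(bl["tau_r"]); brx.tau_v0 = as<double>(bl["tau_v0"]);
  brx.tau_c = as<double>(bl["tau_c"]);
  brx.p_filt = as<double>(bl["p_filt"]);
  brx.m_hr = as<double>(bl["m_hr"]); brx.m_e = as<double>(bl["m_e"]);
  brx.m_r = as<double>(bl["m_r"]); brx.m_v0 = as<double>(bl["m_v0"]);
  brx.m_c = as<double>(bl["m_c"]);
  int carotid_seg = as<int>(bl["carotid_seg"]);   // -1: use root only
  int carotid_cell = as<int>(bl["carotid_cell"]);
  double w_aortic = as<double>(bl["w_aortic"]);

  // ---- control
  double dt = as<double>(ctrl["dt"]);
  int n_beats = as<int>(ctrl["n_beats"]);
  int stride = as<int>(ctrl["sample_stride"]);
  IntegerVector rec_kind = ctrl["rec_kind"], rec_i1 = ctrl["rec_i1"], rec_i2 = ctrl["rec_i2"];
  int nrec = rec_kind.size();
  double hr_override = as<double>(ctrl["hr"]);  // <=0: use baroreflex baseline
  int n_ramp = ctrl.containsElementNamed("n_ramp_beats") ?
               as<int>(ctrl["n_ramp_beats"]) : 3;  // soft-start beats

  double hr0 = hr_override > 0 ? hr_override : brx.hr_base;
  double RR = 60.0 / (hr0 * (brx.enabled ? brx.m_hr : 1.0));

  // rough sample capacity
  int max_steps = (int)std::ceil(n_beats * 2.2 * 60.0 / hr0 / dt) + 16;
  int cap = max_steps / stride + 8;
  NumericMatrix signals(cap, nrec);
  std::vector<double> times; times.reserve(cap);

  std::vector<double> beat_start_t; beat_start_t.push_back(0.0);
  std::vector<double> beat_RR; beat_RR.push_back(RR);
  std::vector<double> beat_volume;

  NumericVector node_P(nnode);
  std::vector<double> term_Q(nterm, 0.0);
  double root_P = as<double>(net["root_P0"]);
  double root_Q = 0.0;

  // per-node net flow accumulator
  std::vector<double> dVdt(nnode, 0.0);

  auto total_volume = [&]() {
    double v = 0;
    for (int i = 0; i < nnode; ++i) if (node_kind[i] != 2) v += node_V[i];
    for (int s = 0; s < nseg; ++s) v += S[s].volume();
    return v;
  };
  beat_volume.push_back(total_volume());

  double t = 0.0, t_beat = 0.0;
  int beat = 0, step = 0, nsamp = 0;
  std::string err;

  while (beat < n_beats) {
    double phase = (t - t_beat) / RR;
    // contraction soft-start: scale activation amplitude up over the first
    // n_ramp beats so the initial systole does not launch an unphysical
    // transient; irrelevant to the steady state
    double ramp = (n_ramp > 0 && beat < n_ramp) ?
                  (beat + 1.0) / n_ramp : 1.0;
    // ---- node pressures
    for (int i = 0; i < nnode; ++i) {
      if (node_kind[i] == 0) {
        double V0 = node_V0[i], C = node_C[i];
        if (node_venous[i] && brx.enabled) { V0 *= brx.m_v0; C *= brx.m_c; }
        node_P[i] = (node_V[i] - V0) / C;
      } else if (node_kind[i] == 1) {
        int c = node_chamber[i];
        double amp = ch_Eamp[c] * ramp;
        if (ch_ventricle[c] && brx.enabled) amp *= brx.m_e;
        double E = ch_Emin[c] + amp * activation(phase, ch_onset[c], ch_dur[c], ch_peak[c]);
        node_P[i] = E * (node_V[i] - node_V0[i]);
      } else node_P[i] = node_Pfix[i];
    }

    // ---- valves and edge flows
    for (int e = 0; e < nedge; ++e) {
      double Pf = node_P[e_from[e]];
      double Pt = (e_to[e] >= 0) ? node_P[e_to[e]] : root_P;
      double dP = Pf - Pt;
      int k = e_kind[e];
      if (k == 0) {
        double R = e_R[e] * ((e_peri[e] && brx.enabled) ? brx.m_r : 1.0);
        e_Q[e] = dP / R;
      } else if (k == 1) {
        double R = e_R[e] * ((e_peri[e] && brx.enabled) ? brx.m_r : 1.0);
        e_Q[e] = (e_Q[e] + dt * dP / e_L[e]) / (1.0 + dt * R / e_L[e]);
      } else if (k == 2) {
        int v = e_valve[e];
        Valve V{v_xi[v], v_om[v], v_kp[v], v_kf[v], v_km[v], v_kv[v], v_Rv[v]};
        V.step(dP, e_Q[e], dt);
        v_xi[v] = V.xi; v_om[v] = V.omega;
        if (V.xi < 1e-6) {
          e_Q[e] = 0.0;                       // closed valve: exactly no flow
        } else if (e_to[e] >= 0) {            // inertial flow (open valve)
          double Reff = v_Rv[v] / (V.xi * V.xi);
          int cf = node_chamber[e_from[e]];
          if (cf >= 0) Reff += ch_Rs[cf];     // ventricular internal resistance
          e_Q[e] = (e_Q[e] + dt * dP / v_L[v]) / (1.0 + dt * Reff / v_L[v]);
        }                                     // aortic valve: set by root solve
      } else {
        e_Q[e] = dP > 0 ? dP / e_R[e] : 0.0;
      }
    }
    root_Q = (av_edge >= 0) ? e_Q[av_edge] : 0.0;
    if (root_mode == 1 && root_seg >= 0) {
      int m = root_qin.size();
      double x = phase * m;
      int i0 = (int)std::floor(x) % m; int i1 = (i0 + 1) % m;
      double w = x - std::floor(x);
      // prescribed inflow shares the soft-start ramp so a cold start does
      // not launch a discontinuous front
      root_Q = ((1 - w) * root_qin[i0] + w * root_qin[i1]) * ramp;
    }

    // ---- 1D step
    if (nseg > 0) {
      try {
        for (int s = 0; s < nseg; ++s) {
          double ms = S[s].max_speed();
          if (dt > S[s].dx / ms * (1.0 + 1e-12))
            throw std::runtime_error("CFL violation in segment " + std::to_string(s) +
                                     " at t=" + std::to_string(t));
          S[s].half_states(dt);
        }
        // root inlet
        if (root_seg >= 0) {
          Seg& g = S[root_seg];
          double W2 = g.W_out(false, dt);
          double Af, Qf;
          if (root_mode == 1) {               // prescribed inflow
            Af = solve_inflow(W2, root_Q, g.A0f[0], g.betaf[0], g.rho, g.A[0]);
            Qf = root_Q;
          } else if (root_mode == 0 && av_edge >= 0 &&
                     v_xi[e_valve[av_edge]] > 1e-6) {
            int v = e_valve[av_edge];
            double xi = v_xi[v];
            double Rv_eff = e_R[av_edge] / (xi * xi);
            int cf = node_chamber[e_from[av_edge]];
            if (cf >= 0) Rv_eff += ch_Rs[cf];
            double Plv = node_P[e_from[av_edge]];
            Af = solve_root_valve(W2, Plv, Rv_eff, v_L[v], e_Q[av_edge], dt,
                                  g.A0f[0], g.betaf[0], g.pext, g.rho, g.A[0]);
            double c = wave_c(Af, g.A0f[0], g.betaf[0], g.rho);
            Qf = Af * (W2 + 4.0 * c);
          } else {                            // closed end (shut valve)
            double c = -W2 / 4.0;
            Af = area_from_c(c, g.A0f[0], g.betaf[0], g.rho);
            Qf = 0.0;
          }
          g.set_face(0, Af, Qf);
          root_P = g.pext + p_elastic(Af, g.A0f[0], g.betaf[0]);
          if (root_mode == 0 && av_edge >= 0) { e_Q[av_edge] = Qf; root_Q = Qf; }
        }
        // junctions
        for (int j = 0; j < njun; ++j) {
          int ps = j_parent[j];
          IntegerVector dd = j_dau[j];
          Seg& P = S[ps];
          JunSide par{P.W_out(true, dt), P.A0f[P.n], P.betaf[P.n], P.pext,
                      P.A[P.n - 1]};
          std::vector<JunSide> dau;
          for (int k = 0; k < dd.size(); ++k) {
            Seg& D = S[dd[k]];
            dau.push_back({D.W_out(false, dt), D.A0f[0], D.betaf[0], D.pext, D.A[0]});
          }
          if (!solve_junction_core(par, dau, P.rho, 1e-12, 50, nullptr, nullptr)) {
            std::string msg = "junction " + std::to_string(j) +
                              " Newton failure at t=" + std::to_string(t) +
                              " [parent W=" + std::to_string(par.W) +
                              " A=" + std::to_string(par.A) +
                              " A0=" + std::to_string(par.A0) +
                              " beta=" + std::to_string(par.beta);
            for (size_t k2 = 0; k2 < dau.size(); ++k2)
              msg += "; d" + std::to_string(k2) + " W=" + std::to_string(dau[k2].W) +
                     " A=" + std::to_string(dau[k2].A) +
                     " A0=" + std::to_string(dau[k2].A0) +
                     " beta=" + std::to_string(dau[k2].beta);
            throw std::runtime_error(msg + "]");
          }
          double cp = wave_c(par.A, par.A0, par.beta, P.rho);
          double Qp = par.A * (par.W - 4.0 * cp);
          P.set_face(P.n, par.A, Qp);
          for (int k = 0; k < dd.size(); ++k) {
            Seg& D = S[dd[k]];
            double cd = wave_c(dau[k].A, dau[k].A0, dau[k].beta, D.rho);
            D.set_face(0, dau[k].A, dau[k].A * (dau[k].W + 4.0 * cd));
          }
        }
        // terminals
        for (int k = 0; k < nterm; ++k) {
          Seg& g = S[t_seg[k]];
          double W1 = g.W_out(true, dt);
          double Pd = node_P[t_node[k]];
          double Af = solve_terminal(W1, g.A0f[g.n], g.betaf[g.n], g.pext,
                                     t_Z[k], Pd, g.rho, g.A[g.n - 1]);
          double c = wave_c(Af, g.A0f[g.n], g.betaf[g.n], g.rho);
          double Qf = Af * (W1 - 4.0 * c);
          g.set_face(g.n, Af, Qf);
          term_Q[k] = Qf;
        }
        for (int s = 0; s < nseg; ++s) S[s].update(dt);
      } catch (std::runtime_error& ex) {
        stop("1D solver error: %s (beat %d, t=%.4f s)", ex.what(), beat + 1, t);
      }
    }

    // ---- node volume updates
    std::fill(dVdt.begin(), dVdt.end(), 0.0);
    for (int e = 0; e < nedge; ++e) {
      dVdt[e_from[e]] -= e_Q[e];
      if (e_to[e] >= 0) dVdt[e_to[e]] += e_Q[e];
    }
    for (int k = 0; k < nterm; ++k) dVdt[t_node[k]] += term_Q[k];
    for (int i = 0; i < nnode; ++i)
      if (node_kind[i] != 2) node_V[i] += dt * dVdt[i];

    // ---- baroreflex
    if (brx.enabled) {
      double p_car = root_P;
      if (carotid_seg >= 0) {
        Seg& g = S[carotid_seg];
        p_car = g.pext + p_elastic(g.A[carotid_cell], g.A0c[carotid_cell],
                                   g.betac[carotid_cell]);
      }
      double p_ao = (nseg > 0) ? root_P : node_P[0];
      brx.step(w_aortic * p_ao + (1.0 - w_aortic) * p_car, dt);
    }

    // ---- sample
    if (step % stride == 0 && nsamp < cap) {
      times.push_back(t);
      for (int r = 0; r < nrec; ++r) {
        int k = rec_kind[r], i1 = rec_i1[r], i2 = rec_i2[r];
        double val = NA_REAL;
        switch (k) {
        case 0: { Seg& g = S[i1];
          val = g.pext + p_elastic(g.A[i2], g.A0c[i2], g.betac[i2]); break; }
        case 1: val = S[i1].Q[i2]; break;
        case 2: val = S[i1].A[i2]; break;
        case 3: {
          val = node_P[i1];
          int c3 = node_chamber[i1];
          if (c3 >= 0 && node_outvalve[i1] >= 0)
            val -= ch_Rs[c3] * e_Q[node_outvalve[i1]];
          break; }
        case 4: val = node_V[i1]; break;
        case 5: val = e_Q[i1]; break;
        case 6: val = v_xi[i1]; break;
        case 7: { int c = node_chamber[i1];
          double amp = ch_Eamp[c] * ramp;
          if (ch_ventricle[c] && brx.enabled) amp *= brx.m_e;
          val = ch_Emin[c] + amp * activation(phase, ch_onset[c], ch_dur[c], ch_peak[c]);
          break; }
        case 8: val = root_P; break;
        case 9: val = brx.p_filt; break;
        case 10: val = term_Q[i1]; break;
        }
        signals(nsamp, r) = val;
      }
      ++nsamp;
    }

    t += dt; ++step;
    if (t - t_beat >= RR - 0.5 * dt) {
      t_beat += RR;
      ++beat;
      beat_volume.push_back(total_volume());
      if (beat < n_beats) {
        RR = 60.0 / (hr0 * (brx.enabled ? brx.m_hr : 1.0));
        beat_start_t.push_back(t_beat);
        beat_RR.push_back(RR);
      }
    }
  }

  // trim signals
  NumericMatrix sig(nsamp, nrec);
  for (int r = 0; r < nrec; ++r)
    for (int i = 0; i < nsamp; ++i) sig(i, r) = signals(i, r);

  // final 1D state
  List seg_state(nseg);
  for (int s = 0; s < nseg; ++s)
    seg_state[s] = List::create(_["A"] = wrap(S[s].A), _["Q"] = wrap(S[s].Q));

  return List::create(
    _["time"] = wrap(times), _["signals"] = sig,
    _["beat_start"] = wrap(beat_start_t), _["beat_RR"] = wrap(beat_RR),
    _["beat_volume"] = wrap(beat_volume),
    _["node_V"] = node_V, _["node_P"] = node_P,
    _["edge_Q"] = e_Q, _["valve_xi"] = v_xi, _["valve_omega"] = v_om,
    _["seg_state"] = seg_state, _["root_P"] = root_P,
    _["brx_state"] = NumericVector::create(
      _["p_filt"] = brx.p_filt, _["m_hr"] = brx.m_hr, _["m_e"] = brx.m_e,
      _["m_r"] = brx.m_r, _["m_v0"] = brx.m_v0, _["m_c"] = brx.m_c),
    _["dt"] = dt, _["n_steps"] = step);
}
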