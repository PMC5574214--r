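// 1D compliant-vessel blood flow on a bifurcation (parent + two daughters).
//
// Conservation form  dU/dt + dF/dz = S  with U = (A, Q),
//   F = (Q, Q^2/A + f(r0) sqrt(A0 A) / rho),
//   S = (0, -(2 pi nu R / delta_b) Q/A
//           + (1/rho) (2 sqrt(A)(sqrt(pi) f + sqrt(A0) f') - A f') dr0/dz),
// advanced with Richtmyer's two-step Lax-Wendroff scheme. Boundaries use
// characteristic compatibility (Riemann invariants W+- = u -+ 4c with
// c^2 = f sqrt(A0/A) / (2 rho)) combined with: prescribed inlet flux,
// a Newton-solved three-element Windkessel at each outlet, and a
// Newton-solved junction (flux conservation + pressure continuity).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Segment {
  int n;                    // nodes
  double dz;
  // node geometry
  std::vector<double> r0, A0, f, df, dr0dz, sA0;
  // face geometry (n-1 faces)
  std::vector<double> r0h, A0h, fh, dfh, dr0dzh, sA0h;
  // state
  std::vector<double> A, Q;
  // scratch
  std::vector<double> F1, F2, S2, Ah, Qh, F1h, F2h, S2h;
};

const double SQPI = 1.7724538509055160273;

inline double wavec(double f, double A0, double A, double rho) {
  return std::sqrt(0.5 * f * std::sqrt(A0 / A) / rho);
}

void fill_geom(Segment& s, const List& g) {
  NumericVector r0 = g["r0"], A0 = g["A0"], f = g["f"], df = g["df"],
                dr = g["dr0dz"], r0h = g["r0h"], A0h = g["A0h"],
                fh = g["fh"], dfh = g["dfh"], drh = g["dr0dzh"];
  s.n = r0.size();
  s.dz = as<double>(g["dz"]);
  s.r0.assign(r0.begin(), r0.end());
  s.A0.assign(A0.begin(), A0.end());
  s.f.assign(f.begin(), f.end());
  s.df.assign(df.begin(), df.end());
  s.dr0dz.assign(dr.begin(), dr.end());
  s.r0h.assign(r0h.begin(), r0h.end());
  s.A0h.assign(A0h.begin(), A0h.end());
  s.fh.assign(fh.begin(), fh.end());
  s.dfh.assign(dfh.begin(), dfh.end());
  s.dr0dzh.assign(drh.begin(), drh.end());
  s.sA0.resize(s.n); s.sA0h.resize(s.n - 1);
  for (int j = 0; j < s.n; ++j) s.sA0[j] = std::sqrt(s.A0[j]);
  for (int j = 0; j < s.n - 1; ++j) s.sA0h[j] = std::sqrt(s.A0h[j]);
  s.A = s.A0;
  s.Q.assign(s.n, 0.0);
  s.F1.resize(s.n); s.F2.resize(s.n); s.S2.resize(s.n);
  s.Ah.resize(s.n - 1); s.Qh.resize(s.n - 1);
  s.F1h.resize(s.n - 1); s.F2h.resize(s.n - 1); s.S2h.resize(s.n - 1);
}

inline void flux_source(double A, double Q, double f, double sA0, double df,
                        double dr0dz, double rho, double fric_coef,
                        double& F2, double& S2) {
  double sA = std::sqrt(A);
  F2 = Q * Q / A + f * sA0 * sA / rho;
  double R = sA / SQPI;
  S2 = -fric_coef * R * Q / A +
       (2.0 * sA * (SQPI * f + sA0 * df) - A * df) * dr0dz / rho;
}

// one Richtmyer interior update; boundary nodes left untouched
void interior_step(Segment& s, double dt, double rho, double fric_coef,
                   std::vector<double>& Anew, std::vector<double>& Qnew) {
  const int n = s.n;
  const double dz = s.dz;
  for (int j = 0; j < n; ++j) {
    s.F1[j] = s.Q[j];
    flux_source(s.A[j], s.Q[j], s.f[j], s.sA0[j], s.df[j], s.dr0dz[j],
                rho, fric_coef, s.F2[j], s.S2[j]);
  }
  for (int j = 0; j < n - 1; ++j) {
    s.Ah[j] = 0.5 * (s.A[j] + s.A[j + 1]) -
              0.5 * dt / dz * (s.F1[j + 1] - s.F1[j]);
    s.Qh[j] = 0.5 * (s.Q[j] + s.Q[j + 1]) -
              0.5 * dt / dz * (s.F2[j + 1] - s.F2[j]) +
              0.25 * dt * (s.S2[j] + s.S2[j + 1]);
    s.F1h[j] = s.Qh[j];
    flux_source(s.Ah[j], s.Qh[j], s.fh[j], s.sA0h[j], s.dfh[j],
                s.dr0dzh[j], rho, fric_coef, s.F2h[j], s.S2h[j]);
  }
  Anew = s.A; Qnew = s.Q;
  for (int j = 1; j < n - 1; ++j) {
    Anew[j] = s.A[j] - dt / dz * (s.F1h[j] - s.F1h[j - 1]);
    Qnew[j] = s.Q[j] - dt / dz * (s.F2h[j] - s.F2h[j - 1]) +
              0.5 * dt * (s.S2h[j] + s.S2h[j - 1]);
  }
}

// Riemann invariants from old state, interpolated at the characteristic foot
// distance x from the boundary node towards the interior.
inline double interp(double y0, double y1, double w) {
  return y0 + w * (y1 - y0);
}

// Source terms of the characteristic equations. In a tapered vessel the
// quasi-invariants W-+ = u +- 4c are not constant along dx/dt = u +- c:
//   d(W-)/dt = g + 4 c_z (u - c),  d(W+)/dt = g - 4 c_z (u + c),
// with g = (S2 - dB/dz|_A)/A (friction plus the non-balanced part of the
// geometric source) and c_z = dc/dz|_A. Omitting these terms forces a
// spurious flux through strongly tapered boundary nodes.
inline double char_g(const Segment& s, int j, double rho, double fric_coef) {
  double A = s.A[j], u = s.Q[j] / s.A[j];
  double sA = std::sqrt(A);
  double R = sA / SQPI;
  double geo = (sA * (s.sA0[j] * s.df[j] + SQPI * s.f[j]) - A * s.df[j]) *
               s.dr0dz[j] / (rho * A);
  return -fric_coef * R * u / A + geo;
}

inline double char_cz(const Segment& s, int j, double rho, double c) {
  double sc = (s.df[j] * s.sA0[j] + s.f[j] * SQPI) * s.dr0dz[j];
  return sc / (4.0 * rho * std::sqrt(s.A[j]) * c);
}

double foot_Wminus_inlet(const Segment& s, double dt, double rho,
                         double fric_coef) {
  // backward characteristic (u - c < 0) reaching node 0 from inside
  double c0 = wavec(s.f[0], s.A0[0], s.A[0], rho);
  double u0 = s.Q[0] / s.A[0];
  double x = (c0 - u0) * dt;                      // foot position in [0, dz]
  double w = std::min(std::max(x / s.dz, 0.0), 1.0);
  double u1 = s.Q[1] / s.A[1];
  double c1 = wavec(s.f[1], s.A0[1], s.A[1], rho);
  double W = interp(u0 + 4.0 * c0, u1 + 4.0 * c1, w);
  return W + dt * (char_g(s, 0, rho, fric_coef) +
                   4.0 * char_cz(s, 0, rho, c0) * (u0 - c0));
}

double foot_Wplus_end(const Segment& s, double dt, double rho,
                      double fric_coef) {
  // forward characteristic (u + c > 0) reaching last node from inside
  int J = s.n - 1;
  double cJ = wavec(s.f[J], s.A0[J], s.A[J], rho);
  double uJ = s.Q[J] / s.A[J];
  double x = (uJ + cJ) * dt;
  double w = std::min(std::max(x / s.dz, 0.0), 1.0);
  double u1 = s.Q[J - 1] / s.A[J - 1];
  double c1 = wavec(s.f[J - 1], s.A0[J - 1], s.A[J - 1], rho);
  double W = interp(uJ - 4.0 * cJ, u1 - 4.0 * c1, w);
  return W + dt * (char_g(s, J, rho, fric_coef) -
                   4.0 * char_cz(s, J, rho, cJ) * (uJ + cJ));
}

// inlet: prescribed Q, solve A from W- compatibility
double solve_inlet_area(const Segment& s, double Qin, double Wm, double rho) {
  double A = s.A[0];
  for (int it = 0; it < 50; ++it) {
    double c = wavec(s.f[0], s.A0[0], A, rho);
    double g = Qin / A + 4.0 * c - Wm;
    double dg = -Qin / (A * A) - c / A;
    double dA = -g / dg;
    if (A + dA <= 0) dA = -0.5 * A;
    A += dA;
    if (std::fabs(dA) < 1e-14 * A) break;
  }
  return A;
}

struct WK { double R1, R2, CT; double pc; };

// outlet: W+ compatibility + backward-Euler Windkessel
void solve_outlet(Segment& s, WK& wk, double dt, double rho, double Wp) {
  int J = s.n - 1;
  double A = s.A[J], u = s.Q[J] / s.A[J];
  double beta = 1.0 / (1.0 + dt / (wk.R2 * wk.CT));
  double rq = wk.R1 + beta * dt / wk.CT;  // d p_wk / d Q
  for (int it = 0; it < 60; ++it) {
    double c = wavec(s.f[J], s.A0[J], A, rho);
    double p = s.f[J] * (1.0 - std::sqrt(s.A0[J] / A));
    double dpdA = 0.5 * s.f[J] * s.sA0[J] / (A * std::sqrt(A));
    double G1 = u - 4.0 * c - Wp;
    double G2 = p - rq * A * u - beta * wk.pc;
    // Jacobian
    double a11 = c / A, a12 = 1.0;
    double a21 = dpdA - rq * u, a22 = -rq * A;
    double det = a11 * a22 - a12 * a21;
    double dA = (-G1 * a22 + G2 * a12) / det;
    double du = (-a11 * G2 + a21 * G1) / det;
    if (A + dA <= 0) dA = -0.5 * A;
    A += dA; u += du;
    if (std::fabs(dA) < 1e-14 * A && std::fabs(du) < 1e-12 * (1 + std::fabs(u)))
      break;
  }
  wk.pc = beta * (wk.pc + dt / wk.CT * A * u);
  s.A[J] = A; s.Q[J] = A * u;
}

// 6x6 linear solve with partial pivoting (in place)
bool solve6(double M[6][7]) {
  for (int k = 0; k < 6; ++k) {
    int piv = k;
    for (int i = k + 1; i < 6; ++i)
      if (std::fabs(M[i][k]) > std::fabs(M[piv][k])) piv = i;
    if (std::fabs(M[piv][k]) < 1e-300) return false;
    if (piv != k) for (int j = k; j < 7; ++j) std::swap(M[k][j], M[piv][j]);
    for (int i = k + 1; i < 6; ++i) {
      double m = M[i][k] / M[k][k];
      for (int j = k; j < 7; ++j) M[i][j] -= m * M[k][j];
    }
  }
  for (int k = 5; k >= 0; --k) {
    for (int j = k + 1; j < 6; ++j) M[k][6] -= M[k][j] * M[j][6];
    M[k][6] /= M[k][k];
  }
  return true;
}

// junction: parent end node + both daughter start nodes.
// x holds (Ap, up, A1, u1, A2, u2): initial guess in, solution out.
void solve_junction(double WpF, double Wm1, double Wm2,
                    double fp, double f1, double f2,
                    double A0p, double A01, double A02,
                    double rho, double x[6],
                    double& res_q, double& res_p) {
  for (int it = 0; it < 60; ++it) {
    double cp = wavec(fp, A0p, x[0], rho);
    double c1 = wavec(f1, A01, x[2], rho);
    double c2 = wavec(f2, A02, x[4], rho);
    double pp = fp * (1.0 - std::sqrt(A0p / x[0]));
    double p1 = f1 * (1.0 - std::sqrt(A01 / x[2]));
    double p2 = f2 * (1.0 - std::sqrt(A02 / x[4]));
    double dpp = 0.5 * fp * std::sqrt(A0p) / (x[0] * std::sqrt(x[0]));
    double dp1 = 0.5 * f1 * std::sqrt(A01) / (x[2] * std::sqrt(x[2]));
    double dp2 = 0.5 * f2 * std::sqrt(A02) / (x[4] * std::sqrt(x[4]));
    double r[6] = {
      x[1] - 4.0 * cp - WpF,
      x[3] + 4.0 * c1 - Wm1,
      x[5] + 4.0 * c2 - Wm2,
      x[0] * x[1] - x[2] * x[3] - x[4] * x[5],
      pp - p1,
      pp - p2
    };
    double M[6][7] = {};
    M[0][0] = cp / x[0];  M[0][1] = 1.0;
    M[1][2] = -c1 / x[2]; M[1][3] = 1.0;
    M[2][4] = -c2 / x[4]; M[2][5] = 1.0;
    M[3][0] = x[1]; M[3][1] = x[0];
    M[3][2] = -x[3]; M[3][3] = -x[2];
    M[3][4] = -x[5]; M[3][5] = -x[4];
    M[4][0] = dpp; M[4][2] = -dp1;
    M[5][0] = dpp; M[5][4] = -dp2;
    double nrm = 0.0;
    for (int i = 0; i < 6; ++i) { M[i][6] = -r[i]; nrm += r[i] * r[i]; }
    if (std::sqrt(nrm) < 1e-12 * (1.0 + std::fabs(x[0] * x[1]))) break;
    if (!solve6(M)) break;
    double relax = 1.0;
    for (int i = 0; i < 3; ++i)
      if (x[2 * i] + M[2 * i][6] <= 0) relax = std::min(relax, 0.4);
    for (int i = 0; i < 6; ++i) x[i] += relax * M[i][6];
  }
  double rq = std::fabs(x[0] * x[1] - x[2] * x[3] - x[4] * x[5]);
  double pp = fp * (1.0 - std::sqrt(A0p / x[0]));
  double p1 = f1 * (1.0 - std::sqrt(A01 / x[2]));
  double p2 = f2 * (1.0 - std::sqrt(A02 / x[4]));
  double rp = std::max(std::fabs(pp - p1), std::fabs(pp - p2));
  bool finite = true;
  for (int i = 0; i < 6; ++i) if (!std::isfinite(x[i])) finite = false;
  double scale = 1.0 + std::fabs(x[0] * x[1]);
  if (!finite || !(rq < 1e-8 * scale)) {
    Rcpp::stop("junction solve did not converge (flux residual %g, "
               "pressure residual %g)", rq, rp);
  }
  if (rq > res_q) res_q = rq;
  if (rp > res_p) res_p = rp;
}

double max_cfl(const Segment& s, double dt, double rho) {
  double m = 0.0;
  for (int j = 0; j < s.n; ++j) {
    double u = std::fabs(s.Q[j] / s.A[j]);
    double c = wavec(s.f[j], s.A0[j], s.A[j], rho);
    double v = (u + c) * dt / s.dz;
    if (v > m) m = v;
  }
  return m;
}

} // namespace

// [[Rcpp::export(name = ".solve_bifurcation")]]
List solve_bifurcation(List geom_p, List geom_d1, List geom_d2,
                       NumericVector inlet_q, double period,
                       double rho, double nu, double delta_b,
                       double R1, double R2, double CT,
                       double dt, int n_steps, int store_every,
                       double q0) {
  Segment p, d1, d2;
  fill_geom(p, geom_p); fill_geom(d1, geom_d1); fill_geom(d2, geom_d2);
  // warm start: uniform flux, capacitors at their steady charge
  for (int j = 0; j < p.n; ++j) p.Q[j] = q0;
  for (int j = 0; j < d1.n; ++j) d1.Q[j] = q0 / 2.0;
  for (int j = 0; j < d2.n; ++j) d2.Q[j] = q0 / 2.0;
  WK wk1 = { R1, R2, CT, R2 * q0 / 2.0 };
  WK wk2 = { R1, R2, CT, R2 * q0 / 2.0 };
  const double fric_coef = 2.0 * M_PI * nu / delta_b;

  const int m = inlet_q.size();
  auto Qin = [&](double t) {
    double frac = t / period;
    frac -= std::floor(frac);               // wrap to [0, 1)
    double tau = frac * m;
    int i = (int)std::floor(tau);
    double w = tau - i;
    int i2 = (i + 1) % m;
    return inlet_q[i % m] * (1.0 - w) + inlet_q[i2] * w;
  };

  int n_store = n_steps / store_every + 1;
  NumericMatrix Ap(p.n, n_store), Qp(p.n, n_store),
                Ad1(d1.n, n_store), Qd1(d1.n, n_store),
                Ad2(d2.n, n_store), Qd2(d2.n, n_store);
  NumericVector t_store(n_store);
  auto store = [&](int col, double t) {
    for (int j = 0; j < p.n; ++j) { Ap(j, col) = p.A[j]; Qp(j, col) = p.Q[j]; }
    for (int j = 0; j < d1.n; ++j) { Ad1(j, col) = d1.A[j]; Qd1(j, col) = d1.Q[j]; }
    for (int j = 0; j < d2.n; ++j) { Ad2(j, col) = d2.A[j]; Qd2(j, col) = d2.Q[j]; }
    t_store[col] = t;
  };
  store(0, 0.0);

  std::vector<double> Anp, Qnp, An1, Qn1, An2, Qn2;
  double cfl_max = 0.0, res_q = 0.0, res_p = 0.0;
  int col = 1;
  for (int step = 1; step <= n_steps; ++step) {
    double t_new = step * dt;
    // characteristic feet use the old state
    double Wm_in = foot_Wminus_inlet(p, dt, rho, fric_coef);
    double Wp_d1 = foot_Wplus_end(d1, dt, rho, fric_coef);
    double Wp_d2 = foot_Wplus_end(d2, dt, rho, fric_coef);
    double WpF = foot_Wplus_end(p, dt, rho, fric_coef);
    double Wm1 = foot_Wminus_inlet(d1, dt, rho, fric_coef);
    double Wm2 = foot_Wminus_inlet(d2, dt, rho, fric_coef);
    int J = p.n - 1;
    double xj[6] = { p.A[J], p.Q[J] / p.A[J],
                     d1.A[0], d1.Q[0] / d1.A[0],
                     d2.A[0], d2.Q[0] / d2.A[0] };

    interior_step(p, dt, rho, fric_coef, Anp, Qnp);
    interior_step(d1, dt, rho, fric_coef, An1, Qn1);
    interior_step(d2, dt, rho, fric_coef, An2, Qn2);

    solve_junction(WpF, Wm1, Wm2, p.f[J], d1.f[0], d2.f[0],
                   p.A0[J], d1.A0[0], d2.A0[0], rho, xj, res_q, res_p);

    Segment* segs[3] = { &p, &d1, &d2 };
    std::vector<double>* As[3] = { &Anp, &An1, &An2 };
    std::vector<double>* Qs[3] = { &Qnp, &Qn1, &Qn2 };
    for (int s = 0; s < 3; ++s) { segs[s]->A = *As[s]; segs[s]->Q = *Qs[s]; }
    p.A[J] = xj[0]; p.Q[J] = xj[0] * xj[1];
    d1.A[0] = xj[2]; d1.Q[0] = xj[2] * xj[3];
    d2.A[0] = xj[4]; d2.Q[0] = xj[4] * xj[5];
    // inlet
    double qin = Qin(t_new);
    double Ain = solve_inlet_area(p, qin, Wm_in, rho);
    p.A[0] = Ain; p.Q[0] = qin;
    // outlets
    solve_outlet(d1, wk1, dt, rho, Wp_d1);
    solve_outlet(d2, wk2, dt, rho, Wp_d2);

    if (step % 50 == 0 || step == n_steps) {
      double c = std::max({ max_cfl(p, dt, rho), max_cfl(d1, dt, rho),
                            max_cfl(d2, dt, rho) });
      if (c > cfl_max) cfl_max = c;
      if (c > 1.0)
        stop("CFL condition violated at t = %g s (CFL = %g); reduce dt",
             t_new, c);
      for (int s = 0; s < 3; ++s)
        for (int j = 0; j < segs[s]->n; ++j)
          if (!std::isfinite(segs[s]->A[j]) || segs[s]->A[j] <= 0.0)
            stop("solver divergence: non-positive or non-finite area at t = %g s",
                 t_new);
    }
    if (step % store_every == 0) { store(col, t_new); ++col; }
  }

  return List::create(
    _["t"] = t_store,
    _["mca"] = List::create(_["A"] = Ap, _["Q"] = Qp),
    _["d1"] = List::create(_["A"] = Ad1, _["Q"] = Qd1),
    _["d2"] = List::create(_["A"] = Ad2, _["Q"] = Qd2),
    _["diagnostics"] = List::create(
      _["cfl_max"] = cfl_max,
      _["junction_residual_flux"] = res_q,
      _["junction_residual_pressure"] = res_p)
  );
}

// Standalone junction solve for contract tests: given the three incoming
// quasi-invariants and the wall laws of the adjoining nodes, return the
// coupled boundary states and the conservation/continuity residuals.
// [[Rcpp::export(name = ".junction_solve")]]
List junction_solve_r(double WpF, double Wm1, double Wm2,
                      double fp, double f1, double f2,
                      double A0p, double A01, double A02,
                      double rho, NumericVector guess) {
  double x[6];
  for (int i = 0; i < 6; ++i) x[i] = guess[i];
  double res_q = 0.0, res_p = 0.0;
  solve_junction(WpF, Wm1, Wm2, fp, f1, f2, A0p, A01, A02, rho, x,
                 res_q, res_p);
  return List::create(
    _["A"] = NumericVector::create(x[0], x[2], x[4]),
    _["u"] = NumericVector::create(x[1], x[3], x[5]),
    _["Q"] = NumericVector::create(x[0] * x[1], x[2] * x[3], x[4] * x[5]),
    _["residual_flux"] = res_q,
    _["residual_pressure"] = res_p);
}
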