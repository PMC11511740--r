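// Explicit MUSCL finite-volume solver for 1D blood flow in an elastic
// vessel network, coupled to lumped R-C-R outlet models.
//
// Per vessel the scheme integrates
//   dA/dt + dQ/dz = 0
//   dQ/dt + d(alpha Q^2/A + b A^{3/2}/(3 rho))/dz = S_geom + S_fric
// with the tube law P(A) = Pext + beta (sqrt(A/A0) - 1), b = beta/sqrt(A0).
// Reconstruction is performed on the dimensionless distension eta = A/A0
// evaluated with exact face geometry, which keeps the rest state
// (A = A0, Q = 0) an exact discrete steady state under axial taper.
// Junctions enforce mass conservation, continuity of total pressure and
// invariance of the outgoing characteristic via Newton iteration.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <string>
#include <cmath>
#include <cstring>

using namespace Rcpp;

namespace {

struct Vessel {
  int n;              // cells
  double dx;
  int off;            // global cell offset
  int foff;           // global face offset (n+1 faces)
};

struct Outlet {
  int vessel;         // index into vessels (distal end)
  double R1, R2, C, Pout;
  double Pc;          // stored windkessel pressure
  double Astar;       // warm start
  bool resistive;     // pure resistor (R2 or C not positive)
};

struct Junction {
  // single parent (distal end) feeding k children (proximal ends)
  int parent;
  std::vector<int> children;
  std::vector<double> Astar;  // warm starts, parent first
};

inline double minmod(double a, double b) {
  if (a > 0 && b > 0) return a < b ? a : b;
  if (a < 0 && b < 0) return a > b ? a : b;
  return 0.0;
}

// dense Gaussian elimination with partial pivoting, n <= 8
inline bool solve_dense(int n, double *J, double *r) {
  int piv[8];
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int c = 0; c < n; ++c) {
    int best = c;
    double bv = std::fabs(J[piv[c] * n + c]);
    for (int r2 = c + 1; r2 < n; ++r2) {
      double v = std::fabs(J[piv[r2] * n + c]);
      if (v > bv) { bv = v; best = r2; }
    }
    if (bv == 0.0) return false;
    std::swap(piv[c], piv[best]);
    double d = J[piv[c] * n + c];
    for (int r2 = c + 1; r2 < n; ++r2) {
      double f = J[piv[r2] * n + c] / d;
      if (f == 0.0) continue;
      for (int c2 = c; c2 < n; ++c2) J[piv[r2] * n + c2] -= f * J[piv[c] * n + c2];
      r[piv[r2]] -= f * r[piv[c]];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double s = r[piv[c]];
    for (int c2 = c + 1; c2 < n; ++c2) s -= J[piv[c] * n + c2] * r[piv[c2]];
    r[piv[c]] = s / J[piv[c] * n + c];
  }
  // unpermute solution into the first n slots of r (row order == unknown order)
  double tmp[8];
  for (int i = 0; i < n; ++i) tmp[i] = r[piv[i]];
  // After the loop above r[piv[c]] holds x_c, so reorder:
  for (int i = 0; i < n; ++i) r[i] = tmp[i];
  return true;
}

class Solver {
public:
  int nv;
  std::vector<Vessel> ves;
  std::vector<std::string> vname;
  int ncell, nface;
  // state
  std::vector<double> A, Q;
  // geometry per cell / face
  std::vector<double> A0c, betac, dxinv;
  std::vector<double> A0f, betaf, bf, kf;   // face ref area, beta, b, c-coef
  std::vector<double> Grest, D2c;           // geometric source coefficients
  // scratch
  std::vector<double> sEta, sQ, F1, F2, eta;
  // boundary fluxes per vessel end: [vessel][0]=proximal, [1]=distal
  std::vector<double> bF1p, bF2p, bF1d, bF2d;
  double rho, mu, alpha, fcoef, pext;
  double cfl;
  std::vector<Outlet> outlets;
  std::vector<Junction> juncs;
  int inlet_vessel;
  double inlet_Astar;
  // inlet waveform
  std::vector<double> inQ;
  double period;
  double tnow = 0.0;

  double cA(double k, double a) const { return k * std::sqrt(std::sqrt(a)); }

  // --- boundary helpers -------------------------------------------------
  // proximal end state of vessel v (first cell), with face geometry
  inline void end_state(const Vessel &V, bool distal, double &Ae, double &ue,
                        double &k, double &beta, double &A0) const {
    int c = distal ? V.off + V.n - 1 : V.off;
    int f = distal ? V.foff + V.n : V.foff;
    double et = A[c] / A0c[c];
    A0 = A0f[f]; beta = betaf[f]; k = kf[f];
    Ae = et * A0;
    ue = Q[c] / Ae;
  }

  // inlet: impose Q(t), invariance of backward characteristic W- = u - 4c
  void solve_inlet(double Qin) {
    const Vessel &V = ves[inlet_vessel];
    double Ae, ue, k, beta, A0;
    end_state(V, false, Ae, ue, k, beta, A0);
    double Wm = ue - 4.0 * cA(k, Ae);
    double a = inlet_Astar > 0 ? inlet_Astar : Ae;
    for (int it = 0; it < 60; ++it) {
      double c = cA(k, a);
      double f = Qin / a - 4.0 * c - Wm;
      double fp = -Qin / (a * a) - c / a;
      double da = f / fp;
      double anew = a - da;
      if (anew <= 0.1 * a) anew = 0.1 * a;
      a = anew;
      if (std::fabs(da) < 1e-14 * a) break;
    }
    inlet_Astar = a;
    double u = Qin / a;
    bF1p[inlet_vessel] = Qin;
    bF2p[inlet_vessel] = alpha * Qin * u + bf[V.foff] * a * std::sqrt(a) / (3.0 * rho);
  }

  // outlet windkessel / resistor, distal end of vessel v; returns the
  // star (interface) flow.  Pc integration happens in the RK stages.
  double solve_outlet(Outlet &o) {
    const Vessel &V = ves[o.vessel];
    double Ae, ue, k, beta, A0;
    end_state(V, true, Ae, ue, k, beta, A0);
    double Wp = ue + 4.0 * cA(k, Ae);
    double Pd = o.resistive ? o.Pout : o.Pc;       // distal pressure seen by R1
    double R1 = o.resistive ? (o.R1 + o.R2) : o.R1;
    double a = o.Astar > 0 ? o.Astar : Ae;
    double b = beta / std::sqrt(A0);
    for (int it = 0; it < 60; ++it) {
      double c = cA(k, a);
      double u = Wp - 4.0 * c;
      double P = pext + beta * (std::sqrt(a / A0) - 1.0);
      double f = P - Pd - R1 * a * u;
      double fp = 0.5 * b / std::sqrt(a) - R1 * (u - c);
      double da = f / fp;
      double anew = a - da;
      if (anew <= 0.1 * a) anew = 0.1 * a;
      a = anew;
      if (std::fabs(da) < 1e-14 * a) break;
    }
    o.Astar = a;
    double u = Wp - 4.0 * cA(k, a);
    double Qs = a * u;
    int fi = V.foff + V.n;
    bF1d[o.vessel] = Qs;
    bF2d[o.vessel] = alpha * Qs * u + bf[fi] * a * std::sqrt(a) / (3.0 * rho);
    return Qs;
  }

  // junction: one parent (distal end), k children (proximal ends)
  // Newton solve of the junction system in the unknown areas x[0..k-1];
  // returns true on convergence (relative residuals < 1e-11).
  bool newton_junction(int k, const double *kk, const double *beta,
                       const double *A0, const double *W, double *x) const {
    double Qscale = 0.0, Pscale = 0.0;
    for (int i = 0; i < k; ++i) {
      Qscale += A0[i] * cA(kk[i], A0[i]);
      if (beta[i] > Pscale) Pscale = beta[i];
    }
    double J[64], r[8], u[8], c[8], P[8];
    auto worst_of = [&](const double *xx, double *rr) {
      for (int i = 0; i < k; ++i) {
        c[i] = cA(kk[i], xx[i]);
        u[i] = (i == 0) ? (W[0] - 4.0 * c[0]) : (W[i] + 4.0 * c[i]);
        P[i] = pext + beta[i] * (std::sqrt(xx[i] / A0[i]) - 1.0);
      }
      double rmass = xx[0] * u[0];
      for (int i = 1; i < k; ++i) rmass -= xx[i] * u[i];
      rr[0] = rmass;
      double pt0 = P[0] + 0.5 * rho * u[0] * u[0];
      double worst = std::fabs(rmass) / Qscale;
      for (int i = 1; i < k; ++i) {
        rr[i] = pt0 - (P[i] + 0.5 * rho * u[i] * u[i]);
        double rp = std::fabs(rr[i]) / Pscale;
        if (rp > worst) worst = rp;
      }
      return worst;
    };
    for (int it = 0; it < 100; ++it) {
      double worst = worst_of(x, r);
      if (worst < 1e-11) return true;
      std::memset(J, 0, sizeof(double) * k * k);
      for (int i = 0; i < k; ++i) {
        double dudA = (i == 0 ? -1.0 : 1.0) * c[i] / x[i];
        double dAu = u[i] + x[i] * dudA;
        J[0 * k + i] = (i == 0 ? dAu : -dAu);
        double dPdA = beta[i] / (2.0 * std::sqrt(x[i] * A0[i]));
        double dPt = dPdA + rho * u[i] * dudA;
        if (i == 0) {
          for (int q = 1; q < k; ++q) J[q * k + 0] = dPt;
        } else {
          J[i * k + i] -= dPt;
        }
      }
      if (!solve_dense(k, J, r)) return false;
      double damp = 1.0;
      for (int i = 0; i < k; ++i) {
        if (x[i] - damp * r[i] < 0.1 * x[i]) {
          damp = std::min(damp, 0.9 * x[i] / r[i]);
        }
      }
      // backtracking line search on the residual norm
      double rtry[8], xtry[8];
      for (int ls = 0; ls < 30; ++ls) {
        for (int i = 0; i < k; ++i) xtry[i] = x[i] - damp * r[i];
        double wtry = worst_of(xtry, rtry);
        if (wtry < worst || damp < 1e-6) {
          for (int i = 0; i < k; ++i) x[i] = xtry[i];
          break;
        }
        damp *= 0.5;
      }
    }
    return worst_of(x, r) < 1e-11;
  }

  void solve_junction(Junction &j) {
    int k = 1 + (int)j.children.size();
    double Ae[8], ue[8], kk[8], beta[8], A0[8], W[8];
    {
      double a, u, kc, be, a0;
      end_state(ves[j.parent], true, a, u, kc, be, a0);
      Ae[0] = a; ue[0] = u; kk[0] = kc; beta[0] = be; A0[0] = a0;
      W[0] = u + 4.0 * cA(kc, a);
    }
    for (int i = 1; i < k; ++i) {
      double a, u, kc, be, a0;
      end_state(ves[j.children[i - 1]], false, a, u, kc, be, a0);
      Ae[i] = a; ue[i] = u; kk[i] = kc; beta[i] = be; A0[i] = a0;
      W[i] = u - 4.0 * cA(kc, a);
    }
    double x[8];
    for (int i = 0; i < k; ++i) {
      x[i] = (j.Astar[i] > 0) ? j.Astar[i] : Ae[i];
    }
    if (!newton_junction(k, kk, beta, A0, W, x)) {
      for (int i = 0; i < k; ++i) x[i] = Ae[i];   // cold restart
      if (!newton_junction(k, kk, beta, A0, W, x)) {
        for (int i = 0; i < k; ++i) {
          Rprintf("member %d: Ae=%g ue=%g A0=%g beta=%g W=%g x=%g\n",
                  i, Ae[i], ue[i], A0[i], beta[i], W[i], x[i]);
        }
        stop("junction at vessel '%s': Newton iteration failed to reach residual tolerance (t = %g s)",
             vname[j.parent].c_str(), tnow);
      }
    }
    for (int i = 0; i < k; ++i) j.Astar[i] = x[i];
    // fluxes
    {
      const Vessel &V = ves[j.parent];
      int fi = V.foff + V.n;
      double a = x[0];
      double uu = W[0] - 4.0 * cA(kk[0], a);
      bF1d[j.parent] = a * uu;
      bF2d[j.parent] = alpha * a * uu * uu + bf[fi] * a * std::sqrt(a) / (3.0 * rho);
    }
    for (int i = 1; i < k; ++i) {
      int v = j.children[i - 1];
      const Vessel &V = ves[v];
      double a = x[i];
      double uu = W[i] + 4.0 * cA(kk[i], a);
      bF1p[v] = a * uu;
      bF2p[v] = alpha * a * uu * uu + bf[V.foff] * a * std::sqrt(a) / (3.0 * rho);
    }
  }

  // spatial operator: boundary solves + MUSCL-HLL fluxes + sources for the
  // current state (members A, Q, outlet Pc); fills dA, dQ, dPc and records
  // the boundary star flows in bF1p/bF1d.
  void rhs(double t, std::vector<double> &dA, std::vector<double> &dQ,
           std::vector<double> &dPc) {
    tnow = t;
    solve_inlet(inlet_flow(t));
    for (auto &j : juncs) solve_junction(j);
    for (size_t i = 0; i < outlets.size(); ++i) {
      Outlet &o = outlets[i];
      double Qs = solve_outlet(o);
      dPc[i] = o.resistive ? 0.0
                           : (Qs - (o.Pc - o.Pout) / o.R2) / o.C;
    }
    for (int v = 0; v < nv; ++v) {
      const Vessel &V = ves[v];
      int n = V.n, off = V.off, foff = V.foff;
      double dxi = dxinv[v];
      for (int i = 0; i < n; ++i) eta[i] = A[off + i] / A0c[off + i];
      sEta[0] = 0.0; sQ[0] = 0.0; sEta[n - 1] = 0.0; sQ[n - 1] = 0.0;
      for (int i = 1; i < n - 1; ++i) {
        sEta[i] = minmod(eta[i] - eta[i - 1], eta[i + 1] - eta[i]);
        sQ[i] = minmod(Q[off + i] - Q[off + i - 1], Q[off + i + 1] - Q[off + i]);
      }
      F1[0] = bF1p[v]; F2[0] = bF2p[v];
      F1[n] = bF1d[v]; F2[n] = bF2d[v];
      for (int f = 1; f < n; ++f) {
        double a0 = A0f[foff + f], bfc = bf[foff + f], kfc = kf[foff + f];
        double etaL = eta[f - 1] + 0.5 * sEta[f - 1];
        double etaR = eta[f] - 0.5 * sEta[f];
        double AL = etaL * a0, AR = etaR * a0;
        double QL = Q[off + f - 1] + 0.5 * sQ[f - 1];
        double QR = Q[off + f] - 0.5 * sQ[f];
        double uL = QL / AL, uR = QR / AR;
        double cL = cA(kfc, AL), cR = cA(kfc, AR);
        double SL = std::min(uL - cL, uR - cR);
        double SR = std::max(uL + cL, uR + cR);
        double f1L = QL, f1R = QR;
        double f2L = alpha * QL * uL + bfc * AL * std::sqrt(AL) / (3.0 * rho);
        double f2R = alpha * QR * uR + bfc * AR * std::sqrt(AR) / (3.0 * rho);
        if (SL >= 0.0) { F1[f] = f1L; F2[f] = f2L; }
        else if (SR <= 0.0) { F1[f] = f1R; F2[f] = f2R; }
        else {
          double inv = 1.0 / (SR - SL);
          F1[f] = (SR * f1L - SL * f1R + SL * SR * (AR - AL)) * inv;
          F2[f] = (SR * f2L - SL * f2R + SL * SR * (QR - QL)) * inv;
        }
      }
      for (int i = 0; i < n; ++i) {
        int g = off + i;
        double et = eta[i];
        double Sgeo = (et * (Grest[g] + D2c[g]) - et * std::sqrt(et) * D2c[g]) / rho;
        double Sfric = -fcoef * Q[g] / A[g];
        dA[g] = -dxi * (F1[i + 1] - F1[i]);
        dQ[g] = -dxi * (F2[i + 1] - F2[i]) + Sgeo + Sfric;
      }
    }
  }

  // one SSP-RK2 (Heun) step; accumulates inlet/outlet volume fluxes
  std::vector<double> Asave, Qsave, Pcsave, dA1, dQ1, dA2, dQ2, dPc1, dPc2;
  double vol_in_acc = 0.0, vol_out_acc = 0.0;
  double smax_cached = -1.0;   // max (|u|+c)/dx of the last accepted state

  void report_negative(double t) const {
    for (int v = 0; v < nv; ++v) {
      const Vessel &V = ves[v];
      for (int i = 0; i < V.n; ++i) {
        if (!(A[V.off + i] > 0.0)) {
          stop("negative area in vessel '%s' at t = %g s", vname[v].c_str(), t);
        }
      }
    }
    stop("negative area at t = %g s", t);
  }

  void step(double t, double dt) {
    Asave = A; Qsave = Q;
    for (size_t i = 0; i < outlets.size(); ++i) Pcsave[i] = outlets[i].Pc;
    rhs(t, dA1, dQ1, dPc1);
    double vin1 = bF1p[inlet_vessel], vout1 = 0.0;
    for (auto &o : outlets) vout1 += bF1d[o.vessel];
    bool ok = true;
    for (int g = 0; g < ncell; ++g) {
      double An = Asave[g] + dt * dA1[g];
      ok = ok && (An > 0.0);
      A[g] = An;
      Q[g] = Qsave[g] + dt * dQ1[g];
    }
    if (!ok) report_negative(t);
    for (size_t i = 0; i < outlets.size(); ++i) {
      outlets[i].Pc = Pcsave[i] + dt * dPc1[i];
    }
    rhs(t + dt, dA2, dQ2, dPc2);
    double vin2 = bF1p[inlet_vessel], vout2 = 0.0;
    for (auto &o : outlets) vout2 += bF1d[o.vessel];
    double sm = 0.0;
    ok = true;
    for (int v = 0; v < nv; ++v) {
      const Vessel &V = ves[v];
      double dxi = dxinv[v];
      for (int i = 0; i < V.n; ++i) {
        int g = V.off + i;
        double An = Asave[g] + 0.5 * dt * (dA1[g] + dA2[g]);
        ok = ok && (An > 0.0);
        A[g] = An;
        Q[g] = Qsave[g] + 0.5 * dt * (dQ1[g] + dQ2[g]);
        double kc = 0.5 * (kf[V.foff + i] + kf[V.foff + i + 1]);
        double c = kc * std::sqrt(std::sqrt(An));
        double u = std::fabs(Q[g] / An);
        double s = (u + c) * dxi;
        if (s > sm) sm = s;
      }
    }
    smax_cached = sm;
    if (!ok) report_negative(t + dt);
    for (size_t i = 0; i < outlets.size(); ++i) {
      outlets[i].Pc = Pcsave[i] + 0.5 * dt * (dPc1[i] + dPc2[i]);
    }
    vol_in_acc += 0.5 * dt * (vin1 + vin2);
    vol_out_acc += 0.5 * dt * (vout1 + vout2);
  }

  double inlet_flow(double t) const {
    double ph = t / period;
    ph -= std::floor(ph);
    double s = ph * (double)inQ.size();
    int i = (int)s;
    double w = s - i;
    int j = (i + 1) % (int)inQ.size();
    if (i >= (int)inQ.size()) i = (int)inQ.size() - 1;
    return inQ[i] * (1.0 - w) + inQ[j] * w;
  }

  double max_signal_speed() const {
    double m = 0.0;
    for (int v = 0; v < nv; ++v) {
      const Vessel &V = ves[v];
      for (int i = 0; i < V.n; ++i) {
        int g = V.off + i;
        double kc = 0.5 * (kf[V.foff + i] + kf[V.foff + i + 1]);
        double c = kc * std::sqrt(std::sqrt(A[g]));
        double u = std::fabs(Q[g] / A[g]);
        double s = (u + c) / ves[v].dx;
        if (s > m) m = s;
      }
    }
    return m;  // in 1/s (speed over dx)
  }

  double stored_volume() const {
    double vtot = 0.0;
    for (int v = 0; v < nv; ++v) {
      const Vessel &V = ves[v];
      for (int i = 0; i < V.n; ++i) vtot += A[V.off + i] * V.dx;
    }
    return vtot;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_run_simulation")]]
List cpp_run_simulation(List net, List inlet, List blood, List numerics,
                        DataFrame probes_df) {
  Solver S;
  // vessels
  List vs = net["vessels"];
  CharacterVector ids = vs["id"];
  NumericVector len = vs["length"], rp = vs["r_prox"], rd = vs["r_dist"],
    h0 = vs["h0"], E = vs["E"], nu = vs["nu"];
  S.nv = ids.size();
  S.rho = as<double>(blood["density"]);
  S.mu = as<double>(blood["viscosity"]);
  S.alpha = as<double>(blood["coriolis_coefficient"]);
  double gv = as<double>(blood["profile_exponent"]);
  std::string ffrm = as<std::string>(numerics["friction_form"]);
  S.fcoef = (ffrm == "standard") ? 2.0 * (gv + 2.0) * M_PI * S.mu / S.rho
                                 : 2.0 * (gv + 2.0) * S.mu;
  S.pext = 0.0;
  S.cfl = as<double>(numerics["cfl_number"]);
  double dz = as<double>(numerics["target_cell_size"]);
  int minc = as<int>(numerics["min_cells_per_vessel"]);
  double tol = as<double>(numerics["convergence_tolerance"]);
  int max_cycles = as<int>(numerics["max_cycles"]);
  int spc = as<int>(numerics["samples_per_cycle"]);
  double p0 = as<double>(numerics["init_pressure"]);

  int celloff = 0, faceoff = 0;
  S.ves.resize(S.nv);
  for (int v = 0; v < S.nv; ++v) {
    S.vname.push_back(as<std::string>(ids[v]));
    int n = std::max(minc, (int)std::ceil(len[v] / dz));
    Vessel &V = S.ves[v];
    V.n = n; V.dx = len[v] / n; V.off = celloff; V.foff = faceoff;
    celloff += n; faceoff += n + 1;
  }
  S.ncell = celloff; S.nface = faceoff;
  S.A.resize(celloff); S.Q.assign(celloff, 0.0);
  S.A0c.resize(celloff); S.betac.resize(celloff);
  S.dxinv.resize(S.nv);
  S.A0f.resize(faceoff); S.betaf.resize(faceoff); S.bf.resize(faceoff);
  S.kf.resize(faceoff);
  S.Grest.resize(celloff); S.D2c.resize(celloff);
  S.bF1p.assign(S.nv, 0.0); S.bF2p.assign(S.nv, 0.0);
  S.bF1d.assign(S.nv, 0.0); S.bF2d.assign(S.nv, 0.0);
  int maxn = 0;
  for (int v = 0; v < S.nv; ++v) {
    Vessel &V = S.ves[v];
    if (V.n > maxn) maxn = V.n;
    S.dxinv[v] = 1.0 / V.dx;
    double bmod = E[v] * h0[v] / (1.0 - nu[v] * nu[v]);
    for (int f = 0; f <= V.n; ++f) {
      double z = (double)f / V.n;
      double r0 = rp[v] + (rd[v] - rp[v]) * z;
      double a0 = M_PI * r0 * r0;
      double beta = bmod / r0;
      int gf = V.foff + f;
      S.A0f[gf] = a0; S.betaf[gf] = beta;
      S.bf[gf] = beta / std::sqrt(a0);
      S.kf[gf] = std::sqrt(S.bf[gf] / (2.0 * S.rho));
    }
    for (int i = 0; i < V.n; ++i) {
      double z = (i + 0.5) / V.n;
      double r0 = rp[v] + (rd[v] - rp[v]) * z;
      double a0 = M_PI * r0 * r0;
      double beta = bmod / r0;
      int g = V.off + i;
      S.A0c[g] = a0; S.betac[g] = beta;
      int fl = V.foff + i, fr = V.foff + i + 1;
      S.Grest[g] = (S.betaf[fr] * S.A0f[fr] - S.betaf[fl] * S.A0f[fl]) /
        (3.0 * V.dx);
      S.D2c[g] = (2.0 / 3.0) * (S.bf[fr] - S.bf[fl]) / V.dx *
        a0 * std::sqrt(a0);
      // initial state at uniform transmural pressure p0
      double s = 1.0 + p0 / beta;
      S.A[g] = a0 * s * s;
    }
  }
  S.sEta.resize(maxn); S.sQ.resize(maxn);
  S.F1.resize(maxn + 1); S.F2.resize(maxn + 1);
  S.eta.resize(maxn);
  S.dA1.resize(celloff); S.dQ1.resize(celloff);
  S.dA2.resize(celloff); S.dQ2.resize(celloff);

  // topology
  std::map<std::string, int> vidx;
  for (int v = 0; v < S.nv; ++v) vidx[S.vname[v]] = v;
  CharacterVector parents = vs["parent_ids"];
  std::map<int, std::vector<int> > children;
  S.inlet_vessel = -1;
  for (int v = 0; v < S.nv; ++v) {
    std::string p = as<std::string>(parents[v]);
    if (p.empty()) { S.inlet_vessel = v; continue; }
    // split on ';' (single parent expected, take the first)
    size_t sc = p.find(';');
    std::string p1 = (sc == std::string::npos) ? p : p.substr(0, sc);
    children[vidx[p1]].push_back(v);
  }
  if (S.inlet_vessel < 0) stop("no inlet vessel (empty parent_ids) found");
  for (auto &kvp : children) {
    Junction j;
    j.parent = kvp.first;
    j.children = kvp.second;
    j.Astar.assign(1 + j.children.size(), -1.0);
    S.juncs.push_back(j);
  }
  S.inlet_Astar = -1.0;

  // outlets
  DataFrame od = as<DataFrame>(net["outlets"]);
  CharacterVector ovid = od["vessel_id"];
  NumericVector oR = od["R_total"], oC = od["C"], of1 = od["r1_frac"],
    oP = od["p_out"];
  for (int i = 0; i < ovid.size(); ++i) {
    Outlet o;
    o.vessel = vidx[as<std::string>(ovid[i])];
    const Vessel &V = S.ves[o.vessel];
    double A0e = S.A0f[V.foff + V.n];
    double c0e = S.kf[V.foff + V.n] * std::sqrt(std::sqrt(A0e));
    double Z0 = S.rho * c0e / A0e;
    double R1;
    if (NumericVector::is_na(of1[i])) {
      R1 = (Z0 < oR[i]) ? Z0 : 0.05 * oR[i];
    } else {
      R1 = of1[i] * oR[i];
    }
    o.R1 = R1; o.R2 = oR[i] - R1; o.C = oC[i]; o.Pout = oP[i];
    o.resistive = !(o.R2 > 0.0) || !(o.C > 0.0);
    o.Pc = o.resistive ? oP[i] : (p0 > 0 ? p0 : oP[i]);
    o.Astar = -1.0;
    S.outlets.push_back(o);
  }

  S.Pcsave.resize(S.outlets.size());
  S.dPc1.resize(S.outlets.size());
  S.dPc2.resize(S.outlets.size());

  // inlet waveform
  S.inQ = as<std::vector<double> >(inlet["flow_samples"]);
  S.period = as<double>(inlet["period"]);

  // probes
  CharacterVector pnames = probes_df["name"], pvid = probes_df["vessel_id"];
  NumericVector pfrac = probes_df["frac"];
  int np = pnames.size();
  std::vector<int> pcell(np);
  for (int i = 0; i < np; ++i) {
    int v = vidx[as<std::string>(pvid[i])];
    const Vessel &V = S.ves[v];
    int c = (int)std::floor(pfrac[i] * V.n);
    if (c >= V.n) c = V.n - 1;
    pcell[i] = V.off + c;
  }

  NumericMatrix P(np, spc), Qm(np, spc), Am(np, spc), Um(np, spc);
  NumericMatrix Pprev(np, spc);
  NumericVector tout(spc);
  for (int s = 0; s < spc; ++s) tout[s] = S.period * s / spc;

  double t = 0.0;
  int cycle = 0;
  bool converged = false;
  double conv_err = NA_REAL;
  double vol_in = 0.0, vol_out = 0.0, vol0 = 0.0;
  long nsteps = 0;

  while (cycle < max_cycles) {
    double tc0 = cycle * S.period;
    int samp = 0;
    S.vol_in_acc = 0.0; S.vol_out_acc = 0.0;
    vol0 = S.stored_volume();
    while (t < tc0 + S.period - 1e-12) {
      double smax = (S.smax_cached > 0) ? S.smax_cached
                                        : S.max_signal_speed();
      double dt = (smax > 0) ? 0.98 * S.cfl / smax : S.period / 1000;
      if (dt < 1e-9) {
        stop("time step collapsed (CFL limit %g s) at t = %g s", dt, t);
      }
      double tend = tc0 + S.period;
      // land exactly on sample times and on the cycle end
      double tnext = tend;
      if (samp < spc) {
        double ts = tc0 + tout[samp];
        if (ts < tnext) tnext = ts;
      }
      if (t + dt > tnext) dt = tnext - t;
      if (dt > 1e-15) {
        S.step(t, dt);
        t += dt;
        ++nsteps;
      } else {
        t = tnext;
      }
      if (samp < spc && t >= tc0 + tout[samp] - 1e-12) {
        for (int i = 0; i < np; ++i) {
          int g = pcell[i];
          double a = S.A[g];
          P(i, samp) = S.pext + S.betac[g] * (std::sqrt(a / S.A0c[g]) - 1.0);
          Qm(i, samp) = S.Q[g];
          Am(i, samp) = a;
          Um(i, samp) = S.Q[g] / a;
        }
        ++samp;
      }
    }
    ++cycle;
    if (cycle >= 2) {
      double worst = 0.0;
      for (int i = 0; i < np; ++i) {
        double mx = 0.0, dmx = 0.0;
        for (int s = 0; s < spc; ++s) {
          double ap = std::fabs(P(i, s));
          if (ap > mx) mx = ap;
          double d = std::fabs(P(i, s) - Pprev(i, s));
          if (d > dmx) dmx = d;
        }
        double e = dmx / (mx + 1e-3);
        if (e > worst) worst = e;
      }
      conv_err = worst;
      if (worst <= tol) { converged = true; break; }
    }
    Pprev = clone(P);
  }

  double vol_end = S.stored_volume();
  vol_in = S.vol_in_acc; vol_out = S.vol_out_acc;
  double mass_err = std::fabs(vol_in - vol_out - (vol_end - vol0)) /
    (std::fabs(vol_in) + 1e-300);

  List dimn = List::create(pnames, R_NilValue);
  P.attr("dimnames") = dimn; Qm.attr("dimnames") = dimn;
  Am.attr("dimnames") = dimn; Um.attr("dimnames") = dimn;
  return List::create(
    _["t"] = tout, _["P"] = P, _["Q"] = Qm, _["A"] = Am, _["u"] = Um,
    _["cycles_to_convergence"] = cycle, _["converged"] = converged,
    _["convergence_error"] = conv_err,
    _["mass_balance_error"] = mass_err,
    _["n_steps"] = (double)nsteps, _["n_cells"] = S.ncell);
}

// Standalone junction solve, exposed for verification: given end states of
// one parent and k children, returns the coupled interface states and the
// residuals of (mass, total pressure, characteristic invariance).
// [[Rcpp::export(name = ".cpp_solve_junction")]]
List cpp_solve_junction(NumericVector A_end, NumericVector u_end,
                        NumericVector beta, NumericVector A0,
                        double rho) {
  int k = A_end.size();
  if (k < 2 || k > 8) stop("junction arity must be between 2 and 8");
  Solver S;
  S.rho = rho; S.alpha = 1.0; S.pext = 0.0;
  // build a fake two-cell vessel per member so we can reuse solve_junction
  // (simpler: replicate the Newton here)
  std::vector<double> kk(k), W(k);
  for (int i = 0; i < k; ++i) {
    double b = beta[i] / std::sqrt(A0[i]);
    kk[i] = std::sqrt(b / (2.0 * rho));
    double c = kk[i] * std::sqrt(std::sqrt(A_end[i]));
    W[i] = (i == 0) ? u_end[i] + 4.0 * c : u_end[i] - 4.0 * c;
  }
  std::vector<double> x(A_end.begin(), A_end.end());
  double J[64], r[8], u[8], c[8], P[8];
  double Qscale = 0.0, Pscale = 0.0;
  for (int i = 0; i < k; ++i) {
    Qscale += A0[i] * kk[i] * std::sqrt(std::sqrt(A0[i]));
    if (beta[i] > Pscale) Pscale = beta[i];
  }
  bool ok = false;
  for (int it = 0; it < 200; ++it) {
    for (int i = 0; i < k; ++i) {
      c[i] = kk[i] * std::sqrt(std::sqrt(x[i]));
      u[i] = (i == 0) ? (W[0] - 4.0 * c[0]) : (W[i] + 4.0 * c[i]);
      P[i] = beta[i] * (std::sqrt(x[i] / A0[i]) - 1.0);
    }
    double rmass = x[0] * u[0];
    for (int i = 1; i < k; ++i) rmass -= x[i] * u[i];
    r[0] = rmass;
    double pt0 = P[0] + 0.5 * rho * u[0] * u[0];
    double worst = std::fabs(rmass) / Qscale;
    for (int i = 1; i < k; ++i) {
      r[i] = pt0 - (P[i] + 0.5 * rho * u[i] * u[i]);
      double rp = std::fabs(r[i]) / Pscale;
      if (rp > worst) worst = rp;
    }
    if (worst < 1e-12) { ok = true; break; }
    std::memset(J, 0, sizeof(double) * k * k);
    for (int i = 0; i < k; ++i) {
      double dudA = (i == 0 ? -1.0 : 1.0) * c[i] / x[i];
      double dAu = u[i] + x[i] * dudA;
      J[0 * k + i] = (i == 0 ? dAu : -dAu);
      double dPdA = beta[i] / (2.0 * std::sqrt(x[i] * A0[i]));
      double dPt = dPdA + rho * u[i] * dudA;
      if (i == 0) {
        for (int q = 1; q < k; ++q) J[q * k + 0] = dPt;
      } else {
        J[i * k + i] -= dPt;
      }
    }
    if (!solve_dense(k, J, r)) break;
    double damp = 1.0;
    for (int i = 0; i < k; ++i) {
      if (x[i] - damp * r[i] < 0.1 * x[i]) damp = std::min(damp, 0.9 * x[i] / r[i]);
    }
    for (int i = 0; i < k; ++i) x[i] -= damp * r[i];
  }
  if (!ok) stop("junction Newton iteration did not converge");
  NumericVector As(k), us(k), Qs(k), Ptot(k), resid(k);
  for (int i = 0; i < k; ++i) {
    double cc = kk[i] * std::sqrt(std::sqrt(x[i]));
    double uu = (i == 0) ? W[0] - 4.0 * cc : W[i] + 4.0 * cc;
    As[i] = x[i]; us[i] = uu; Qs[i] = x[i] * uu;
    Ptot[i] = beta[i] * (std::sqrt(x[i] / A0[i]) - 1.0) + 0.5 * rho * uu * uu;
    // characteristic invariance residual (relative)
    double Wi = (i == 0) ? uu + 4.0 * cc : uu - 4.0 * cc;
    resid[i] = std::fabs(Wi - W[i]) / (std::fabs(W[i]) + 1e-300);
  }
  double rmass = Qs[0];
  for (int i = 1; i < k; ++i) rmass -= Qs[i];
  return List::create(_["A"] = As, _["u"] = us, _["Q"] = Qs,
                      _["total_pressure"] = Ptot,
                      _["mass_residual"] = rmass,
                      _["mass_residual_rel"] = std::fabs(rmass) / Qscale,
                      _["char_residual"] = resid);
}
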