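// Energy/force kernels for the core-shell MD engine.
// Units: eV, Angstrom, e, amu, fs; Coulomb constant 14.399645 eV A / e^2.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double C_COUL = 14.399645;
static const double TWO_OVER_SQRTPI = 1.1283791670955126;

struct Cell {
  bool pbc = false, ortho = false;
  double a[3][3];    // rows = lattice vectors
  double inv[3][3];  // inverse (r_frac = r %*% inv)
  double Ld[3];      // diagonal for ortho fast path
  double invLd[3];
};

static Cell make_cell(SEXP cellS) {
  Cell c;
  if (Rf_isNull(cellS)) return c;
  NumericMatrix m(cellS);
  c.pbc = true;
  double off = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      c.a[i][j] = m(i, j);
      if (i != j) off += std::fabs(m(i, j));
    }
  c.ortho = off < 1e-12;
  for (int i = 0; i < 3; ++i) { c.Ld[i] = c.a[i][i]; c.invLd[i] = 1.0 / c.a[i][i]; }
  // inverse of 3x3
  const double (*A)[3] = c.a;
  double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
             - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
             + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  if (std::fabs(det) < 1e-12) stop("singular cell");
  double inv[3][3] = {
    { (A[1][1]*A[2][2]-A[1][2]*A[2][1]), -(A[0][1]*A[2][2]-A[0][2]*A[2][1]),  (A[0][1]*A[1][2]-A[0][2]*A[1][1]) },
    {-(A[1][0]*A[2][2]-A[1][2]*A[2][0]),  (A[0][0]*A[2][2]-A[0][2]*A[2][0]), -(A[0][0]*A[1][2]-A[0][2]*A[1][0]) },
    { (A[1][0]*A[2][1]-A[1][1]*A[2][0]), -(A[0][0]*A[2][1]-A[0][1]*A[2][0]),  (A[0][0]*A[1][1]-A[0][1]*A[1][0]) }
  };
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) c.inv[i][j] = inv[i][j] / det;
  return c;
}

static inline void min_image(const Cell& c, double* d) {
  if (!c.pbc) return;
  if (c.ortho) {
    for (int k = 0; k < 3; ++k) d[k] -= c.Ld[k] * std::nearbyint(d[k] * c.invLd[k]);
    return;
  }
  // fractional wrap then 27-image search (general triclinic)
  double f[3];
  for (int k = 0; k < 3; ++k) {
    f[k] = d[0]*c.inv[0][k] + d[1]*c.inv[1][k] + d[2]*c.inv[2][k];
    f[k] -= std::nearbyint(f[k]);
  }
  double best = 1e300, bd[3] = {0, 0, 0};
  for (int n1 = -1; n1 <= 1; ++n1)
    for (int n2 = -1; n2 <= 1; ++n2)
      for (int n3 = -1; n3 <= 1; ++n3) {
        double g0 = f[0] + n1, g1 = f[1] + n2, g2 = f[2] + n3;
        double x = g0*c.a[0][0] + g1*c.a[1][0] + g2*c.a[2][0];
        double y = g0*c.a[0][1] + g1*c.a[1][1] + g2*c.a[2][1];
        double z = g0*c.a[0][2] + g1*c.a[1][2] + g2*c.a[2][2];
        double r2 = x*x + y*y + z*z;
        if (r2 < best) { best = r2; bd[0] = x; bd[1] = y; bd[2] = z; }
      }
  d[0] = bd[0]; d[1] = bd[1]; d[2] = bd[2];
}

// [[Rcpp::export]]
NumericMatrix cpp_minimum_image(NumericMatrix d, NumericMatrix cell) {
  Cell c = make_cell(cell);
  NumericMatrix out(d.nrow(), 3);
  for (int i = 0; i < d.nrow(); ++i) {
    double v[3] = { d(i, 0), d(i, 1), d(i, 2) };
    min_image(c, v);
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}

// binary search over sorted pair keys
static inline bool pair_excluded(const std::vector<double>& keys, double key) {
  return std::binary_search(keys.begin(), keys.end(), key);
}

// Main MM energy/force evaluation. `ftab` is a precompiled interaction table
// (see compile_interactions() in R); positions are the only per-step inputs.
// [[Rcpp::export]]
List cpp_energy_forces(List ftab, NumericMatrix core_pos, NumericMatrix shell_pos) {
  const int n = as<int>(ftab["n"]);
  const int ns = as<int>(ftab["ns"]);
  const IntegerVector owner = ftab["owner"];   // 0-based
  const IntegerVector geom = ftab["geom"];     // 0-based site index per atom
  const NumericVector q = ftab["q"];           // length n+ns (MM charges)
  Cell cell = make_cell(ftab["cell"]);

  const int nsite = n + ns;
  std::vector<double> px(nsite), py(nsite), pz(nsite);
  for (int i = 0; i < n; ++i) { px[i] = core_pos(i,0); py[i] = core_pos(i,1); pz[i] = core_pos(i,2); }
  for (int k = 0; k < ns; ++k) { px[n+k] = shell_pos(k,0); py[n+k] = shell_pos(k,1); pz[n+k] = shell_pos(k,2); }
  std::vector<double> fx(nsite, 0.0), fy(nsite, 0.0), fz(nsite, 0.0);

  // site -> atom map (shell site belongs to its owner atom)
  std::vector<int> satom(nsite);
  for (int i = 0; i < n; ++i) satom[i] = i;
  for (int k = 0; k < ns; ++k) satom[n+k] = owner[k];

  const NumericVector exclv = ftab["excl_key"];
  std::vector<double> excl(exclv.begin(), exclv.end());

  double e_bond = 0, e_angle = 0, e_lj = 0, e_coul = 0, e_spring = 0;

  // ---- bonds (harmonic, evaluated at geometry sites) ----
  {
    IntegerVector bi = ftab["bond_i"], bj = ftab["bond_j"];
    NumericVector bk = ftab["bond_k"], br0 = ftab["bond_r0"];
    for (int b = 0; b < bi.size(); ++b) {
      int si = geom[bi[b]], sj = geom[bj[b]];
      double d[3] = { px[si]-px[sj], py[si]-py[sj], pz[si]-pz[sj] };
      min_image(cell, d);
      double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
      if (r <= 0) stop("zero-length bond");
      double dr = r - br0[b];
      e_bond += 0.5 * bk[b] * dr * dr;
      double dEdr = bk[b] * dr, f = -dEdr / r;
      fx[si] += f*d[0]; fy[si] += f*d[1]; fz[si] += f*d[2];
      fx[sj] -= f*d[0]; fy[sj] -= f*d[1]; fz[sj] -= f*d[2];
    }
  }

  // ---- angles (harmonic in theta, vertex = j) ----
  {
    IntegerVector ai = ftab["ang_i"], aj = ftab["ang_j"], ak = ftab["ang_k"];
    NumericVector kth = ftab["ang_kth"], th0 = ftab["ang_th0"];
    for (int a = 0; a < ai.size(); ++a) {
      int si = geom[ai[a]], sj = geom[aj[a]], sk = geom[ak[a]];
      double u[3] = { px[si]-px[sj], py[si]-py[sj], pz[si]-pz[sj] };
      double v[3] = { px[sk]-px[sj], py[sk]-py[sj], pz[sk]-pz[sj] };
      min_image(cell, u); min_image(cell, v);
      double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
      double nv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
      double ct = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (nu*nv);
      ct = std::max(-1.0, std::min(1.0, ct));
      double st = std::sqrt(1.0 - ct*ct);
      if (st < 1e-8) stop("degenerate (collinear) angle");
      double th = std::acos(ct);
      double dth = th - th0[a];
      e_angle += 0.5 * kth[a] * dth * dth;
      double dEdth = kth[a] * dth;
      double c1 = dEdth / (st * nu), c2 = dEdth / (st * nv);
      // dth/du = -(n_v - ct n_u)/(nu st), so F_i = -dE/dth dth/du
      //        = +dE/dth (n_v - ct n_u)/(nu st)
      double fi[3], fk[3];
      for (int t = 0; t < 3; ++t) {
        double nut = u[t]/nu, nvt = v[t]/nv;
        fi[t] = c1 * (nvt - ct*nut);
        fk[t] = c2 * (nut - ct*nvt);
      }
      fx[si] += fi[0]; fy[si] += fi[1]; fz[si] += fi[2];
      fx[sk] += fk[0]; fy[sk] += fk[1]; fz[sk] += fk[2];
      fx[sj] -= fi[0]+fk[0]; fy[sj] -= fi[1]+fk[1]; fz[sj] -= fi[2]+fk[2];
    }
  }

  // ---- Lennard-Jones over geometry sites (Lorentz-Berthelot) ----
  {
    NumericVector eps = ftab["lj_eps"], sig = ftab["lj_sig"];
    IntegerVector act = ftab["lj_atoms"];  // 0-based atoms with eps > 0
    double rc = as<double>(ftab["lj_cut"]);
    bool do_shift = as<int>(ftab["lj_shift"]) != 0;
    double rc2 = rc * rc;
    for (int p = 0; p < act.size(); ++p) {
      int i = act[p], si = geom[i];
      for (int qq = p + 1; qq < act.size(); ++qq) {
        int j = act[qq], sj = geom[j];
        double d[3] = { px[si]-px[sj], py[si]-py[sj], pz[si]-pz[sj] };
        min_image(cell, d);
        double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
        if (r2 > rc2) continue;
        double key = (double)std::min(i, j) * n + std::max(i, j);
        if (pair_excluded(excl, key)) continue;
        double e = std::sqrt(eps[i]*eps[j]), s = 0.5*(sig[i]+sig[j]);
        double s2 = s*s/r2, s6 = s2*s2*s2, s12 = s6*s6;
        double ePair = 4*e*(s12 - s6);
        if (do_shift) {
          double t2 = s*s/rc2, t6 = t2*t2*t2;
          ePair -= 4*e*(t6*t6 - t6);
        }
        e_lj += ePair;
        double dEdr_over_r = 4*e*(-12*s12 + 6*s6) / r2;
        double f = -dEdr_over_r;
        fx[si] += f*d[0]; fy[si] += f*d[1]; fz[si] += f*d[2];
        fx[sj] -= f*d[0]; fy[sj] -= f*d[1]; fz[sj] -= f*d[2];
      }
    }
  }

  // ---- core-shell springs ----
  {
    NumericVector kap = ftab["kappa"];
    for (int k = 0; k < ns; ++k) {
      int i = owner[k];
      double s[3] = { core_pos(i,0)-shell_pos(k,0), core_pos(i,1)-shell_pos(k,1),
                      core_pos(i,2)-shell_pos(k,2) };
      min_image(cell, s);
      double s2 = s[0]*s[0]+s[1]*s[1]+s[2]*s[2];
      e_spring += 0.5 * kap[k] * s2;
      // E = 0.5 kappa |R - r|^2: F_core = -kappa s, F_shell = +kappa s
      fx[i] -= kap[k]*s[0]; fy[i] -= kap[k]*s[1]; fz[i] -= kap[k]*s[2];
      fx[n+k] += kap[k]*s[0]; fy[n+k] += kap[k]*s[1]; fz[n+k] += kap[k]*s[2];
    }
  }

  // ---- electrostatics ----
  bool coul_on = as<int>(ftab["coul_on"]) != 0;
  if (coul_on && !cell.pbc) {
    // open system: plain pairwise Coulomb with exclusions
    for (int s1 = 0; s1 < nsite; ++s1) {
      if (q[s1] == 0.0) continue;
      for (int s2 = s1 + 1; s2 < nsite; ++s2) {
        if (q[s2] == 0.0) continue;
        int a1 = satom[s1], a2 = satom[s2];
        if (a1 == a2) continue;  // core with its own shell
        double key = (double)std::min(a1, a2) * n + std::max(a1, a2);
        if (pair_excluded(excl, key)) continue;
        double d[3] = { px[s1]-px[s2], py[s1]-py[s2], pz[s1]-pz[s2] };
        double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
        if (r2 < 1e-12) stop("coincident interacting charge sites");
        double r = std::sqrt(r2);
        double e = C_COUL * q[s1] * q[s2] / r;
        e_coul += e;
        double f = e / r2;  // -dE/dr / r
        fx[s1] += f*d[0]; fy[s1] += f*d[1]; fz[s1] += f*d[2];
        fx[s2] -= f*d[0]; fy[s2] -= f*d[1]; fz[s2] -= f*d[2];
      }
    }
  } else if (coul_on && cell.pbc) {
    const double alpha = as<double>(ftab["ew_alpha"]);
    const double rcut = as<double>(ftab["ew_rcut"]);
    const double rcut2 = rcut * rcut;
    // real space: erfc within cutoff for included pairs; subtract erf part
    // for excluded pairs (they are still present in the reciprocal sum)
    // NOTE: exclusion corrections are only applied inside the real-space
    // cutoff; compile_interactions() warns when the cutoff is small enough
    // for a topologically excluded pair to fall outside it.
    for (int s1 = 0; s1 < nsite; ++s1) {
      if (q[s1] == 0.0) continue;
      const double x1 = px[s1], y1 = py[s1], z1 = pz[s1];
      for (int s2 = s1 + 1; s2 < nsite; ++s2) {
        if (q[s2] == 0.0) continue;
        double d[3] = { x1-px[s2], y1-py[s2], z1-pz[s2] };
        min_image(cell, d);
        double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
        if (r2 > rcut2) continue;
        int a1 = satom[s1], a2 = satom[s2];
        bool exc = (a1 == a2);
        if (!exc) {
          double key = (double)std::min(a1, a2) * n + std::max(a1, a2);
          exc = pair_excluded(excl, key);
        }
        double qq = C_COUL * q[s1] * q[s2];
        if (exc) {
          // remove erf(alpha r)/r (finite limit 2 alpha/sqrt(pi) at r -> 0)
          if (r2 < 1e-16) { e_coul -= qq * alpha * TWO_OVER_SQRTPI; continue; }
          double r = std::sqrt(r2);
          double er = std::erf(alpha * r);
          e_coul -= qq * er / r;
          // d/dr[erf/r] = 2a/sqrt(pi) e^{-a2r2}/r - erf/r^2 ; F1 = +qq d/dr[..] rhat
          double dEdr = -qq * (TWO_OVER_SQRTPI*alpha*std::exp(-alpha*alpha*r2)/r - er/r2);
          double f = -dEdr / r;
          fx[s1] += f*d[0]; fy[s1] += f*d[1]; fz[s1] += f*d[2];
          fx[s2] -= f*d[0]; fy[s2] -= f*d[1]; fz[s2] -= f*d[2];
        } else {
          double r = std::sqrt(r2);
          double ec = std::erfc(alpha * r);
          e_coul += qq * ec / r;
          double f = qq * (ec / r2 + TWO_OVER_SQRTPI*alpha*std::exp(-alpha*alpha*r2)/r) / r;
          fx[s1] += f*d[0]; fy[s1] += f*d[1]; fz[s1] += f*d[2];
          fx[s2] -= f*d[0]; fy[s2] -= f*d[1]; fz[s2] -= f*d[2];
        }
      }
    }
    // reciprocal space
    NumericMatrix kvec = ftab["ew_kvec"];
    NumericVector coef = ftab["ew_coef"];   // 2 * (2 pi C / V) * exp(-k2/4a2)/k2
    IntegerMatrix kint = ftab["ew_kint"];
    IntegerVector mmax = ftab["ew_mmax"];
    const int nk = kvec.nrow();
    if (nk > 0) {
      // per-axis phase tables from fractional coordinates
      int m1 = mmax[0], m2 = mmax[1], m3 = mmax[2];
      std::vector<double> c1((m1+1)*nsite), s1v((m1+1)*nsite),
                          c2((m2+1)*nsite), s2v((m2+1)*nsite),
                          c3((m3+1)*nsite), s3v((m3+1)*nsite);
      const double twopi = 2.0 * M_PI;
      for (int s = 0; s < nsite; ++s) {
        double f1 = px[s]*cell.inv[0][0] + py[s]*cell.inv[1][0] + pz[s]*cell.inv[2][0];
        double f2 = px[s]*cell.inv[0][1] + py[s]*cell.inv[1][1] + pz[s]*cell.inv[2][1];
        double f3 = px[s]*cell.inv[0][2] + py[s]*cell.inv[1][2] + pz[s]*cell.inv[2][2];
        double cb, sb;
        cb = std::cos(twopi*f1); sb = std::sin(twopi*f1);
        c1[s] = 1; s1v[s] = 0;
        for (int m = 1; m <= m1; ++m) {
          c1[m*nsite+s] = c1[(m-1)*nsite+s]*cb - s1v[(m-1)*nsite+s]*sb;
          s1v[m*nsite+s] = s1v[(m-1)*nsite+s]*cb + c1[(m-1)*nsite+s]*sb;
        }
        cb = std::cos(twopi*f2); sb = std::sin(twopi*f2);
        c2[s] = 1; s2v[s] = 0;
        for (int m = 1; m <= m2; ++m) {
          c2[m*nsite+s] = c2[(m-1)*nsite+s]*cb - s2v[(m-1)*nsite+s]*sb;
          s2v[m*nsite+s] = s2v[(m-1)*nsite+s]*cb + c2[(m-1)*nsite+s]*sb;
        }
        cb = std::cos(twopi*f3); sb = std::sin(twopi*f3);
        c3[s] = 1; s3v[s] = 0;
        for (int m = 1; m <= m3; ++m) {
          c3[m*nsite+s] = c3[(m-1)*nsite+s]*cb - s3v[(m-1)*nsite+s]*sb;
          s3v[m*nsite+s] = s3v[(m-1)*nsite+s]*cb + c3[(m-1)*nsite+s]*sb;
        }
      }
      std::vector<double> cphi(nsite), sphi(nsite);
      for (int kk = 0; kk < nk; ++kk) {
        int i1 = kint(kk,0), i2 = kint(kk,1), i3 = kint(kk,2);
        int a2i = std::abs(i2), a3i = std::abs(i3);
        double Sre = 0, Sim = 0;
        for (int s = 0; s < nsite; ++s) {
          if (q[s] == 0.0) { cphi[s] = 1; sphi[s] = 0; continue; }
          double ca = c1[i1*nsite+s], sa = s1v[i1*nsite+s];
          double cbb = c2[a2i*nsite+s], sbb = (i2 < 0 ? -1 : 1) * s2v[a2i*nsite+s];
          double cc = c3[a3i*nsite+s], sc = (i3 < 0 ? -1 : 1) * s3v[a3i*nsite+s];
          double cab = ca*cbb - sa*sbb, sab = sa*cbb + ca*sbb;
          double cp = cab*cc - sab*sc, sp = sab*cc + cab*sc;
          cphi[s] = cp; sphi[s] = sp;
          Sre += q[s]*cp; Sim += q[s]*sp;
        }
        double w = coef[kk];
        e_coul += w * (Sre*Sre + Sim*Sim);
        double fxk = 2*w*kvec(kk,0), fyk = 2*w*kvec(kk,1), fzk = 2*w*kvec(kk,2);
        for (int s = 0; s < nsite; ++s) {
          if (q[s] == 0.0) continue;
          // Im(S* e^{i k r_s}) = Sre*sphi - Sim*cphi
          double g = q[s] * (Sre*sphi[s] - Sim*cphi[s]);
          fx[s] += fxk*g; fy[s] += fyk*g; fz[s] += fzk*g;
        }
      }
    }
    // self energy and neutralising background
    double q2 = 0, qt = 0;
    for (int s = 0; s < nsite; ++s) { q2 += q[s]*q[s]; qt += q[s]; }
    e_coul -= C_COUL * alpha / std::sqrt(M_PI) * q2;
    if (alpha > 0 && std::fabs(qt) > 1e-12) {
      double V = as<double>(ftab["ew_vol"]);
      e_coul -= C_COUL * M_PI * qt * qt / (2.0 * alpha * alpha * V);
    }
  }

  NumericMatrix f_core(n, 3), f_shell(ns, 3);
  for (int i = 0; i < n; ++i) { f_core(i,0)=fx[i]; f_core(i,1)=fy[i]; f_core(i,2)=fz[i]; }
  for (int k = 0; k < ns; ++k) { f_shell(k,0)=fx[n+k]; f_shell(k,1)=fy[n+k]; f_shell(k,2)=fz[n+k]; }

  return List::create(
    _["bond"] = e_bond, _["angle"] = e_angle, _["lj"] = e_lj,
    _["coulomb"] = e_coul, _["spring"] = e_spring,
    _["f_core"] = f_core, _["f_shell"] = f_shell);
}
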