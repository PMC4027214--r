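// Restrained molecular dynamics / simulated annealing engine.
//
// Units: Angstrom, kcal/mol, AKMA time (1 unit = 48.88821 fs), amu.
// Integrator: velocity Verlet with per-step velocity rescaling to the
// stage temperature.  Restraint force constants ramp linearly within a
// stage.  Distance restraints act between (pseudo-)atom group centroids
// with a skewed bi-harmonic well centred on the target distance.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0019872041;   // kcal/mol/K
static const double AKMA_FS = 48.88821;  // fs per AKMA time unit
static const double COULOMB = 332.0716;  // kcal A / (mol e^2)

struct System {
  int n;
  std::vector<int> b1, b2; std::vector<double> br0, bk;
  std::vector<int> t1, t2; std::vector<double> tlo, thi, tk;
  std::vector<int> a1, a2, a3; std::vector<double> at0, ak;
  std::vector<int> d1, d2, d3, d4; std::vector<double> dp0, dk;
  std::vector<double> radii, q, mass;
  double k_rep, rep_scale, coul_cut;
  std::unordered_set<long long> excl;
  std::vector<int> charged;
  // restraints
  std::vector<int> ri_ptr, ri_idx, rj_ptr, rj_idx, r_hb;
  std::vector<double> r_tgt;
  double skew_u, skew_l;
  double max_radius;
};

static inline long long pkey(int i, int j, int n) {
  return (long long)std::min(i, j) * n + std::max(i, j);
}

static void fill_system(const List& sys, System& S) {
  S.n = as<int>(sys["n_atoms"]);
  IntegerMatrix B = sys["bonds"];
  NumericVector br0 = sys["bond_r0"], bk = sys["bond_k"];
  for (int k = 0; k < B.nrow(); ++k) {
    S.b1.push_back(B(k, 0) - 1); S.b2.push_back(B(k, 1) - 1);
    S.br0.push_back(br0[k]); S.bk.push_back(bk[k]);
  }
  IntegerMatrix T = sys["tethers"];
  NumericVector tlo = sys["tether_lo"], thi = sys["tether_hi"],
                tk = sys["tether_k"];
  for (int k = 0; k < T.nrow(); ++k) {
    S.t1.push_back(T(k, 0) - 1); S.t2.push_back(T(k, 1) - 1);
    S.tlo.push_back(tlo[k]); S.thi.push_back(thi[k]); S.tk.push_back(tk[k]);
  }
  IntegerMatrix A = sys["angles"];
  NumericVector at0 = sys["angle_t0"], ak = sys["angle_k"];
  for (int k = 0; k < A.nrow(); ++k) {
    S.a1.push_back(A(k, 0) - 1); S.a2.push_back(A(k, 1) - 1);
    S.a3.push_back(A(k, 2) - 1);
    S.at0.push_back(at0[k] * M_PI / 180.0); S.ak.push_back(ak[k]);
  }
  IntegerMatrix D = sys["torsions"];
  NumericVector dp0 = sys["torsion_p0"], dk = sys["torsion_k"];
  for (int k = 0; k < D.nrow(); ++k) {
    S.d1.push_back(D(k, 0) - 1); S.d2.push_back(D(k, 1) - 1);
    S.d3.push_back(D(k, 2) - 1); S.d4.push_back(D(k, 3) - 1);
    S.dp0.push_back(dp0[k] * M_PI / 180.0); S.dk.push_back(dk[k]);
  }
  S.radii = as<std::vector<double>>(sys["radii"]);
  S.q = as<std::vector<double>>(sys["charges"]);
  S.mass = as<std::vector<double>>(sys["mass"]);
  S.k_rep = as<double>(sys["k_rep"]);
  S.rep_scale = as<double>(sys["rep_scale"]);
  S.coul_cut = as<double>(sys["coulomb_cutoff"]);
  IntegerMatrix E = sys["excl"];
  for (int k = 0; k < E.nrow(); ++k)
    S.excl.insert(pkey(E(k, 0) - 1, E(k, 1) - 1, S.n));
  for (int i = 0; i < S.n; ++i) if (S.q[i] != 0) S.charged.push_back(i);
  S.ri_ptr = as<std::vector<int>>(sys["rest_i_ptr"]);
  S.rj_ptr = as<std::vector<int>>(sys["rest_j_ptr"]);
  if (S.ri_ptr.size() > 1) {
    S.ri_idx = as<std::vector<int>>(sys["rest_i_idx"]);
    S.rj_idx = as<std::vector<int>>(sys["rest_j_idx"]);
  }
  S.r_tgt = as<std::vector<double>>(sys["rest_r"]);
  S.r_hb = as<std::vector<int>>(sys["rest_hbond"]);
  S.skew_u = as<double>(sys["skew_upper"]);
  S.skew_l = as<double>(sys["skew_lower"]);
  S.max_radius = 0;
  for (double r : S.radii) S.max_radius = std::max(S.max_radius, r);
}

struct Energies {
  double bond = 0, tether = 0, angle = 0, torsion = 0, rep = 0, coul = 0,
         restraint = 0;
  double total() const {
    return bond + tether + angle + torsion + rep + coul + restraint;
  }
};

// full energy + forces; forces array f (3n) is overwritten
static Energies eval_all(const System& S, const std::vector<double>& x,
                         double k_noe, double k_hbond,
                         std::vector<double>& f) {
  Energies E;
  std::fill(f.begin(), f.end(), 0.0);
  const int n = S.n;

  auto addf = [&](int i, double fx, double fy, double fz) {
    f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
  };
  auto dvec = [&](int i, int j, double* d) {
    d[0] = x[3 * i] - x[3 * j];
    d[1] = x[3 * i + 1] - x[3 * j + 1];
    d[2] = x[3 * i + 2] - x[3 * j + 2];
  };

  // bonds
  for (size_t k = 0; k < S.b1.size(); ++k) {
    double d[3]; dvec(S.b1[k], S.b2[k], d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double dr = r - S.br0[k];
    E.bond += S.bk[k] * dr * dr;
    double g = -2.0 * S.bk[k] * dr / std::max(r, 1e-8);
    addf(S.b1[k], g * d[0], g * d[1], g * d[2]);
    addf(S.b2[k], -g * d[0], -g * d[1], -g * d[2]);
  }
  // flat-bottom tethers
  for (size_t k = 0; k < S.t1.size(); ++k) {
    double d[3]; dvec(S.t1[k], S.t2[k], d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double ex = 0;
    if (r > S.thi[k]) ex = r - S.thi[k];
    else if (r < S.tlo[k]) ex = r - S.tlo[k];
    if (ex != 0) {
      E.tether += S.tk[k] * ex * ex;
      double g = -2.0 * S.tk[k] * ex / std::max(r, 1e-8);
      addf(S.t1[k], g * d[0], g * d[1], g * d[2]);
      addf(S.t2[k], -g * d[0], -g * d[1], -g * d[2]);
    }
  }
  // angles
  for (size_t k = 0; k < S.a1.size(); ++k) {
    int i = S.a1[k], j = S.a2[k], l = S.a3[k];
    double u[3], v[3];
    dvec(i, j, u); dvec(l, j, v);
    double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    double c = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - S.at0[k];
    E.angle += S.ak[k] * dth * dth;
    double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
    double coef = -2.0 * S.ak[k] * dth / s;   // dE/dc (chain rule via acos)
    for (int m = 0; m < 3; ++m) {
      double dci = (v[m] / nv - c * u[m] / nu) / nu;   // dc/dx_i
      double dcl = (u[m] / nu - c * v[m] / nv) / nv;   // dc/dx_l
      f[3 * i + m] -= coef * dci;                      // force = -dE/dx
      f[3 * l + m] -= coef * dcl;
      f[3 * j + m] += coef * (dci + dcl);
    }
  }
  // torsions (harmonic in wrapped delta-phi)
  for (size_t k = 0; k < S.d1.size(); ++k) {
    int i = S.d1[k], j = S.d2[k], l = S.d3[k], m = S.d4[k];
    double b1[3], b2[3], b3[3];
    for (int t = 0; t < 3; ++t) {
      b1[t] = x[3 * j + t] - x[3 * i + t];
      b2[t] = x[3 * l + t] - x[3 * j + t];
      b3[t] = x[3 * m + t] - x[3 * l + t];
    }
    double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                    b1[2] * b2[0] - b1[0] * b2[2],
                    b1[0] * b2[1] - b1[1] * b2[0]};
    double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                    b2[2] * b3[0] - b2[0] * b3[2],
                    b2[0] * b3[1] - b2[1] * b3[0]};
    double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
    double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
    double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    if (n1sq < 1e-10 || n2sq < 1e-10 || nb2 < 1e-8) continue;
    double cx[3] = {n1[1] * n2[2] - n1[2] * n2[1],
                    n1[2] * n2[0] - n1[0] * n2[2],
                    n1[0] * n2[1] - n1[1] * n2[0]};
    // sign convention matches the R-side .dihedral (m1 . n2 form)
    double sphi = -(cx[0] * b2[0] + cx[1] * b2[1] + cx[2] * b2[2]) / nb2;
    double cphi = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double phi = std::atan2(sphi, cphi);
    double dphi = phi - S.dp0[k];
    while (dphi > M_PI) dphi -= 2 * M_PI;
    while (dphi < -M_PI) dphi += 2 * M_PI;
    E.torsion += S.dk[k] * dphi * dphi;
    double dEdphi = 2.0 * S.dk[k] * dphi;
    // dphi/dr
    // dphi/dr in this sign convention (verified against finite
    // differences): G1 = |b2|/|n1|^2 n1, G4 = -|b2|/|n2|^2 n2,
    // G2 = (-1-a) G1 + b G4, G3 = a G1 + (-1-b) G4,
    // with a = b1.b2/|b2|^2, b = b3.b2/|b2|^2.
    double g1[3], g4[3];
    for (int t = 0; t < 3; ++t) {
      g1[t] = nb2 / n1sq * n1[t];
      g4[t] = -nb2 / n2sq * n2[t];
    }
    double a = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (nb2 * nb2);
    double b = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (nb2 * nb2);
    for (int t = 0; t < 3; ++t) {
      double g2 = (-1.0 - a) * g1[t] + b * g4[t];
      double g3 = a * g1[t] + (-1.0 - b) * g4[t];
      f[3 * i + t] -= dEdphi * g1[t];
      f[3 * j + t] -= dEdphi * g2;
      f[3 * l + t] -= dEdphi * g3;
      f[3 * m + t] -= dEdphi * g4[t];
    }
  }
  // soft quartic repulsion (all pairs within reach, minus exclusions)
  double reach = 2.0 * S.rep_scale * S.max_radius;
  double reach2 = reach * reach;
  for (int i = 0; i < n - 1; ++i) {
    double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - x[3 * j];
      if (dx > reach || dx < -reach) continue;
      double dy = yi - x[3 * j + 1];
      double dz = zi - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= reach2) continue;
      double rm = S.rep_scale * (S.radii[i] + S.radii[j]);
      double rm2 = rm * rm;
      if (r2 >= rm2) continue;
      if (S.excl.count(pkey(i, j, n))) continue;
      double diff = rm2 - r2;
      E.rep += S.k_rep * diff * diff;
      double g = 4.0 * S.k_rep * diff;   // -dE/dr2 * 2
      addf(i, g * dx, g * dy, g * dz);
      addf(j, -g * dx, -g * dy, -g * dz);
    }
  }
  // electrostatics with eps(r) = r  =>  E = C q1 q2 / r^2
  for (size_t a = 0; a + 1 < S.charged.size(); ++a) {
    for (size_t b = a + 1; b < S.charged.size(); ++b) {
      int i = S.charged[a], j = S.charged[b];
      double d[3]; dvec(i, j, d);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 > S.coul_cut * S.coul_cut) continue;
      if (S.excl.count(pkey(i, j, n))) continue;
      double e = COULOMB * S.q[i] * S.q[j] / r2;
      E.coul += e;
      double g = 2.0 * e / r2;   // force = +2E/r^2 * dvec (repulsive if e>0)
      addf(i, g * d[0], g * d[1], g * d[2]);
      addf(j, -g * d[0], -g * d[1], -g * d[2]);
    }
  }
  // distance restraints between group centroids: skewed bi-harmonic
  // about the target distance (different stiffness above / below)
  size_t nrest = S.r_tgt.size();
  for (size_t k = 0; k < nrest; ++k) {
    int i0 = S.ri_ptr[k], i1 = S.ri_ptr[k + 1];
    int j0 = S.rj_ptr[k], j1 = S.rj_ptr[k + 1];
    double ci[3] = {0, 0, 0}, cj[3] = {0, 0, 0};
    for (int t = i0; t < i1; ++t)
      for (int m = 0; m < 3; ++m) ci[m] += x[3 * (S.ri_idx[t] - 1) + m];
    for (int t = j0; t < j1; ++t)
      for (int m = 0; m < 3; ++m) cj[m] += x[3 * (S.rj_idx[t] - 1) + m];
    int ni = i1 - i0, nj = j1 - j0;
    for (int m = 0; m < 3; ++m) { ci[m] /= ni; cj[m] /= nj; }
    double d[3] = {ci[0] - cj[0], ci[1] - cj[1], ci[2] - cj[2]};
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double kk = S.r_hb[k] ? k_hbond : k_noe;
    double ex = r - S.r_tgt[k];
    double skew = ex > 0 ? S.skew_u : S.skew_l;
    if (ex != 0) {
      E.restraint += kk * skew * ex * ex;
      double g = -2.0 * kk * skew * ex / std::max(r, 1e-8);
      for (int t = i0; t < i1; ++t) {
        int ii = S.ri_idx[t] - 1;
        addf(ii, g * d[0] / ni, g * d[1] / ni, g * d[2] / ni);
      }
      for (int t = j0; t < j1; ++t) {
        int jj = S.rj_idx[t] - 1;
        addf(jj, -g * d[0] / nj, -g * d[1] / nj, -g * d[2] / nj);
      }
    }
  }
  return E;
}

static List energies_list(const Energies& E) {
  return List::create(
    _["E_bond"] = E.bond, _["E_tether"] = E.tether, _["E_angle"] = E.angle,
    _["E_torsion"] = E.torsion, _["E_repulsion"] = E.rep,
    _["E_coulomb"] = E.coul, _["E_restraint"] = E.restraint,
    _["E_total"] = E.total());
}

// [[Rcpp::export]]
List engine_eval(List sys, NumericMatrix xyz, double k_noe, double k_hbond) {
  System S; fill_system(sys, S);
  std::vector<double> x(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int m = 0; m < 3; ++m) x[3 * i + m] = xyz(i, m);
  Energies E = eval_all(S, x, k_noe, k_hbond, f);
  NumericMatrix fo(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int m = 0; m < 3; ++m) fo(i, m) = f[3 * i + m];
  List out = energies_list(E);
  out["forces"] = fo;
  return out;
}

// [[Rcpp::export]]
List engine_anneal(List sys, NumericMatrix xyz0, NumericMatrix vel0,
                   DataFrame stages, int nmin) {
  System S; fill_system(sys, S);
  const int n = S.n;
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < 3; ++m) {
      x[3 * i + m] = xyz0(i, m);
      v[3 * i + m] = vel0(i, m);
    }
  IntegerVector st_steps = stages["nsteps"];
  NumericVector st_dt = stages["dt_fs"], st_T = stages["temperature"];
  NumericVector st_kn0 = stages["k_noe_start"], st_kn1 = stages["k_noe_end"];
  NumericVector st_kh0 = stages["k_hbond_start"], st_kh1 = stages["k_hbond_end"];
  IntegerVector st_avg = stages["average"];
  int n_stages = st_steps.size();

  double k_noe = st_kn1[n_stages - 1], k_hb = st_kh1[n_stages - 1];
  Energies E = eval_all(S, x, st_kn0[0], st_kh0[0], f);
  bool aborted = false;

  std::vector<double> xsum(3 * n, 0.0);
  long navg = 0;
  NumericVector log_T(n_stages), log_E(n_stages), log_Er(n_stages);

  for (int s = 0; s < n_stages && !aborted; ++s) {
    int steps = st_steps[s];
    double dt = st_dt[s] / AKMA_FS;
    double Ttarget = st_T[s];
    double tsum = 0; long tcount = 0;
    int skip = steps / 10;
    for (int step = 0; step < steps; ++step) {
      double frac = steps > 1 ? (double)step / (steps - 1) : 1.0;
      k_noe = st_kn0[s] + frac * (st_kn1[s] - st_kn0[s]);
      k_hb = st_kh0[s] + frac * (st_kh1[s] - st_kh0[s]);
      // velocity Verlet
      for (int i = 0; i < n; ++i)
        for (int m = 0; m < 3; ++m) {
          v[3 * i + m] += 0.5 * dt * f[3 * i + m] / S.mass[i];
          x[3 * i + m] += dt * v[3 * i + m];
        }
      E = eval_all(S, x, k_noe, k_hb, f);
      if (!std::isfinite(E.total()) || std::fabs(E.total()) > 1e10) {
        aborted = true; break;
      }
      double ke = 0;
      for (int i = 0; i < n; ++i)
        for (int m = 0; m < 3; ++m) {
          v[3 * i + m] += 0.5 * dt * f[3 * i + m] / S.mass[i];
          ke += 0.5 * S.mass[i] * v[3 * i + m] * v[3 * i + m];
        }
      double Tkin = 2.0 * ke / (3.0 * n * KB);
      if (step >= skip) { tsum += Tkin; ++tcount; }
      double lambda = Tkin > 1e-12 ? std::sqrt(Ttarget / Tkin) : 1.0;
      for (int i = 0; i < 3 * n; ++i) v[i] *= lambda;
      if (st_avg[s]) {
        for (int i = 0; i < 3 * n; ++i) xsum[i] += x[i];
        ++navg;
      }
    }
    log_T[s] = tcount ? tsum / tcount : NA_REAL;
    log_E[s] = E.total();
    log_Er[s] = E.restraint;
  }

  if (!aborted && navg > 0)
    for (int i = 0; i < 3 * n; ++i) x[i] = xsum[i] / navg;

  // steepest-descent minimization with adaptive step
  double alpha = 0.01;   // max per-coordinate displacement cap (A)
  if (!aborted && nmin > 0) {
    E = eval_all(S, x, k_noe, k_hb, f);
    std::vector<double> xtry(3 * n), ftry(3 * n);
    for (int it = 0; it < nmin; ++it) {
      double fmax = 0;
      for (int i = 0; i < 3 * n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
      if (fmax < 1e-6) break;
      double scale = alpha / std::max(fmax, 1.0);
      for (int i = 0; i < 3 * n; ++i) xtry[i] = x[i] + scale * f[i];
      Energies Et = eval_all(S, xtry, k_noe, k_hb, ftry);
      if (std::isfinite(Et.total()) && Et.total() < E.total()) {
        x = xtry; f = ftry; E = Et; alpha *= 1.2;
      } else {
        alpha *= 0.5;
      }
    }
  }
  E = eval_all(S, x, k_noe, k_hb, f);

  NumericMatrix xo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < 3; ++m) xo(i, m) = x[3 * i + m];
  List out = energies_list(E);
  out["xyz"] = xo;
  out["aborted"] = aborted;
  out["stage_T"] = log_T;
  out["stage_E"] = log_E;
  out["stage_E_restraint"] = log_Er;
  return out;
}
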