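// Core numerical kernels for the bead-spring filament model:
// harmonic bond / harmonic angle / cosine dihedral energies and analytic
// gradients, a BAOAB Langevin integrator, and binary image thinning.
// Units: nm, pN, pN*nm, ns, radians. Indices are 0-based on entry.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}

struct Topo {
  std::vector<int> bi, bj;
  std::vector<double> l0, kl;
  std::vector<int> aj, ai, ak;
  std::vector<double> th0, kth;
  std::vector<int> di, dj, dk, dl, mult;
  std::vector<double> ph0, kph;
};

static Topo make_topo(const IntegerMatrix& bonds, const NumericVector& l0,
                      const NumericVector& kl,
                      const IntegerMatrix& angles, const NumericVector& th0,
                      const NumericVector& kth,
                      const IntegerMatrix& dihedrals, const NumericVector& ph0,
                      const NumericVector& kph, const IntegerVector& mult) {
  Topo t;
  int nb = bonds.nrow(), na = angles.nrow(), nd = dihedrals.nrow();
  t.bi.resize(nb); t.bj.resize(nb); t.l0.resize(nb); t.kl.resize(nb);
  for (int q = 0; q < nb; ++q) {
    t.bi[q] = bonds(q, 0); t.bj[q] = bonds(q, 1);
    t.l0[q] = l0[q]; t.kl[q] = kl[q];
  }
  t.aj.resize(na); t.ai.resize(na); t.ak.resize(na);
  t.th0.resize(na); t.kth.resize(na);
  for (int q = 0; q < na; ++q) {
    t.aj[q] = angles(q, 0); t.ai[q] = angles(q, 1); t.ak[q] = angles(q, 2);
    t.th0[q] = th0[q]; t.kth[q] = kth[q];
  }
  t.di.resize(nd); t.dj.resize(nd); t.dk.resize(nd); t.dl.resize(nd);
  t.ph0.resize(nd); t.kph.resize(nd); t.mult.resize(nd);
  for (int q = 0; q < nd; ++q) {
    t.di[q] = dihedrals(q, 0); t.dj[q] = dihedrals(q, 1);
    t.dk[q] = dihedrals(q, 2); t.dl[q] = dihedrals(q, 3);
    t.ph0[q] = ph0[q]; t.kph[q] = kph[q]; t.mult[q] = mult[q];
  }
  return t;
}

// p is row-major (x,y,z per particle); force accumulated likewise if given
static double eval_raw(const double* p, const Topo& t, double* force) {
  double E = 0.0;

  for (size_t b = 0; b < t.bi.size(); ++b) {
    const double* pi = p + 3 * t.bi[b];
    const double* pj = p + 3 * t.bj[b];
    double d[3] = { pi[0]-pj[0], pi[1]-pj[1], pi[2]-pj[2] };
    double l = std::sqrt(dot3(d, d));
    if (l <= 0) stop("coincident bonded particles %d and %d",
                     t.bi[b] + 1, t.bj[b] + 1);
    double dl = l - t.l0[b];
    E += 0.5 * t.kl[b] * dl * dl;
    if (force) {
      double f = -t.kl[b] * dl / l;
      double* fi = force + 3 * t.bi[b];
      double* fj = force + 3 * t.bj[b];
      for (int c = 0; c < 3; ++c) { fi[c] += f * d[c]; fj[c] -= f * d[c]; }
    }
  }

  for (size_t a = 0; a < t.ai.size(); ++a) {
    const double* pj = p + 3 * t.aj[a];
    const double* pi = p + 3 * t.ai[a];
    const double* pk = p + 3 * t.ak[a];
    double u[3] = { pj[0]-pi[0], pj[1]-pi[1], pj[2]-pi[2] };
    double v[3] = { pk[0]-pi[0], pk[1]-pi[1], pk[2]-pi[2] };
    double lu2 = dot3(u, u), lv2 = dot3(v, v);
    if (lu2 <= 0 || lv2 <= 0)
      stop("degenerate angle triplet at vertex %d", t.ai[a] + 1);
    double lu = std::sqrt(lu2), lv = std::sqrt(lv2);
    double ct = dot3(u, v) / (lu * lv);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double dth = th - t.th0[a];
    E += 0.5 * t.kth[a] * dth * dth;
    if (force) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-10) st = 1e-10; // collinear arms: clamped
      double coef = t.kth[a] * dth / st;
      double* fjv = force + 3 * t.aj[a];
      double* fiv = force + 3 * t.ai[a];
      double* fkv = force + 3 * t.ak[a];
      for (int c = 0; c < 3; ++c) {
        double dcdu = (v[c] / (lu * lv)) - ct * u[c] / lu2;
        double dcdv = (u[c] / (lu * lv)) - ct * v[c] / lv2;
        double fj = coef * dcdu;
        double fk = coef * dcdv;
        fjv[c] += fj; fkv[c] += fk; fiv[c] -= (fj + fk);
      }
    }
  }

  for (size_t d = 0; d < t.di.size(); ++d) {
    const double* pi = p + 3 * t.di[d];
    const double* pj = p + 3 * t.dj[d];
    const double* pk = p + 3 * t.dk[d];
    const double* pl = p + 3 * t.dl[d];
    double b1[3] = { pj[0]-pi[0], pj[1]-pi[1], pj[2]-pi[2] };
    double b2[3] = { pk[0]-pj[0], pk[1]-pj[1], pk[2]-pj[2] };
    double b3[3] = { pl[0]-pk[0], pl[1]-pk[1], pl[2]-pk[2] };
    double n1[3], n2[3], m1[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    cross3(n1, n2, m1);
    double b2sq = dot3(b2, b2);
    if (b2sq <= 0) stop("degenerate dihedral quadruplet starting at %d",
                        t.di[d] + 1);
    double lb2 = std::sqrt(b2sq);
    double phi = std::atan2(dot3(m1, b2) / lb2, dot3(n1, n2));
    double nm = (double) t.mult[d];
    E += t.kph[d] * (1.0 - std::cos(nm * phi - t.ph0[d]));
    if (force) {
      double dV = t.kph[d] * nm * std::sin(nm * phi - t.ph0[d]);
      double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
      if (n1sq < 1e-18 || n2sq < 1e-18) continue; // collinear: no torque
      double c1 = -lb2 / n1sq, c2 = lb2 / n2sq;
      double s12 = dot3(b1, b2) / b2sq;
      double s32 = dot3(b3, b2) / b2sq;
      double* fi = force + 3 * t.di[d];
      double* fj = force + 3 * t.dj[d];
      double* fk = force + 3 * t.dk[d];
      double* fl = force + 3 * t.dl[d];
      for (int c = 0; c < 3; ++c) {
        double gi = c1 * n1[c];
        double gl = c2 * n2[c];
        double gj = (-1.0 - s12) * gi + s32 * gl;
        double gk = -gi - gj - gl;
        fi[c] -= dV * gi;
        fj[c] -= dV * gj;
        fk[c] -= dV * gk;
        fl[c] -= dV * gl;
      }
    }
  }
  return E;
}

static std::vector<double> pos_rowmajor(const NumericMatrix& pos) {
  const int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) p[3 * i + c] = pos(i, c);
  return p;
}

// [[Rcpp::export]]
double cg_energy_cpp(NumericMatrix pos,
                     IntegerMatrix bonds, NumericVector l0, NumericVector kl,
                     IntegerMatrix angles, NumericVector th0, NumericVector kth,
                     IntegerMatrix dihedrals, NumericVector ph0,
                     NumericVector kph, IntegerVector mult) {
  Topo t = make_topo(bonds, l0, kl, angles, th0, kth, dihedrals, ph0, kph, mult);
  std::vector<double> p = pos_rowmajor(pos);
  return eval_raw(p.data(), t, nullptr);
}

// [[Rcpp::export]]
NumericMatrix cg_forces_cpp(NumericMatrix pos,
                            IntegerMatrix bonds, NumericVector l0, NumericVector kl,
                            IntegerMatrix angles, NumericVector th0, NumericVector kth,
                            IntegerMatrix dihedrals, NumericVector ph0,
                            NumericVector kph, IntegerVector mult) {
  Topo t = make_topo(bonds, l0, kl, angles, th0, kth, dihedrals, ph0, kph, mult);
  std::vector<double> p = pos_rowmajor(pos);
  std::vector<double> f(p.size(), 0.0);
  double E = eval_raw(p.data(), t, f.data());
  const int n = pos.nrow();
  NumericMatrix force(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) force(i, c) = f[3 * i + c];
  force.attr("energy") = E;
  return force;
}

// BAOAB Langevin integrator. ext_force is n x 3 constant external force (pN);
// fixed is a 0-based index vector of immobilised particles. gamma = 0 and
// kBT = 0 gives velocity-Verlet NVE. Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
List cg_langevin_cpp(NumericMatrix pos0, NumericMatrix vel0,
                     IntegerMatrix bonds, NumericVector l0, NumericVector kl,
                     IntegerMatrix angles, NumericVector th0, NumericVector kth,
                     IntegerMatrix dihedrals, NumericVector ph0,
                     NumericVector kph, IntegerVector mult,
                     NumericMatrix ext_force, IntegerVector fixed,
                     double dt, double gamma, double kBT, double mass,
                     int nsteps, int save_every, double blow_up) {
  const int n = pos0.nrow();
  Topo topo = make_topo(bonds, l0, kl, angles, th0, kth, dihedrals, ph0, kph, mult);
  std::vector<double> pos = pos_rowmajor(pos0);
  std::vector<double> vel = pos_rowmajor(vel0);
  std::vector<double> ext = pos_rowmajor(ext_force);
  std::vector<double> force(3 * n, 0.0);
  std::vector<bool> is_fixed(n, false);
  for (int q = 0; q < fixed.size(); ++q) is_fixed[fixed[q]] = true;

  const int nsaved = nsteps / save_every;
  NumericVector frames(Dimension(n, 3, nsaved));
  double c1 = (gamma > 0) ? std::exp(-gamma * dt / mass) : 1.0;
  double c2 = (kBT > 0) ? std::sqrt((1.0 - c1 * c1) * kBT / mass) : 0.0;

  eval_raw(pos.data(), topo, force.data());
  for (int i = 0; i < n; ++i)
    if (!is_fixed[i]) for (int c = 0; c < 3; ++c)
      force[3 * i + c] += ext[3 * i + c];

  RNGScope rng;
  int isave = 0;
  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      if (is_fixed[i]) continue;
      double* v = &vel[3 * i];
      double* x = &pos[3 * i];
      const double* f = &force[3 * i];
      for (int c = 0; c < 3; ++c) {
        v[c] += 0.5 * dt * f[c] / mass;                 // B
        x[c] += 0.5 * dt * v[c];                        // A
        v[c] = c1 * v[c] + (c2 > 0 ? c2 * norm_rand() : 0.0); // O
        x[c] += 0.5 * dt * v[c];                        // A
      }
    }
    std::fill(force.begin(), force.end(), 0.0);
    eval_raw(pos.data(), topo, force.data());
    for (int i = 0; i < n; ++i) {
      if (is_fixed[i]) continue;
      double* v = &vel[3 * i];
      double* f = &force[3 * i];
      for (int c = 0; c < 3; ++c) {
        f[c] += ext[3 * i + c];
        v[c] += 0.5 * dt * f[c] / mass;                 // B
      }
    }
    if (step % save_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          frames[i + n * c + 3 * n * isave] = pos[3 * i + c];
      ++isave;
    }
    if (step % 1000 == 0) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(pos[i]) || std::fabs(pos[i]) > blow_up)
          stop("integration diverged at step %d (particle %d)", step, i / 3 + 1);
    }
  }
  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      pos_out(i, c) = pos[3 * i + c];
      vel_out(i, c) = vel[3 * i + c];
    }
  return List::create(_["frames"] = frames, _["pos"] = pos_out,
                      _["vel"] = vel_out);
}

// Zhang-Suen thinning of a binary image (matrix of 0/1), 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix thin_zhang_suen_cpp(IntegerMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix a = clone(img);
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return a(r, c);
  };
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < nr; ++r) for (int c = 0; c < nc; ++c) {
        if (!a(r, c)) continue;
        // neighbours p2..p9 clockwise from north
        int p2 = P(r-1,c),   p3 = P(r-1,c+1), p4 = P(r,c+1), p5 = P(r+1,c+1);
        int p6 = P(r+1,c),   p7 = P(r+1,c-1), p8 = P(r,c-1), p9 = P(r-1,c-1);
        int B = p2+p3+p4+p5+p6+p7+p8+p9;
        if (B < 2 || B > 6) continue;
        int p[9] = {p2,p3,p4,p5,p6,p7,p8,p9,p2};
        int A = 0;
        for (int q = 0; q < 8; ++q) if (p[q] == 0 && p[q+1] == 1) ++A;
        if (A != 1) continue;
        if (pass == 0) {
          if (p2*p4*p6 != 0 || p4*p6*p8 != 0) continue;
        } else {
          if (p2*p4*p8 != 0 || p2*p6*p8 != 0) continue;
        }
        kill.push_back(std::make_pair(r, c));
      }
      if (!kill.empty()) changed = true;
      for (size_t q = 0; q < kill.size(); ++q) a(kill[q].first, kill[q].second) = 0;
    }
  }
  return a;
}
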