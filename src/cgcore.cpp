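// Core numerics for the coarse-grained MD engine.
//
// Unit system (GROMACS-style, internally consistent without conversion
// factors): length nm, time ps, mass amu, energy kJ/mol, so that
// 1 amu nm^2 ps^-2 == 1 kJ/mol.  Temperature K, pressure reported in atm.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double KB = 0.0083144621;      // kJ mol^-1 K^-1
static const double PRESS_ATM = 16.388246;  // 1 kJ mol^-1 nm^-3 in atm

static inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// fast path for coordinates already wrapped into [0, box): |d| < box
static inline double mi_fast(double d, double half, double box) {
  if (d > half) return d - box;
  if (d < -half) return d + box;
  return d;
}

static inline double wrap0(double x, double box) {
  double w = x - box * std::floor(x / box);
  if (w >= box) w -= box;   // guard against floor rounding at the edge
  return w;
}

static inline bool excluded(int i, int j, const int* exptr, const int* exidx) {
  const int* lo = exidx + exptr[i];
  const int* hi = exidx + exptr[i + 1];
  return std::binary_search(lo, hi, j);
}

// ---------------------------------------------------------------------------
// Verlet pair list, built through linked cells when the box admits >= 3 cells
// per dimension, otherwise by an all-pairs scan (small test boxes).
// Excluded (1-2, 1-3 bonded) pairs are filtered at build time.
// ---------------------------------------------------------------------------
static void build_pairs(const double* x, int n, double box, double rlist,
                        const int* exptr, const int* exidx,
                        std::vector<int>& pi, std::vector<int>& pj) {
  pi.clear(); pj.clear();
  const double rl2 = rlist * rlist;
  const double half = 0.5 * box;
  // fine cells (up to 2 per list radius) cut the number of candidate pairs;
  // m >= 2s+1 keeps half-space offsets distinct modulo m
  int shells = 0, m = 0;
  for (int s = 2; s >= 1; --s) {
    int ms = (int)std::floor(box * s / rlist);
    if (ms >= 2 * s + 1) { shells = s; m = ms; break; }
  }
  if (shells == 0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = mi_fast(x[3*i]   - x[3*j],   half, box);
        double dy = mi_fast(x[3*i+1] - x[3*j+1], half, box);
        double dz = mi_fast(x[3*i+2] - x[3*j+2], half, box);
        if (dx*dx + dy*dy + dz*dz < rl2 && !excluded(i, j, exptr, exidx)) {
          pi.push_back(i); pj.push_back(j);
        }
      }
    }
    return;
  }
  const double cw = box / m;
  const int nc = m * m * m;
  // counting sort of beads into cells: contiguous per-cell ranges
  std::vector<int> cell_of(n), start(nc + 1, 0), order(n);
  for (int i = 0; i < n; ++i) {
    int a = (int)(wrap0(x[3*i],   box) / cw); if (a >= m) a = m - 1;
    int b = (int)(wrap0(x[3*i+1], box) / cw); if (b >= m) b = m - 1;
    int c = (int)(wrap0(x[3*i+2], box) / cw); if (c >= m) c = m - 1;
    int cell = (a * m + b) * m + c;
    cell_of[i] = cell;
    ++start[cell + 1];
  }
  for (int c = 0; c < nc; ++c) start[c + 1] += start[c];
  {
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[fill[cell_of[i]]++] = i;
  }
  // half-space neighbour offsets within `shells`, pruned by the minimum
  // possible cell-to-cell distance (self cell first)
  std::vector<int> off; off.reserve(200);
  off.push_back(0); off.push_back(0); off.push_back(0);
  for (int dz = -shells; dz <= shells; ++dz)
  for (int dy = -shells; dy <= shells; ++dy)
  for (int dx = -shells; dx <= shells; ++dx) {
    bool half = (dz > 0) || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0);
    if (!half) continue;
    double ex = std::max(std::abs(dx) - 1, 0) * cw;
    double ey = std::max(std::abs(dy) - 1, 0) * cw;
    double ez = std::max(std::abs(dz) - 1, 0) * cw;
    if (ex*ex + ey*ey + ez*ez > rl2) continue;
    off.push_back(dx); off.push_back(dy); off.push_back(dz);
  }
  const int noff = (int)off.size() / 3;
  std::vector<int> wt(m + 2 * shells);
  for (int i = 0; i < m + 2 * shells; ++i) wt[i] = (i - shells + m) % m;
  const int* wtp = wt.data() + shells;
  for (int a = 0; a < m; ++a)
  for (int b = 0; b < m; ++b)
  for (int c = 0; c < m; ++c) {
    int c1 = (a * m + b) * m + c;
    if (start[c1] == start[c1 + 1]) continue;
    for (int k = 0; k < noff; ++k) {
      int a2 = wtp[a + off[3*k]];
      int b2 = wtp[b + off[3*k+1]];
      int c2i = wtp[c + off[3*k+2]];
      int c2 = (a2 * m + b2) * m + c2i;
      const int s2 = start[c2 + 1];
      if (k == 0) {
        for (int ii = start[c1]; ii < s2; ++ii) {
          int i = order[ii];
          for (int jj = ii + 1; jj < s2; ++jj) {
            int j = order[jj];
            double dx = mi_fast(x[3*i]   - x[3*j],   half, box);
            double dy = mi_fast(x[3*i+1] - x[3*j+1], half, box);
            double dz = mi_fast(x[3*i+2] - x[3*j+2], half, box);
            if (dx*dx + dy*dy + dz*dz < rl2 && !excluded(i, j, exptr, exidx)) {
              pi.push_back(i); pj.push_back(j);
            }
          }
        }
      } else {
        const int i0 = start[c1], i1 = start[c1 + 1];
        const int j0 = start[c2];
        for (int ii = i0; ii < i1; ++ii) {
          int i = order[ii];
          double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
          for (int jj = j0; jj < s2; ++jj) {
            int j = order[jj];
            double dx = mi_fast(xi - x[3*j],   half, box);
            double dy = mi_fast(yi - x[3*j+1], half, box);
            double dz = mi_fast(zi - x[3*j+2], half, box);
            if (dx*dx + dy*dy + dz*dz < rl2 && !excluded(i, j, exptr, exidx)) {
              pi.push_back(i); pj.push_back(j);
            }
          }
        }
      }
    }
  }
}

struct EnergyAcc {
  double ebond = 0.0, eangle = 0.0, elj = 0.0, W = 0.0; // W: virial sum r.F
};

// expanded type table: index type + ntype*is_ring, so ring-ring pairs
// resolve their smaller sigma / scaled epsilon without branching
struct TypeTables {
  int nt2;
  std::vector<double> s2tab, etab;
  std::vector<int> teff;
};

static TypeTables make_type_tables(const int* type, const int* ring, int n,
                                   const double* sig, const double* eps,
                                   int ntype, double ring_sigma,
                                   double ring_eps_scale) {
  TypeTables t;
  t.nt2 = 2 * ntype;
  t.s2tab.resize(t.nt2 * t.nt2);
  t.etab.resize(t.nt2 * t.nt2);
  t.teff.resize(n);
  for (int a = 0; a < t.nt2; ++a)
    for (int b = 0; b < t.nt2; ++b) {
      bool rr = (a >= ntype) && (b >= ntype);
      double sg = rr ? ring_sigma : sig[(a % ntype) * ntype + (b % ntype)];
      double ee = eps[(a % ntype) * ntype + (b % ntype)] *
                  (rr ? ring_eps_scale : 1.0);
      t.s2tab[a * t.nt2 + b] = sg * sg;
      t.etab[a * t.nt2 + b] = ee;
    }
  for (int i = 0; i < n; ++i) t.teff[i] = type[i] + (ring[i] ? ntype : 0);
  return t;
}

// 12-6 LJ with the C1-continuous switching function applied to the potential
// between r_on and r_cut:
//   S(r) = (rc^2 - r^2)^2 (rc^2 + 2 r^2 - 3 ron^2) / (rc^2 - ron^2)^3
// with S(r<=ron)=1, S(r>=rc)=0, dS/dr(ron)=dS/dr(rc)=0.
static inline void lj_pair(double r2, double s2, double e,
                           double ron2, double rc2, double swdenom,
                           double& E, double& fac) {
  double inv_r2 = 1.0 / r2;
  double sr2 = s2 * inv_r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double V = 4.0 * e * (sr12 - sr6);
  double dVdr_r = 4.0 * e * (-12.0 * sr12 + 6.0 * sr6) * inv_r2; // (dV/dr)/r
  if (r2 > ron2) {
    double A = rc2 - r2;
    double B = rc2 + 2.0 * r2 - 3.0 * ron2;
    double S = A * A * B * swdenom;
    double dSdr_r = 12.0 * A * (ron2 - r2) * swdenom;        // (dS/dr)/r
    fac = -(dVdr_r * S + V * dSdr_r);
    E = V * S;
  } else {
    fac = -dVdr_r;
    E = V;
  }
}

static void eval_forces(const double* x, int n, double box,
                        const TypeTables& tt,
                        double ron2, double rc2, double swdenom,
                        const std::vector<int>& pi, const std::vector<int>& pj,
                        const int* b_i, const int* b_j,
                        const double* b_r0, const double* b_k, int nb,
                        const int* a_i, const int* a_j, const int* a_k,
                        const double* a_cos0, const double* a_kf, int na,
                        double* f, EnergyAcc& acc) {
  std::fill(f, f + 3 * n, 0.0);
  acc = EnergyAcc();
  const double half = 0.5 * box;
  const int nt2 = tt.nt2;
  const double* s2tab = tt.s2tab.data();
  const double* etab = tt.etab.data();
  const int* teff = tt.teff.data();
  // Lennard-Jones over the pair list
  const size_t np = pi.size();
  for (size_t p = 0; p < np; ++p) {
    int i = pi[p], j = pj[p];
    double dx = mi_fast(x[3*i]   - x[3*j],   half, box);
    double dy = mi_fast(x[3*i+1] - x[3*j+1], half, box);
    double dz = mi_fast(x[3*i+2] - x[3*j+2], half, box);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rc2) continue;
    int ti = teff[i] * nt2 + teff[j];
    double E, fac;
    lj_pair(r2, s2tab[ti], etab[ti], ron2, rc2, swdenom, E, fac);
    acc.elj += E;
    acc.W += fac * r2;
    f[3*i]   += fac * dx; f[3*j]   -= fac * dx;
    f[3*i+1] += fac * dy; f[3*j+1] -= fac * dy;
    f[3*i+2] += fac * dz; f[3*j+2] -= fac * dz;
  }
  // Harmonic bonds V = k/2 (r - r0)^2
  for (int b = 0; b < nb; ++b) {
    int i = b_i[b], j = b_j[b];
    double dx = mi_fast(x[3*i]   - x[3*j],   half, box);
    double dy = mi_fast(x[3*i+1] - x[3*j+1], half, box);
    double dz = mi_fast(x[3*i+2] - x[3*j+2], half, box);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - b_r0[b];
    acc.ebond += 0.5 * b_k[b] * dr * dr;
    double fac = -b_k[b] * dr / r;
    acc.W += fac * r * r;
    f[3*i]   += fac * dx; f[3*j]   -= fac * dx;
    f[3*i+1] += fac * dy; f[3*j+1] -= fac * dy;
    f[3*i+2] += fac * dz; f[3*j+2] -= fac * dz;
  }
  // Cosine-harmonic angles V = k/2 (cos(theta) - cos(theta0))^2
  // (regular at theta = 180 deg, the default equilibrium for CG chains)
  for (int t = 0; t < na; ++t) {
    int i = a_i[t], j = a_j[t], k = a_k[t];
    double ax = mi_fast(x[3*i]   - x[3*j],   half, box);
    double ay = mi_fast(x[3*i+1] - x[3*j+1], half, box);
    double az = mi_fast(x[3*i+2] - x[3*j+2], half, box);
    double bx = mi_fast(x[3*k]   - x[3*j],   half, box);
    double by = mi_fast(x[3*k+1] - x[3*j+1], half, box);
    double bz = mi_fast(x[3*k+2] - x[3*j+2], half, box);
    double la2 = ax*ax + ay*ay + az*az;
    double lb2 = bx*bx + by*by + bz*bz;
    double la = std::sqrt(la2), lb = std::sqrt(lb2);
    double cosv = (ax*bx + ay*by + az*bz) / (la * lb);
    if (cosv > 1.0) cosv = 1.0;
    if (cosv < -1.0) cosv = -1.0;
    double diff = cosv - a_cos0[t];
    acc.eangle += 0.5 * a_kf[t] * diff * diff;
    double dVdc = a_kf[t] * diff;
    double inv_ab = 1.0 / (la * lb);
    // grad of cos(theta) wrt r_i and r_k
    double gix = bx * inv_ab - cosv * ax / la2;
    double giy = by * inv_ab - cosv * ay / la2;
    double giz = bz * inv_ab - cosv * az / la2;
    double gkx = ax * inv_ab - cosv * bx / lb2;
    double gky = ay * inv_ab - cosv * by / lb2;
    double gkz = az * inv_ab - cosv * bz / lb2;
    double fix = -dVdc * gix, fiy = -dVdc * giy, fiz = -dVdc * giz;
    double fkx = -dVdc * gkx, fky = -dVdc * gky, fkz = -dVdc * gkz;
    f[3*i]   += fix; f[3*i+1] += fiy; f[3*i+2] += fiz;
    f[3*k]   += fkx; f[3*k+1] += fky; f[3*k+2] += fkz;
    f[3*j]   -= fix + fkx; f[3*j+1] -= fiy + fky; f[3*j+2] -= fiz + fkz;
    acc.W += ax*fix + ay*fiy + az*fiz + bx*fkx + by*fky + bz*fkz;
  }
}

// Locate the closest pair (diagnostic for non-finite forces).
static void closest_pair(const double* x, int n, double box,
                         int& bi, int& bj, double& br) {
  br = 1e30; bi = -1; bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x[3*i]   - x[3*j],   box);
      double dy = min_image(x[3*i+1] - x[3*j+1], box);
      double dz = min_image(x[3*i+2] - x[3*j+2], box);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < br) { br = r; bi = i; bj = j; }
    }
}

// [[Rcpp::export]]
List cg_forces_cpp(NumericMatrix pos, double box,
                   IntegerVector type, IntegerVector ring,
                   NumericMatrix sigma, NumericMatrix eps,
                   double ring_sigma, double ring_eps_scale,
                   double r_on, double r_cut,
                   IntegerMatrix bonds, NumericVector bond_r0, NumericVector bond_k,
                   IntegerMatrix angles, NumericVector angle_cos0, NumericVector angle_k,
                   IntegerVector excl_ptr, IntegerVector excl_idx) {
  const int n = pos.nrow();
  const int ntype = sigma.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3*i] = pos(i, 0); x[3*i+1] = pos(i, 1); x[3*i+2] = pos(i, 2);
  }
  std::vector<double> sg(ntype * ntype), ep(ntype * ntype);
  for (int a = 0; a < ntype; ++a)
    for (int b = 0; b < ntype; ++b) {
      sg[a * ntype + b] = sigma(a, b);
      ep[a * ntype + b] = eps(a, b);
    }
  std::vector<int> pi, pj;
  build_pairs(x.data(), n, box, r_cut, excl_ptr.begin(), excl_idx.begin(), pi, pj);
  const int nb = bonds.nrow(), na = angles.nrow();
  std::vector<int> b_i(nb), b_j(nb), a_i(na), a_j(na), a_k(na);
  for (int b = 0; b < nb; ++b) { b_i[b] = bonds(b, 0); b_j[b] = bonds(b, 1); }
  for (int t = 0; t < na; ++t) { a_i[t] = angles(t, 0); a_j[t] = angles(t, 1); a_k[t] = angles(t, 2); }
  std::vector<double> f(3 * n);
  EnergyAcc acc;
  double rc2 = r_cut * r_cut, ron2 = r_on * r_on;
  double swdenom = 1.0 / ((rc2 - ron2) * (rc2 - ron2) * (rc2 - ron2));
  TypeTables tt = make_type_tables(type.begin(), ring.begin(), n, sg.data(),
                                   ep.data(), ntype, ring_sigma, ring_eps_scale);
  eval_forces(x.data(), n, box, tt, ron2, rc2, swdenom, pi, pj,
              b_i.data(), b_j.data(), bond_r0.begin(), bond_k.begin(), nb,
              a_i.data(), a_j.data(), a_k.data(),
              angle_cos0.begin(), angle_k.begin(), na, f.data(), acc);
  bool ok = true;
  for (int i = 0; i < 3 * n && ok; ++i) ok = std::isfinite(f[i]);
  if (!ok) {
    int bi, bj; double br;
    closest_pair(x.data(), n, box, bi, bj, br);
    stop("non-finite force (overlapping beads): closest pair %d-%d at %g nm",
         bi + 1, bj + 1, br);
  }
  NumericMatrix fr(n, 3);
  for (int i = 0; i < n; ++i) {
    fr(i, 0) = f[3*i]; fr(i, 1) = f[3*i+1]; fr(i, 2) = f[3*i+2];
  }
  return List::create(_["forces"] = fr, _["bond"] = acc.ebond,
                      _["angle"] = acc.eangle, _["lj"] = acc.elj,
                      _["virial"] = acc.W, _["n_pairs"] = (int)pi.size());
}

// ---------------------------------------------------------------------------
// MD driver: velocity-Verlet with a Langevin thermostat in BAOAB splitting
// (B half-kick, A half-drift, O Ornstein-Uhlenbeck velocity update, A, B).
// With gamma = 0 the O step is the identity and the scheme reduces exactly
// to NVE velocity Verlet.  Optional weak-coupling isotropic barostat.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix pos, NumericMatrix vel, double box,
                IntegerVector type, IntegerVector ring, NumericVector mass,
                NumericMatrix sigma, NumericMatrix eps,
                double ring_sigma, double ring_eps_scale,
                double r_on, double r_cut, double skin,
                IntegerMatrix bonds, NumericVector bond_r0, NumericVector bond_k,
                IntegerMatrix angles, NumericVector angle_cos0, NumericVector angle_k,
                IntegerVector excl_ptr, IntegerVector excl_idx,
                double dt, int n_steps, double gamma, double target_t,
                bool barostat, double target_p, double tau_p, double beta_p,
                int output_stride, int energy_stride) {
  const int n = pos.nrow();
  const int ntype = sigma.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), xref(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3*i] = pos(i, 0); x[3*i+1] = pos(i, 1); x[3*i+2] = pos(i, 2);
    v[3*i] = vel(i, 0); v[3*i+1] = vel(i, 1); v[3*i+2] = vel(i, 2);
  }
  std::vector<double> sg(ntype * ntype), ep(ntype * ntype);
  for (int a = 0; a < ntype; ++a)
    for (int b = 0; b < ntype; ++b) {
      sg[a * ntype + b] = sigma(a, b);
      ep[a * ntype + b] = eps(a, b);
    }
  const int nb = bonds.nrow(), na = angles.nrow();
  std::vector<int> b_i(nb), b_j(nb), a_i(na), a_j(na), a_k(na);
  for (int b = 0; b < nb; ++b) { b_i[b] = bonds(b, 0); b_j[b] = bonds(b, 1); }
  for (int t = 0; t < na; ++t) { a_i[t] = angles(t, 0); a_j[t] = angles(t, 1); a_k[t] = angles(t, 2); }

  const double rc2 = r_cut * r_cut, ron2 = r_on * r_on;
  const double swdenom = 1.0 / ((rc2 - ron2) * (rc2 - ron2) * (rc2 - ron2));
  const double rlist = r_cut + skin;
  const double half_skin2 = 0.25 * skin * skin;

  std::vector<int> pi, pj;
  EnergyAcc acc;
  TypeTables ttab = make_type_tables(type.begin(), ring.begin(), n, sg.data(),
                                     ep.data(), ntype, ring_sigma,
                                     ring_eps_scale);

  auto rebuild = [&]() {
    build_pairs(x.data(), n, box, rlist, excl_ptr.begin(), excl_idx.begin(), pi, pj);
    std::copy(x.begin(), x.end(), xref.begin());
  };
  auto forces = [&](int step) {
    eval_forces(x.data(), n, box, ttab, ron2, rc2, swdenom, pi, pj,
                b_i.data(), b_j.data(), bond_r0.begin(), bond_k.begin(), nb,
                a_i.data(), a_j.data(), a_k.data(),
                angle_cos0.begin(), angle_k.begin(), na, f.data(), acc);
    bool ok = true;
    for (int i = 0; i < 3 * n && ok; ++i) ok = std::isfinite(f[i]);
    if (!ok) {
      int bi, bj; double br;
      closest_pair(x.data(), n, box, bi, bj, br);
      stop("non-finite force at step %d: closest pair %d-%d at %g nm",
           step, bi + 1, bj + 1, br);
    }
  };
  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    return ke;
  };

  rebuild();
  forces(0);

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  // outputs
  List frames;
  std::vector<double> frame_time, frame_box;
  std::vector<double> s_step, s_time, s_ebond, s_eangle, s_elj, s_ekin,
      s_etot, s_temp, s_press, s_box;

  auto snap_frame = [&](double t) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) {
      fr(i, 0) = x[3*i]; fr(i, 1) = x[3*i+1]; fr(i, 2) = x[3*i+2];
    }
    frames.push_back(fr);
    frame_time.push_back(t);
    frame_box.push_back(box);
  };
  auto snap_energy = [&](int step) {
    double ke = kinetic();
    double pot = acc.ebond + acc.eangle + acc.elj;
    double vol = box * box * box;
    double press = (2.0 * ke + acc.W) / (3.0 * vol) * PRESS_ATM;
    s_step.push_back(step);
    s_time.push_back(step * dt);
    s_ebond.push_back(acc.ebond);
    s_eangle.push_back(acc.eangle);
    s_elj.push_back(acc.elj);
    s_ekin.push_back(ke);
    s_etot.push_back(pot + ke);
    s_temp.push_back(2.0 * ke / (3.0 * n * KB));
    s_press.push_back(press);
    s_box.push_back(box);
  };

  snap_frame(0.0);
  snap_energy(0);

  const double sqrt_kt = std::sqrt(KB * target_t);
  for (int step = 1; step <= n_steps; ++step) {
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
    // stability guard: one-step displacement must stay below the skin
    double vmax2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double vv = v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2];
      if (vv > vmax2) vmax2 = vv;
    }
    if (std::sqrt(vmax2) * dt > skin)
      stop("stability error at step %d: one-step displacement exceeds the neighbour skin (time step too large for current forces)", step);
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / mass[i];
      v[3*i] += h * f[3*i]; v[3*i+1] += h * f[3*i+1]; v[3*i+2] += h * f[3*i+2];
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck (identity when gamma == 0)
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i) {
        double sd = sqrt_kt / std::sqrt(mass[i]);
        v[3*i]   = c1 * v[3*i]   + c2 * sd * norm_rand();
        v[3*i+1] = c1 * v[3*i+1] + c2 * sd * norm_rand();
        v[3*i+2] = c1 * v[3*i+2] + c2 * sd * norm_rand();
      }
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    for (int i = 0; i < 3 * n; ++i) x[i] = wrap0(x[i], box);
    // neighbour list maintenance
    double dmax2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = min_image(x[3*i]   - xref[3*i],   box);
      double dy = min_image(x[3*i+1] - xref[3*i+1], box);
      double dz = min_image(x[3*i+2] - xref[3*i+2], box);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > dmax2) dmax2 = d2;
    }
    if (dmax2 > half_skin2) rebuild();
    // force update + B: half kick
    forces(step);
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / mass[i];
      v[3*i] += h * f[3*i]; v[3*i+1] += h * f[3*i+1]; v[3*i+2] += h * f[3*i+2];
    }
    // weak-coupling isotropic barostat
    if (barostat) {
      double ke = kinetic();
      double vol = box * box * box;
      double press = (2.0 * ke + acc.W) / (3.0 * vol) * PRESS_ATM;
      double mu3 = 1.0 - (dt / tau_p) * beta_p * (target_p - press);
      double mu = std::cbrt(std::max(0.97, std::min(1.03, mu3)));
      if (mu != 1.0) {
        box *= mu;
        for (int i = 0; i < 3 * n; ++i) x[i] *= mu;
        // xref kept: displacement check measures the drift and triggers rebuild
      }
    }
    if (output_stride > 0 && step % output_stride == 0) snap_frame(step * dt);
    if (energy_stride > 0 && step % energy_stride == 0) snap_energy(step);
  }

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    pout(i, 0) = x[3*i]; pout(i, 1) = x[3*i+1]; pout(i, 2) = x[3*i+2];
    vout(i, 0) = v[3*i]; vout(i, 1) = v[3*i+1]; vout(i, 2) = v[3*i+2];
  }
  DataFrame series = DataFrame::create(
      _["step"] = s_step, _["time"] = s_time, _["bond"] = s_ebond,
      _["angle"] = s_eangle, _["lj"] = s_elj, _["kinetic"] = s_ekin,
      _["total"] = s_etot, _["temperature"] = s_temp,
      _["pressure"] = s_press, _["box"] = s_box);
  return List::create(_["pos"] = pout, _["vel"] = vout, _["box"] = box,
                      _["frames"] = frames,
                      _["frame_time"] = NumericVector(frame_time.begin(), frame_time.end()),
                      _["frame_box"] = NumericVector(frame_box.begin(), frame_box.end()),
                      _["series"] = series);
}

// ---------------------------------------------------------------------------
// Intermolecular contacts: unique molecule pairs with any bead pair within
// cutoff (minimum image), plus one representative bead pair per contact.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cg_contact_pairs_cpp(NumericMatrix pos, double box, double cutoff,
                                   IntegerVector mol) {
  const int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3*i] = pos(i, 0); x[3*i+1] = pos(i, 1); x[3*i+2] = pos(i, 2);
  }
  std::vector<int> noex_ptr(n + 1, 0);
  std::vector<int> pi, pj;
  build_pairs(x.data(), n, box, cutoff, noex_ptr.data(), noex_ptr.data(), pi, pj);
  std::vector<std::pair<long long, std::pair<int,int> > > seen;
  for (size_t p = 0; p < pi.size(); ++p) {
    int mi = mol[pi[p]], mj = mol[pj[p]];
    if (mi == mj) continue;
    int lo = std::min(mi, mj), hi = std::max(mi, mj);
    int bi = (mi == lo) ? pi[p] : pj[p];
    int bj = (mi == lo) ? pj[p] : pi[p];
    seen.push_back(std::make_pair(((long long)lo << 32) | (unsigned int)hi,
                                  std::make_pair(bi, bj)));
  }
  std::sort(seen.begin(), seen.end());
  std::vector<std::pair<long long, std::pair<int,int> > > uniq;
  for (size_t p = 0; p < seen.size(); ++p)
    if (uniq.empty() || uniq.back().first != seen[p].first) uniq.push_back(seen[p]);
  IntegerMatrix out(uniq.size(), 4);
  for (size_t p = 0; p < uniq.size(); ++p) {
    out(p, 0) = (int)(uniq[p].first >> 32);
    out(p, 1) = (int)(uniq[p].first & 0xffffffffLL);
    out(p, 2) = uniq[p].second.first + 1;    // 1-based bead ids for R
    out(p, 3) = uniq[p].second.second + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Interior-water classification: voxelize the periodic box, block voxels
// whose centre lies within r_block of any lipid bead, flood fill the
// unblocked space from the box faces with periodic 6-connectivity; water
// beads in voxels not reached by the fill are interior.  Beads falling in a
// blocked voxel inherit the label of the nearest non-blocked voxel centre
// within a 3-voxel search radius (defaulting to exterior).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cg_interior_cpp(NumericMatrix lipid_pos, NumericMatrix water_pos,
                     double box, double voxel, double r_block) {
  int m = (int)std::lround(box / voxel);
  if (m < 3) m = 3;
  const double v = box / m;
  const int nc = m * m * m;
  std::vector<signed char> grid(nc, 0); // 0 free, 1 blocked, 2 exterior
  const int nl = lipid_pos.nrow();
  const int rb = (int)std::ceil(r_block / v);
  const double rb2 = r_block * r_block;
  for (int l = 0; l < nl; ++l) {
    double px = wrap0(lipid_pos(l, 0), box);
    double py = wrap0(lipid_pos(l, 1), box);
    double pz = wrap0(lipid_pos(l, 2), box);
    int cx = (int)(px / v), cy = (int)(py / v), cz = (int)(pz / v);
    for (int a = cx - rb; a <= cx + rb; ++a)
    for (int b = cy - rb; b <= cy + rb; ++b)
    for (int c = cz - rb; c <= cz + rb; ++c) {
      double qx = (a + 0.5) * v, qy = (b + 0.5) * v, qz = (c + 0.5) * v;
      double dx = min_image(qx - px, box);
      double dy = min_image(qy - py, box);
      double dz = min_image(qz - pz, box);
      if (dx*dx + dy*dy + dz*dz <= rb2) {
        int aa = ((a % m) + m) % m, bb = ((b % m) + m) % m, cc = ((c % m) + m) % m;
        grid[(aa * m + bb) * m + cc] = 1;
      }
    }
  }
  // Flood fill the exterior with periodic 6-connectivity.  The seed is the
  // unblocked voxel farthest (minimum image) from the lipid centre of mass
  // (circular mean per axis, so a box-straddling aggregate is handled):
  // whenever an exterior exists at all, that voxel belongs to it, and the
  // exterior is connected, so one seed suffices.  Seeding from the box
  // faces would misfire when the aggregate (or its cavity) straddles a
  // face.
  double com[3] = {0.0, 0.0, 0.0};
  if (nl > 0) {
    for (int k = 0; k < 3; ++k) {
      double sx = 0.0, cxs = 0.0;
      for (int l = 0; l < nl; ++l) {
        double th = 2.0 * M_PI * wrap0(lipid_pos(l, k), box) / box;
        sx += std::sin(th); cxs += std::cos(th);
      }
      com[k] = wrap0(std::atan2(sx, cxs) / (2.0 * M_PI) * box, box);
    }
  }
  int seed_id = -1;
  double best_d2 = -1.0;
  for (int a = 0; a < m; ++a)
  for (int b = 0; b < m; ++b)
  for (int c = 0; c < m; ++c) {
    int id = (a * m + b) * m + c;
    if (grid[id] != 0) continue;
    double dx = min_image((a + 0.5) * v - com[0], box);
    double dy = min_image((b + 0.5) * v - com[1], box);
    double dz = min_image((c + 0.5) * v - com[2], box);
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 > best_d2) { best_d2 = d2; seed_id = id; }
  }
  std::vector<int> stack;
  if (seed_id >= 0) { grid[seed_id] = 2; stack.push_back(seed_id); }
  while (!stack.empty()) {
    int id = stack.back(); stack.pop_back();
    int c = id % m, b = (id / m) % m, a = id / (m * m);
    const int na[6][3] = {{a+1,b,c},{a-1,b,c},{a,b+1,c},{a,b-1,c},{a,b,c+1},{a,b,c-1}};
    for (int k = 0; k < 6; ++k) {
      int aa = (na[k][0] + m) % m, bb = (na[k][1] + m) % m, cc = (na[k][2] + m) % m;
      int nid = (aa * m + bb) * m + cc;
      if (grid[nid] == 0) { grid[nid] = 2; stack.push_back(nid); }
    }
  }
  const int nw = water_pos.nrow();
  LogicalVector inside(nw);
  for (int w = 0; w < nw; ++w) {
    double px = wrap0(water_pos(w, 0), box);
    double py = wrap0(water_pos(w, 1), box);
    double pz = wrap0(water_pos(w, 2), box);
    int cx = (int)(px / v), cy = (int)(py / v), cz = (int)(pz / v);
    if (cx >= m) cx = m - 1; if (cy >= m) cy = m - 1; if (cz >= m) cz = m - 1;
    signed char g = grid[(cx * m + cy) * m + cz];
    if (g == 1) {
      // nearest non-blocked voxel centre within 3 shells
      double best = 1e30; signed char bg = 2;
      for (int a = cx - 3; a <= cx + 3; ++a)
      for (int b = cy - 3; b <= cy + 3; ++b)
      for (int c = cz - 3; c <= cz + 3; ++c) {
        int aa = ((a % m) + m) % m, bb = ((b % m) + m) % m, cc = ((c % m) + m) % m;
        signed char gg = grid[(aa * m + bb) * m + cc];
        if (gg == 1) continue;
        double qx = (a + 0.5) * v, qy = (b + 0.5) * v, qz = (c + 0.5) * v;
        double dx = min_image(qx - px, box);
        double dy = min_image(qy - py, box);
        double dz = min_image(qz - pz, box);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) { best = d2; bg = gg; }
      }
      g = bg;
    }
    inside[w] = (g == 0);
  }
  int n_ext = 0, n_blocked = 0;
  for (int id = 0; id < nc; ++id) {
    if (grid[id] == 2) ++n_ext;
    if (grid[id] == 1) ++n_blocked;
  }
  return List::create(_["inside"] = inside, _["n_voxels"] = nc,
                      _["n_exterior"] = n_ext, _["n_blocked"] = n_blocked,
                      _["voxel_actual"] = v);
}
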