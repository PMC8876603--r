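#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Energy units: kcal/mol; distances: Angstrom; charges: elementary units.
static const double COULOMB_K = 332.06;

// Soft saturation of a potential value. Exact identity for |e| <= a, then a
// smooth tanh compression bounded by a + s. Keeps grid and direct evaluation
// consistent near clashes while leaving the physically relevant range intact.
static inline double soft_cap(double e, double a, double s) {
  double ae = std::fabs(e);
  if (ae <= a) return e;
  double v = a + s * std::tanh((ae - a) / s);
  return e < 0 ? -v : v;
}

// Hawkins-Cramer-Truhlar pairwise descreening integral: contribution of a
// descreening sphere of (scaled) radius rho_j at distance r to 1/B of a probe
// with intrinsic radius rho_i.
static inline double hct_integral(double r, double rho_i, double rho_j) {
  if (rho_j <= 0.0) return 0.0;
  if (r + rho_j <= rho_i) return 0.0;       // fully engulfed by the probe
  double L = std::fabs(r - rho_j);
  if (L < rho_i) L = rho_i;
  double U = r + rho_j;
  if (L >= U) return 0.0;
  double invL = 1.0 / L, invU = 1.0 / U;
  double term = invL - invU
    + 0.25 * r * (invU * invU - invL * invL)
    + 0.5 / r * std::log(L / U)
    + 0.25 * (rho_j * rho_j / r) * (invL * invL - invU * invU);
  return 0.5 * term;
}

static inline double lj_1210(double r2, double eps, double rmin) {
  double s2 = (rmin * rmin) / r2;
  double s6 = s2 * s2 * s2;
  return eps * (s6 * s6 - 2.0 * s6);
}

// The Van der Waals maps are stored in a distance-like transform: the
// repulsive sum A = sum eps (rm/r)^12 is tabulated as A^(-1/12) and the
// attractive sum B = sum 2 eps (rm/r)^6 as B^(-1/6). Both transforms are
// nearly linear in distance near an atom, so trilinear interpolation is
// accurate even inside the steep repulsive wall; the energy E = A - B is
// reconstructed per evaluation point and soft-capped there.
static const double VDW_SUM_FLOOR = 1e-10;
static inline double rep_transform(double a) {
  if (a < VDW_SUM_FLOOR) a = VDW_SUM_FLOOR;
  return std::pow(a, -1.0 / 12.0);
}
static inline double att_transform(double b) {
  if (b < VDW_SUM_FLOOR) b = VDW_SUM_FLOOR;
  return std::pow(b, -1.0 / 6.0);
}
static inline double vdw_reconstruct(double p, double q, double a_vdw,
                                     double sw) {
  if (p < 1e-6) p = 1e-6;
  if (q < 1e-6) q = 1e-6;
  double a = std::pow(p, -12.0);
  double b = std::pow(q, -6.0);
  return soft_cap(a - b, a_vdw, sw);
}

// Catmull-Rom weights: exact for cubic polynomials, giving 4th-order
// interpolation of the distance-like VdW transforms.
static inline void cr_weights(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// tricubic interpolation of the two VdW transform maps at one point
static inline void vdw_tricubic(const NumericMatrix &rep,
                                const NumericMatrix &att, int col,
                                double fx, double fy, double fz,
                                int nx, int ny, int nz,
                                double *p_out, double *q_out) {
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
      iz = (int)std::floor(fz);
  if (ix > nx - 2) ix = nx - 2;
  if (iy > ny - 2) iy = ny - 2;
  if (iz > nz - 2) iz = nz - 2;
  double wx[4], wy[4], wz[4];
  cr_weights(fx - ix, wx);
  cr_weights(fy - iy, wy);
  cr_weights(fz - iz, wz);
  double p = 0.0, q = 0.0;
  for (int a = 0; a < 4; ++a) {
    int za = clampi(iz + a - 1, 0, nz - 1);
    for (int b = 0; b < 4; ++b) {
      int yb = clampi(iy + b - 1, 0, ny - 1);
      double wzy = wz[a] * wy[b];
      R_xlen_t base = (R_xlen_t)nx * (yb + (R_xlen_t)ny * za);
      for (int c = 0; c < 4; ++c) {
        int xc = clampi(ix + c - 1, 0, nx - 1);
        double w = wzy * wx[c];
        p += w * rep(base + xc, col);
        q += w * att(base + xc, col);
      }
    }
  }
  *p_out = p;
  *q_out = q;
}

// Raw (uncapped) field components at a single point x for one probe type.
struct FieldAccum {
  double elec;     // kcal/(mol e)
  double inv_born; // accumulated descreening sum
};

// [[Rcpp::export]]
List cpp_build_maps(NumericMatrix rxyz, NumericVector q,
                    NumericVector eps, NumericVector rmin,
                    NumericVector origin, double spacing, IntegerVector nn,
                    NumericVector probe_eps, NumericVector probe_rmin,
                    double eps_in, double tau, double born_rho,
                    double hct_scale, double cap, double a_elec, double a_vdw) {
  const int na = rxyz.nrow();
  const int nx = nn[0], ny = nn[1], nz = nn[2];
  const R_xlen_t nnode = (R_xlen_t)nx * ny * nz;
  const int np = probe_eps.size();
  NumericVector elec(nnode), desolv(nnode);
  NumericMatrix vdw_rep(nnode, np), vdw_att(nnode, np);
  const double s_width = cap - a_elec > 0 ? cap - a_elec : 1.0;

  R_xlen_t idx = 0;
  for (int kz = 0; kz < nz; ++kz) {
    double z = origin[2] + spacing * kz;
    for (int ky = 0; ky < ny; ++ky) {
      double y = origin[1] + spacing * ky;
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        double x = origin[0] + spacing * kx;
        double e = 0.0, binv = 0.0;
        std::vector<double> va(np, 0.0), vb(np, 0.0);
        for (int i = 0; i < na; ++i) {
          double dx = x - rxyz(i, 0), dy = y - rxyz(i, 1), dz = z - rxyz(i, 2);
          double r2 = dx * dx + dy * dy + dz * dz;
          double r = std::sqrt(r2);
          double rg = r < 0.05 ? 0.05 : r;
          e += COULOMB_K * q[i] / (eps_in * rg);
          for (int p = 0; p < np; ++p) {
            double rm = 0.5 * (rmin[i] + probe_rmin[p]);
            double ee = std::sqrt(eps[i] * probe_eps[p]);
            if (ee > 0.0) {
              double s2 = (rm * rm) / (rg * rg);
              double s6 = s2 * s2 * s2;
              va[p] += ee * s6 * s6;
              vb[p] += 2.0 * ee * s6;
            }
          }
          binv += hct_integral(rg, born_rho, hct_scale * 0.5 * rmin[i]);
        }
        elec[idx] = soft_cap(e, a_elec, s_width);
        for (int p = 0; p < np; ++p) {
          vdw_rep(idx, p) = rep_transform(va[p]);
          vdw_att(idx, p) = att_transform(vb[p]);
        }
        double inv_b = 1.0 / born_rho - binv;
        if (inv_b > 1.0 / born_rho) inv_b = 1.0 / born_rho;
        if (inv_b < 1e-6) inv_b = 1e-6;
        desolv[idx] = tau * (1.0 / born_rho - inv_b); // >= 0, per unit charge^2
      }
    }
  }
  return List::create(_["elec"] = elec, _["vdw_rep"] = vdw_rep,
                      _["vdw_att"] = vdw_att, _["desolv"] = desolv);
}

// Exact (ungridded) evaluation of the same capped fields at arbitrary points.
// Returns per-atom energies so callers can decompose.
// [[Rcpp::export]]
NumericVector cpp_direct_energy(NumericMatrix rxyz, NumericVector q,
                                NumericVector eps, NumericVector rmin,
                                NumericMatrix lxyz, NumericVector lq,
                                NumericVector leps, NumericVector lrmin,
                                double eps_in, double tau, double born_rho,
                                double hct_scale, double cap, double a_elec,
                                double a_vdw) {
  const int na = rxyz.nrow(), nl = lxyz.nrow();
  NumericVector out(nl);
  const double sw = cap - a_elec > 0 ? cap - a_elec : 1.0;
  const double swv = cap - a_vdw > 0 ? cap - a_vdw : 1.0;
  for (int j = 0; j < nl; ++j) {
    double e = 0.0, va = 0.0, vb = 0.0, binv = 0.0;
    for (int i = 0; i < na; ++i) {
      double dx = lxyz(j, 0) - rxyz(i, 0);
      double dy = lxyz(j, 1) - rxyz(i, 1);
      double dz = lxyz(j, 2) - rxyz(i, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double rg = r < 0.05 ? 0.05 : r;
      e += COULOMB_K * q[i] / (eps_in * rg);
      double rm = 0.5 * (rmin[i] + lrmin[j]);
      double ee = std::sqrt(eps[i] * leps[j]);
      if (ee > 0.0) {
        double s2 = (rm * rm) / (rg * rg);
        double s6 = s2 * s2 * s2;
        va += ee * s6 * s6;
        vb += 2.0 * ee * s6;
      }
      binv += hct_integral(rg, born_rho, hct_scale * 0.5 * rmin[i]);
    }
    double inv_b = 1.0 / born_rho - binv;
    if (inv_b > 1.0 / born_rho) inv_b = 1.0 / born_rho;
    if (inv_b < 1e-6) inv_b = 1e-6;
    double des = tau * (1.0 / born_rho - inv_b);
    out[j] = lq[j] * soft_cap(e, a_elec, sw) +
      vdw_reconstruct(rep_transform(va), att_transform(vb), a_vdw, swv) +
      lq[j] * lq[j] * des;
  }
  return out;
}

// Trilinear interpolation of the three maps for one conformation.
// vdw_col: 0-based probe-map column per ligand atom.
// [[Rcpp::export]]
NumericVector cpp_grid_energy(NumericVector elec, NumericMatrix vdw_rep,
                              NumericMatrix vdw_att,
                              NumericVector desolv, NumericVector origin,
                              double spacing, IntegerVector nn,
                              NumericMatrix lxyz, NumericVector lq,
                              IntegerVector vdw_col, double penalty,
                              double a_vdw, double cap) {
  const int nx = nn[0], ny = nn[1], nz = nn[2];
  const int nl = lxyz.nrow();
  const double swv = cap - a_vdw > 0 ? cap - a_vdw : 1.0;
  NumericVector out(nl);
  for (int j = 0; j < nl; ++j) {
    double fx = (lxyz(j, 0) - origin[0]) / spacing;
    double fy = (lxyz(j, 1) - origin[1]) / spacing;
    double fz = (lxyz(j, 2) - origin[2]) / spacing;
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      out[j] = penalty;
      continue;
    }
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
    if (ix > nx - 2) ix = nx - 2;
    if (iy > ny - 2) iy = ny - 2;
    if (iz > nz - 2) iz = nz - 2;
    double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    double e = 0.0, d = 0.0;
    int col = vdw_col[j];
    for (int c = 0; c < 8; ++c) {
      int ox = c & 1, oy = (c >> 1) & 1, oz = (c >> 2) & 1;
      double w = (ox ? tx : 1 - tx) * (oy ? ty : 1 - ty) * (oz ? tz : 1 - tz);
      R_xlen_t id = (R_xlen_t)(ix + ox) +
        (R_xlen_t)nx * ((iy + oy) + (R_xlen_t)ny * (iz + oz));
      e += w * elec[id];
      d += w * desolv[id];
    }
    double p, qv;
    vdw_tricubic(vdw_rep, vdw_att, col, fx, fy, fz, nx, ny, nz, &p, &qv);
    out[j] = lq[j] * e + vdw_reconstruct(p, qv, a_vdw, swv) +
      lq[j] * lq[j] * d;
  }
  return out;
}

static inline void quat_to_mat(const double *qv, double R[3][3]) {
  double w = qv[0], x = qv[1], y = qv[2], z = qv[3];
  double n = std::sqrt(w * w + x * x + y * y + z * z);
  if (n < 1e-300) { w = 1; x = y = z = 0; n = 1; }
  w /= n; x /= n; y /= n; z /= n;
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

// Decode a pose genome into Cartesian coordinates: torsion deltas about each
// rotatable bond (applied in listed order to the reference conformer), rigid
// rotation about the reference centroid, then translation of the centroid to
// centre + t.
static void decode_pose(const NumericMatrix &ref, const NumericVector &cen,
                        const IntegerMatrix &tq, const List &tmov,
                        const double *genome, int ntor,
                        std::vector<double> &X) {
  const int m = ref.nrow();
  X.resize(3 * m);
  for (int i = 0; i < m; ++i) {
    X[3 * i] = ref(i, 0); X[3 * i + 1] = ref(i, 1); X[3 * i + 2] = ref(i, 2);
  }
  for (int t = 0; t < ntor; ++t) {
    double ang = genome[7 + t];
    if (ang == 0.0) continue;
    int b = tq(t, 1), c = tq(t, 2); // 0-based
    double ax = X[3 * c] - X[3 * b], ay = X[3 * c + 1] - X[3 * b + 1],
           az = X[3 * c + 2] - X[3 * b + 2];
    double an = std::sqrt(ax * ax + ay * ay + az * az);
    if (an < 1e-12) continue;
    ax /= an; ay /= an; az /= an;
    double ca = std::cos(ang), sa = std::sin(ang);
    IntegerVector mov = tmov[t];
    for (int k = 0; k < mov.size(); ++k) {
      int i = mov[k];
      double px = X[3 * i] - X[3 * b], py = X[3 * i + 1] - X[3 * b + 1],
             pz = X[3 * i + 2] - X[3 * b + 2];
      double dot = ax * px + ay * py + az * pz;
      double cx = ay * pz - az * py, cy = az * px - ax * pz, cz = ax * py - ay * px;
      X[3 * i] = X[3 * b] + px * ca + cx * sa + ax * dot * (1 - ca);
      X[3 * i + 1] = X[3 * b + 1] + py * ca + cy * sa + ay * dot * (1 - ca);
      X[3 * i + 2] = X[3 * b + 2] + pz * ca + cz * sa + az * dot * (1 - ca);
    }
  }
  // centroid of the reference conformer (rigid frame anchor)
  double c0x = 0, c0y = 0, c0z = 0;
  for (int i = 0; i < m; ++i) { c0x += ref(i, 0); c0y += ref(i, 1); c0z += ref(i, 2); }
  c0x /= m; c0y /= m; c0z /= m;
  double R[3][3];
  quat_to_mat(genome + 3, R);
  for (int i = 0; i < m; ++i) {
    double px = X[3 * i] - c0x, py = X[3 * i + 1] - c0y, pz = X[3 * i + 2] - c0z;
    double nx = R[0][0] * px + R[0][1] * py + R[0][2] * pz;
    double ny = R[1][0] * px + R[1][1] * py + R[1][2] * pz;
    double nz = R[2][0] * px + R[2][1] * py + R[2][2] * pz;
    X[3 * i] = cen[0] + genome[0] + nx;
    X[3 * i + 1] = cen[1] + genome[1] + ny;
    X[3 * i + 2] = cen[2] + genome[2] + nz;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pose_coords(NumericMatrix ref, NumericVector cen,
                              IntegerMatrix tq, List tmov,
                              NumericVector genome) {
  int ntor = tq.nrow();
  std::vector<double> X;
  decode_pose(ref, cen, tq, tmov, REAL(genome), ntor, X);
  int m = ref.nrow();
  NumericMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = X[3 * i]; out(i, 1) = X[3 * i + 1]; out(i, 2) = X[3 * i + 2];
  }
  return out;
}

// Intra-ligand nonbonded energy (pairs separated by > 3 bonds), soft-capped.
static double intra_nb(const std::vector<double> &X, const IntegerMatrix &pairs,
                       const NumericVector &pqq, const NumericVector &peps,
                       const NumericVector &prmin, double eps_in,
                       double a_vdw, double sw) {
  double u = 0.0;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0), j = pairs(p, 1);
    double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1],
           dz = X[3 * i + 2] - X[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 0.0025) r2 = 0.0025;
    u += COULOMB_K * pqq[p] / (eps_in * std::sqrt(r2));
    u += soft_cap(lj_1210(r2, peps[p], prmin[p]), a_vdw, sw);
  }
  return u;
}

// [[Rcpp::export]]
double cpp_intra_nb_ref(NumericMatrix ref, IntegerMatrix pairs,
                        NumericVector pqq, NumericVector peps,
                        NumericVector prmin, double eps_in, double a_vdw,
                        double cap) {
  std::vector<double> X(3 * ref.nrow());
  for (int i = 0; i < ref.nrow(); ++i) {
    X[3 * i] = ref(i, 0); X[3 * i + 1] = ref(i, 1); X[3 * i + 2] = ref(i, 2);
  }
  double sw = cap - a_vdw > 0 ? cap - a_vdw : 1.0;
  return intra_nb(X, pairs, pqq, peps, prmin, eps_in, a_vdw, sw);
}

// Evaluate a population of pose genomes: grid interaction + internal strain.
// Returns a vector of objective values (kcal/mol).
// [[Rcpp::export]]
NumericVector cpp_eval_population(NumericVector elec, NumericMatrix vdw_rep,
                                  NumericMatrix vdw_att,
                                  NumericVector desolv, NumericVector origin,
                                  double spacing, IntegerVector nn,
                                  NumericMatrix ref, NumericVector cen,
                                  NumericVector lq, IntegerVector vdw_col,
                                  IntegerMatrix tq, List tmov,
                                  IntegerMatrix pairs, NumericVector pqq,
                                  NumericVector peps, NumericVector prmin,
                                  double kt, double u_ref, double eps_in,
                                  double a_vdw, double cap,
                                  NumericMatrix genomes, double penalty,
                                  bool interaction_only = false) {
  const int npop = genomes.nrow();
  const int m = ref.nrow();
  const int ntor = tq.nrow();
  const int nx = nn[0], ny = nn[1], nz = nn[2];
  const double sw = cap - a_vdw > 0 ? cap - a_vdw : 1.0;
  NumericVector out(npop);
  std::vector<double> X;
  std::vector<double> g(7 + ntor);
  for (int ind = 0; ind < npop; ++ind) {
    for (int k = 0; k < 7 + ntor; ++k) g[k] = genomes(ind, k);
    decode_pose(ref, cen, tq, tmov, g.data(), ntor, X);
    double e = 0.0;
    for (int j = 0; j < m; ++j) {
      double fx = (X[3 * j] - origin[0]) / spacing;
      double fy = (X[3 * j + 1] - origin[1]) / spacing;
      double fz = (X[3 * j + 2] - origin[2]) / spacing;
      if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
        e += penalty;
        continue;
      }
      int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
      if (ix > nx - 2) ix = nx - 2;
      if (iy > ny - 2) iy = ny - 2;
      if (iz > nz - 2) iz = nz - 2;
      double tx = fx - ix, ty = fy - iy, tz = fz - iz;
      double ee = 0.0, dd = 0.0;
      int col = vdw_col[j];
      for (int c = 0; c < 8; ++c) {
        int ox = c & 1, oy = (c >> 1) & 1, oz = (c >> 2) & 1;
        double w = (ox ? tx : 1 - tx) * (oy ? ty : 1 - ty) * (oz ? tz : 1 - tz);
        R_xlen_t id = (R_xlen_t)(ix + ox) +
          (R_xlen_t)nx * ((iy + oy) + (R_xlen_t)ny * (iz + oz));
        ee += w * elec[id];
        dd += w * desolv[id];
      }
      double pp, qq2;
      vdw_tricubic(vdw_rep, vdw_att, col, fx, fy, fz, nx, ny, nz, &pp, &qq2);
      e += lq[j] * ee + vdw_reconstruct(pp, qq2, a_vdw, sw) +
        lq[j] * lq[j] * dd;
    }
    if (!interaction_only && ntor > 0) {
      double tors = 0.0;
      for (int t = 0; t < ntor; ++t) tors += kt * (1.0 - std::cos(g[7 + t]));
      e += tors + intra_nb(X, pairs, pqq, peps, prmin, eps_in, a_vdw, sw) - u_ref;
    }
    out[ind] = e;
  }
  return out;
}

// Exhaustive lattice search: translations x orientations x torsion grid.
// Returns best (translation index, quaternion index, torsion index, energy).
// [[Rcpp::export]]
List cpp_brute_force(NumericVector elec, NumericMatrix vdw_rep,
                     NumericMatrix vdw_att,
                     NumericVector desolv, NumericVector origin,
                     double spacing, IntegerVector nn, NumericMatrix ref,
                     NumericVector cen, NumericVector lq,
                     IntegerVector vdw_col, IntegerMatrix tq, List tmov,
                     IntegerMatrix pairs, NumericVector pqq,
                     NumericVector peps, NumericVector prmin, double kt,
                     double u_ref, double eps_in, double a_vdw, double cap,
                     NumericMatrix trans, NumericMatrix quats,
                     NumericMatrix torgrid, double penalty, int n_keep = 1) {
  const int nt = trans.nrow(), nq = quats.nrow();
  const int ns = torgrid.nrow() > 0 ? torgrid.nrow() : 1;
  const int ntor = tq.nrow();
  if (n_keep < 1) n_keep = 1;
  std::vector<double> top_e(n_keep, R_PosInf);
  std::vector<int> top_t(n_keep, 0), top_q(n_keep, 0), top_s(n_keep, 0);
  NumericMatrix genome(1, 7 + ntor);
  for (int s = 0; s < ns; ++s) {
    for (int iq = 0; iq < nq; ++iq) {
      for (int it = 0; it < nt; ++it) {
        genome(0, 0) = trans(it, 0); genome(0, 1) = trans(it, 1);
        genome(0, 2) = trans(it, 2);
        for (int k = 0; k < 4; ++k) genome(0, 3 + k) = quats(iq, k);
        for (int t = 0; t < ntor; ++t)
          genome(0, 7 + t) = torgrid.nrow() > 0 ? torgrid(s, t) : 0.0;
        NumericVector e = cpp_eval_population(elec, vdw_rep, vdw_att, desolv,
                                              origin, spacing, nn, ref, cen,
                                              lq, vdw_col, tq, tmov, pairs,
                                              pqq, peps, prmin, kt, u_ref,
                                              eps_in, a_vdw, cap, genome,
                                              penalty, false);
        if (e[0] < top_e[n_keep - 1]) {
          int pos = n_keep - 1;
          while (pos > 0 && e[0] < top_e[pos - 1]) {
            top_e[pos] = top_e[pos - 1]; top_t[pos] = top_t[pos - 1];
            top_q[pos] = top_q[pos - 1]; top_s[pos] = top_s[pos - 1];
            --pos;
          }
          top_e[pos] = e[0]; top_t[pos] = it; top_q[pos] = iq; top_s[pos] = s;
        }
      }
    }
  }
  int found = 0;
  for (int k = 0; k < n_keep; ++k) if (R_finite(top_e[k])) ++found;
  IntegerVector i_t(found), i_q(found), i_s(found);
  NumericVector ee(found);
  for (int k = 0; k < found; ++k) {
    i_t[k] = top_t[k] + 1; i_q[k] = top_q[k] + 1; i_s[k] = top_s[k] + 1;
    ee[k] = top_e[k];
  }
  return List::create(_["i_trans"] = i_t, _["i_quat"] = i_q,
                      _["i_tor"] = i_s, _["energy"] = ee);
}
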