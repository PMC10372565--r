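// Monte Carlo engine for deformable self-propelled ellipses on a ridged
// periodic substrate. All randomness is drawn from R's global RNG stream
// (unif_rand), so trajectories are reproducible from set.seed().
//
// Draw order per MCS (documented contract, mirrored by run_mcs_reference):
//   1. Fisher-Yates permutation of cells: N-1 draws, j = floor(U*(i+1)),
//      i = N-1 .. 1.
//   2. Per cell in permuted order: 1 draw for the move kind, then
//      displacement: 2 draws (magnitude, direction); rotation/resize: 1 draw;
//      then always exactly 1 acceptance draw (consumed even when the proposal
//      is auto-rejected for violating a >= b > 0 or when dE <= 0).
//   3. Polarity update per cell in index order (no draws).
//   4. At flip-period boundaries: 1 draw per cell in index order.
//   5. At division boundaries in the growth phase: 1 draw to select the
//      dividing cell.
//
// Neighbor bookkeeping: per-cell candidate lists hold all cells within a
// circle of radius rc_maj + halo. Lists are rebuilt on every division and as
// soon as any cell has accumulated more displacement than the rebuild
// trigger, which is chosen so that no pair can enter the exact elliptical
// cutoff without already being on the list (the exact cutoff is re-applied
// at every energy evaluation, so list rebuild timing never changes the
// trajectory, only the speed).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// general minimum image (any displacement)
static inline double mimg(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

// fast minimum image, valid for |d| < 1.5 L (differences of in-box coords)
static inline double mimg_f(double d, double L, double hl) {
  if (d >= hl) return d - L;
  if (d < -hl) return d + L;
  return d;
}

// fast wrap into [0, L), valid for x in (-L, 2L)
static inline double wrap_f(double x, double L) {
  if (x >= L) return x - L;
  if (x < 0.0) return x + L;
  return x;
}

struct Params {
  double T, delta_r, delta_phi, delta_a, delta_b;
  double A_pref, AR_pref, kA, kAR, k_core;
  double eps0, rc_maj, rc_min, mu, nu;
  double k_move, tau_pol, flip_prob;
  int flip_period;
  double L, skin;
  double p_disp, p_rot, p_resa; // cumulative move-mix thresholds
  double alpha, daughter_factor;
  int relax_mcs, division_period, terminal_count;
  bool uniform_division;
  bool polarity_proposed;
  int n_feeler_rings, n_feeler_points;
};

struct Pattern {
  double cx, cy, spacing, width, k_r;
  int nrings;
  std::vector<double> lo2, hi2; // squared band edges per ring (1-based idx 0)
  void make_bands() {
    lo2.resize(nrings); hi2.resize(nrings);
    for (int k = 1; k <= nrings; ++k) {
      double lo = k * spacing - 0.5 * width;
      double hi = k * spacing + 0.5 * width;
      if (lo < 0) lo = 0;
      lo2[k - 1] = lo * lo;
      hi2[k - 1] = hi * hi;
    }
  }
};

// quartic shape-deviation penalty k * (d^2 - d^3/3 + 4 d^4)
static inline double quartic_pen(double d, double k) {
  double d2 = d * d;
  return k * (d2 - d2 * d / 3.0 + 4.0 * d2 * d2);
}

static inline double shape_en(double a, double b, const Params& P) {
  double dA = (M_PI * a * b - P.A_pref) / P.A_pref;
  double dR = (a / b - P.AR_pref) / P.AR_pref;
  return quartic_pen(dA, P.kA) + quartic_pen(dR, P.kAR);
}

static inline double core_en(double a, double b, double k_core) {
  double a2 = a * a, b2 = b * b;
  return k_core * (1.0 / (a2 * a2) + 1.0 / (b2 * b2));
}

// fraction of feeler points overlapping ridge annuli (minimum-image
// distances); band membership is tested on squared distances
static double ridge_frac(double x, double y, double a, double b,
                         double cphi, double sphi, const Pattern& R, double L,
                         const std::vector<double>& ct,
                         const std::vector<double>& st,
                         const std::vector<double>& scales) {
  if (R.nrings <= 0) return 0.0;
  double hl = 0.5 * L;
  double dx0 = mimg_f(x - R.cx, L, hl), dy0 = mimg_f(y - R.cy, L, hl);
  double rc = std::sqrt(dx0 * dx0 + dy0 * dy0);
  // all feeler points lie within distance a of the cell centre, and the
  // minimum-image distance is 1-Lipschitz, so ring k can only be touched if
  // k*spacing lies in [rc - a - w/2, rc + a + w/2]
  double hw = 0.5 * R.width;
  int klo = (int)std::ceil((rc - a - hw) / R.spacing);
  int khi = (int)((rc + a + hw) / R.spacing); // floor for non-negative arg
  if (klo < 1) klo = 1;
  if (khi > R.nrings) khi = R.nrings;
  if (klo > khi) return 0.0;

  int npts = (int)ct.size();
  int nsc = (int)scales.size();
  int n_on = 0;
  for (int s = 0; s < nsc; ++s) {
    double sa = scales[s] * a, sb = scales[s] * b;
    for (int k = 0; k < npts; ++k) {
      double ex = sa * ct[k], ey = sb * st[k];
      double px = x + ex * cphi - ey * sphi;
      double py = y + ex * sphi + ey * cphi;
      // px,py within (-a, L+a): one wrap step is enough
      double ddx = mimg_f(px - R.cx, L, hl), ddy = mimg_f(py - R.cy, L, hl);
      double d2 = ddx * ddx + ddy * ddy;
      for (int kk = klo; kk <= khi; ++kk) {
        if (d2 < R.lo2[kk - 1]) break; // bands sorted ascending
        if (d2 <= R.hi2[kk - 1]) { ++n_on; break; }
      }
    }
  }
  return (double)n_on / (double)(npts * nsc);
}

// Gay-Berne pair energy from per-cell geometric caches; rn = |r12|,
// (dx,dy) the minimum-image separation, c = u1.u2
static inline double gb_pair_core(double dx, double dy, double rn, double c,
                                  double l21, double d21, double gxx1,
                                  double gxy1, double gyy1, double l22,
                                  double d22, double gxx2, double gxy2,
                                  double gyy2, double eps0, double mu,
                                  double nu) {
  double r2 = rn * rn;
  if (r2 < 1e-12) { dx = 1e-6; dy = 0.0; r2 = 1e-12; rn = 1e-6; }
  double gxx = gxx1 + gxx2, gxy = gxy1 + gxy2, gyy = gyy1 + gyy2;
  double det = gxx * gyy - gxy * gxy;
  double q = (gyy * dx * dx - 2.0 * gxy * dx * dy + gxx * dy * dy) / (det * r2);
  double sigma = 1.0 / std::sqrt(q);
  double s02 = d21 + d22; // sigma0^2 = 2 b1^2 + 2 b2^2
  double s0 = std::sqrt(s02);
  double chi2 = ((l21 - d21) * (l22 - d22)) / ((l21 + d21) * (l22 + d22));
  double ea = 1.0 / std::sqrt(1.0 - chi2 * c * c);
  double eb = s02 * q; // (sigma0/sigma)^2
  double eps = (mu == 1.0 && nu == 1.0)
                 ? eps0 * ea * eb
                 : eps0 * std::pow(ea, nu) * std::pow(eb, mu);
  double rs = (rn - sigma + s0) / s0;
  if (rs < 1e-3) rs = 1e-3;
  double u = 1.0 / rs, u2 = u * u, u6 = u2 * u2 * u2;
  return 4.0 * eps * (u6 * u6 - u6);
}

static inline double gb_pair(double dx, double dy, double ux1, double uy1,
                             double l21, double d21, double gxx1, double gxy1,
                             double gyy1, double ux2, double uy2, double l22,
                             double d22, double gxx2, double gxy2,
                             double gyy2, double eps0, double mu, double nu) {
  double rn = std::sqrt(dx * dx + dy * dy);
  double c = ux1 * ux2 + uy1 * uy2;
  return gb_pair_core(dx, dy, rn, c, l21, d21, gxx1, gxy1, gyy1, l22, d22,
                      gxx2, gxy2, gyy2, eps0, mu, nu);
}

struct Sys {
  std::vector<double> x, y, a, b, phi, px, py;
  std::vector<int> id, parent;
  // geometric caches
  std::vector<double> ux, uy, l2, d2, gxx, gxy, gyy;
  std::vector<double> e_geom, e_ridge; // cached single-cell energies
  std::vector<double> accum;           // displacement since last nb rebuild
  std::vector<std::vector<int>> nb;    // halo (circular) candidate lists

  int n() const { return (int)x.size(); }

  void set_cache(int i) {
    ux[i] = std::cos(phi[i]);
    uy[i] = std::sin(phi[i]);
    l2[i] = 2.0 * a[i] * a[i];
    d2[i] = 2.0 * b[i] * b[i];
    double diff = l2[i] - d2[i];
    gxx[i] = diff * ux[i] * ux[i] + d2[i];
    gxy[i] = diff * ux[i] * uy[i];
    gyy[i] = diff * uy[i] * uy[i] + d2[i];
  }
};

static const double NB_HALO = 12.0; // um of candidate-list padding

static void rebuild_nb(Sys& S, const Params& P) {
  int n = S.n();
  double rpad = P.rc_maj + NB_HALO;
  double rpad2 = rpad * rpad;
  double hl = 0.5 * P.L;
  S.nb.assign(n, std::vector<int>());
  for (int i = 0; i < n; ++i) {
    double xi = S.x[i], yi = S.y[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg_f(S.x[j] - xi, P.L, hl);
      double dy = mimg_f(S.y[j] - yi, P.L, hl);
      if (dx * dx + dy * dy <= rpad2) {
        S.nb[i].push_back(j);
        S.nb[j].push_back(i);
      }
    }
  }
  std::fill(S.accum.begin(), S.accum.end(), 0.0);
}

// dE of the pair terms for a displacement of cell c by (ddx, ddy):
// single scan of the candidate list, separate old/new accumulators
static double pair_dE_move(const Sys& S, int c, double nx, double ny,
                           const Params& P) {
  double Eold = 0.0, Enew = 0.0;
  double rm2 = P.rc_maj * P.rc_maj;
  double irm2 = 1.0 / rm2, irn2 = 1.0 / (P.rc_min * P.rc_min);
  double hl = 0.5 * P.L;
  double xc = S.x[c], yc = S.y[c];
  double ux = S.ux[c], uy = S.uy[c];
  const std::vector<int>& lst = S.nb[c];
  for (size_t k = 0; k < lst.size(); ++k) {
    int j = lst[k];
    double dxo = mimg_f(S.x[j] - xc, P.L, hl);
    double dyo = mimg_f(S.y[j] - yc, P.L, hl);
    double r2o = dxo * dxo + dyo * dyo;
    if (r2o <= rm2) {
      double proj = dxo * ux + dyo * uy, perp = dyo * ux - dxo * uy;
      if (proj * proj * irm2 + perp * perp * irn2 <= 1.0)
        Eold += gb_pair(dxo, dyo, ux, uy, S.l2[c], S.d2[c], S.gxx[c],
                        S.gxy[c], S.gyy[c], S.ux[j], S.uy[j], S.l2[j],
                        S.d2[j], S.gxx[j], S.gxy[j], S.gyy[j], P.eps0, P.mu,
                        P.nu);
    }
    double dxn = mimg_f(S.x[j] - nx, P.L, hl);
    double dyn = mimg_f(S.y[j] - ny, P.L, hl);
    double r2n = dxn * dxn + dyn * dyn;
    if (r2n <= rm2) {
      double proj = dxn * ux + dyn * uy, perp = dyn * ux - dxn * uy;
      if (proj * proj * irm2 + perp * perp * irn2 <= 1.0)
        Enew += gb_pair(dxn, dyn, ux, uy, S.l2[c], S.d2[c], S.gxx[c],
                        S.gxy[c], S.gyy[c], S.ux[j], S.uy[j], S.l2[j],
                        S.d2[j], S.gxx[j], S.gxy[j], S.gyy[j], P.eps0, P.mu,
                        P.nu);
    }
  }
  return Enew - Eold;
}

// dE of the pair terms for a rotation of cell c (same centre, new axes)
static double pair_dE_rot(const Sys& S, int c, double nux, double nuy,
                          double ngxx, double ngxy, double ngyy,
                          const Params& P) {
  double Eold = 0.0, Enew = 0.0;
  double rm2 = P.rc_maj * P.rc_maj;
  double irm2 = 1.0 / rm2, irn2 = 1.0 / (P.rc_min * P.rc_min);
  double hl = 0.5 * P.L;
  double xc = S.x[c], yc = S.y[c];
  double oux = S.ux[c], ouy = S.uy[c];
  const std::vector<int>& lst = S.nb[c];
  for (size_t k = 0; k < lst.size(); ++k) {
    int j = lst[k];
    double dx = mimg_f(S.x[j] - xc, P.L, hl);
    double dy = mimg_f(S.y[j] - yc, P.L, hl);
    double r2 = dx * dx + dy * dy;
    if (r2 > rm2) continue;
    double rn = std::sqrt(r2);
    double po = dx * oux + dy * ouy, qo = dy * oux - dx * ouy;
    if (po * po * irm2 + qo * qo * irn2 <= 1.0) {
      double cc = oux * S.ux[j] + ouy * S.uy[j];
      Eold += gb_pair_core(dx, dy, rn, cc, S.l2[c], S.d2[c], S.gxx[c],
                           S.gxy[c], S.gyy[c], S.l2[j], S.d2[j], S.gxx[j],
                           S.gxy[j], S.gyy[j], P.eps0, P.mu, P.nu);
    }
    double pn = dx * nux + dy * nuy, qn = dy * nux - dx * nuy;
    if (pn * pn * irm2 + qn * qn * irn2 <= 1.0) {
      double cc = nux * S.ux[j] + nuy * S.uy[j];
      Enew += gb_pair_core(dx, dy, rn, cc, S.l2[c], S.d2[c], ngxx, ngxy,
                           ngyy, S.l2[j], S.d2[j], S.gxx[j], S.gxy[j],
                           S.gyy[j], P.eps0, P.mu, P.nu);
    }
  }
  return Enew - Eold;
}

// dE of the pair terms for an axis resize of cell c (same centre and
// orientation, so the cutoff set is unchanged)
static double pair_dE_resize(const Sys& S, int c, double nl2, double nd2,
                             double ngxx, double ngxy, double ngyy,
                             const Params& P) {
  double Eold = 0.0, Enew = 0.0;
  double rm2 = P.rc_maj * P.rc_maj;
  double irm2 = 1.0 / rm2, irn2 = 1.0 / (P.rc_min * P.rc_min);
  double hl = 0.5 * P.L;
  double xc = S.x[c], yc = S.y[c];
  double ux = S.ux[c], uy = S.uy[c];
  const std::vector<int>& lst = S.nb[c];
  for (size_t k = 0; k < lst.size(); ++k) {
    int j = lst[k];
    double dx = mimg_f(S.x[j] - xc, P.L, hl);
    double dy = mimg_f(S.y[j] - yc, P.L, hl);
    double r2 = dx * dx + dy * dy;
    if (r2 > rm2) continue;
    double proj = dx * ux + dy * uy, perp = dy * ux - dx * uy;
    if (proj * proj * irm2 + perp * perp * irn2 > 1.0) continue;
    double rn = std::sqrt(r2);
    double cc = ux * S.ux[j] + uy * S.uy[j];
    Eold += gb_pair_core(dx, dy, rn, cc, S.l2[c], S.d2[c], S.gxx[c],
                         S.gxy[c], S.gyy[c], S.l2[j], S.d2[j], S.gxx[j],
                         S.gxy[j], S.gyy[j], P.eps0, P.mu, P.nu);
    Enew += gb_pair_core(dx, dy, rn, cc, nl2, nd2, ngxx, ngxy, ngyy,
                         S.l2[j], S.d2[j], S.gxx[j], S.gxy[j], S.gyy[j],
                         P.eps0, P.mu, P.nu);
  }
  return Enew - Eold;
}

// ------------------------------------------------------------------ exports

//' @noRd
// [[Rcpp::export]]
double cpp_shape_energy(double a, double b, double A_pref, double AR_pref,
                        double kA, double kAR) {
  Params P; P.A_pref = A_pref; P.AR_pref = AR_pref; P.kA = kA; P.kAR = kAR;
  return shape_en(a, b, P);
}

//' @noRd
// [[Rcpp::export]]
double cpp_core_energy(double a, double b, double k_core) {
  return core_en(a, b, k_core);
}

//' @noRd
// [[Rcpp::export]]
double cpp_ridge_overlap(double x, double y, double a, double b, double phi,
                         double cx, double cy, double spacing, double width,
                         int nrings, double L, int npts,
                         NumericVector scales) {
  Pattern R; R.cx = cx; R.cy = cy; R.spacing = spacing; R.width = width;
  R.nrings = nrings; R.k_r = 0.0;
  R.make_bands();
  std::vector<double> ct(npts), st(npts), sc(scales.begin(), scales.end());
  for (int k = 0; k < npts; ++k) {
    double t = 2.0 * M_PI * k / npts;
    ct[k] = std::cos(t); st[k] = std::sin(t);
  }
  // wrap into the primary box so the fast minimum image applies
  return ridge_frac(x - L * std::floor(x / L), y - L * std::floor(y / L),
                    a, b, std::cos(phi), std::sin(phi), R, L, ct, st, sc);
}

// rows of c1/c2: x, y, a, b, phi
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_pair_energy(NumericMatrix c1, NumericMatrix c2, double L,
                              double eps0, double mu, double nu) {
  int n = c1.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a1 = c1(i, 2), b1 = c1(i, 3), p1 = c1(i, 4);
    double a2 = c2(i, 2), b2 = c2(i, 3), p2 = c2(i, 4);
    double ux1 = std::cos(p1), uy1 = std::sin(p1);
    double ux2 = std::cos(p2), uy2 = std::sin(p2);
    double l21 = 2 * a1 * a1, d21 = 2 * b1 * b1;
    double l22 = 2 * a2 * a2, d22 = 2 * b2 * b2;
    double f1 = l21 - d21, f2 = l22 - d22;
    double dx = mimg(c1(i, 0) - c2(i, 0), L), dy = mimg(c1(i, 1) - c2(i, 1), L);
    out[i] = gb_pair(dx, dy,
                     ux1, uy1, l21, d21,
                     f1 * ux1 * ux1 + d21, f1 * ux1 * uy1, f1 * uy1 * uy1 + d21,
                     ux2, uy2, l22, d22,
                     f2 * ux2 * ux2 + d22, f2 * ux2 * uy2, f2 * uy2 * uy2 + d22,
                     eps0, mu, nu);
  }
  return out;
}

// is each cj-centre inside the elliptical cutoff around the matching ci?
//' @noRd
// [[Rcpp::export]]
LogicalVector cpp_in_cutoff(NumericMatrix ci, NumericMatrix cj, double L,
                            double rc_maj, double rc_min) {
  int n = ci.nrow();
  LogicalVector out(n);
  double irm2 = 1.0 / (rc_maj * rc_maj), irn2 = 1.0 / (rc_min * rc_min);
  for (int i = 0; i < n; ++i) {
    double ux = std::cos(ci(i, 4)), uy = std::sin(ci(i, 4));
    double dx = mimg(cj(i, 0) - ci(i, 0), L), dy = mimg(cj(i, 1) - ci(i, 1), L);
    double proj = dx * ux + dy * uy, perp = dy * ux - dx * uy;
    out[i] = proj * proj * irm2 + perp * perp * irn2 <= 1.0;
  }
  return out;
}

// exact asymmetric elliptical-cutoff neighbor lists (1-based indices)
//' @noRd
// [[Rcpp::export]]
List cpp_exact_neighbors(NumericMatrix cells, double L, double rc_maj,
                         double rc_min) {
  int n = cells.nrow();
  double irm2 = 1.0 / (rc_maj * rc_maj), irn2 = 1.0 / (rc_min * rc_min);
  List out(n);
  for (int i = 0; i < n; ++i) {
    double ux = std::cos(cells(i, 4)), uy = std::sin(cells(i, 4));
    std::vector<int> lst;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = mimg(cells(j, 0) - cells(i, 0), L);
      double dy = mimg(cells(j, 1) - cells(i, 1), L);
      double proj = dx * ux + dy * uy, perp = dy * ux - dx * uy;
      if (proj * proj * irm2 + perp * perp * irn2 <= 1.0)
        lst.push_back(j + 1);
    }
    out[i] = IntegerVector(lst.begin(), lst.end());
  }
  return out;
}

static Params parse_params(List par) {
  Params P;
  P.T = as<double>(par["T"]);
  P.delta_r = as<double>(par["delta_r"]);
  P.delta_phi = as<double>(par["delta_phi"]);
  P.delta_a = as<double>(par["delta_a"]);
  P.delta_b = as<double>(par["delta_b"]);
  P.A_pref = as<double>(par["A_pref"]);
  P.AR_pref = as<double>(par["AR_pref"]);
  P.kA = as<double>(par["k_A"]);
  P.kAR = as<double>(par["k_AR"]);
  P.k_core = as<double>(par["k_core"]);
  P.eps0 = as<double>(par["eps0"]);
  P.rc_maj = as<double>(par["rc_maj"]);
  P.rc_min = as<double>(par["rc_min"]);
  P.mu = as<double>(par["mu"]);
  P.nu = as<double>(par["nu"]);
  P.k_move = as<double>(par["k_move"]);
  P.tau_pol = as<double>(par["tau_pol"]);
  P.flip_prob = as<double>(par["tau_flip_prob"]);
  P.flip_period = as<int>(par["flip_period"]);
  P.L = as<double>(par["L"]);
  P.skin = as<double>(par["skin"]);
  NumericVector mm = par["move_mix"];
  P.p_disp = mm[0];
  P.p_rot = mm[0] + mm[1];
  P.p_resa = mm[0] + mm[1] + mm[2];
  P.alpha = as<double>(par["alpha"]);
  P.daughter_factor = as<double>(par["daughter_factor"]);
  P.relax_mcs = as<int>(par["relax_mcs"]);
  P.division_period = as<int>(par["division_period"]);
  P.terminal_count = as<int>(par["terminal_count"]);
  P.uniform_division =
      as<std::string>(par["division_mode"]) == "uniform_random";
  P.polarity_proposed =
      as<std::string>(par["polarity_update"]) == "proposed";
  P.n_feeler_rings = as<int>(par["n_feeler_rings"]);
  P.n_feeler_points = as<int>(par["n_feeler_points"]);
  return P;
}

static Pattern parse_pattern(List pat) {
  Pattern R;
  if (pat.size() == 0) { R.nrings = 0; R.k_r = 0; R.cx = R.cy = 0;
    R.spacing = 1; R.width = 0; return R; }
  NumericVector ctr = pat["center"];
  R.cx = ctr[0]; R.cy = ctr[1];
  R.spacing = as<double>(pat["spacing"]);
  R.width = as<double>(pat["width"]);
  R.k_r = as<double>(pat["k_r"]);
  R.nrings = as<int>(pat["n_rings"]);
  R.make_bands();
  return R;
}

// cells matrix columns: id, parent_id, x, y, a, b, phi, px, py
//' @noRd
// [[Rcpp::export]]
List cpp_run(NumericMatrix cells_in, int mcs0, int next_id0, List params,
             List pattern, int n_mcs, IntegerVector snapshot_at) {
  Params P = parse_params(params);
  Pattern R = parse_pattern(pattern);

  Sys S;
  int n0 = cells_in.nrow();
  int reserve = std::max(P.terminal_count + 2, n0 + 2);
  auto rsv = [&](std::vector<double>& v) { v.reserve(reserve); };
  rsv(S.x); rsv(S.y); rsv(S.a); rsv(S.b); rsv(S.phi); rsv(S.px); rsv(S.py);
  rsv(S.ux); rsv(S.uy); rsv(S.l2); rsv(S.d2);
  rsv(S.gxx); rsv(S.gxy); rsv(S.gyy);
  rsv(S.e_geom); rsv(S.e_ridge); rsv(S.accum);

  for (int i = 0; i < n0; ++i) {
    S.id.push_back((int)cells_in(i, 0));
    S.parent.push_back((int)cells_in(i, 1));
    S.x.push_back(cells_in(i, 2) - P.L * std::floor(cells_in(i, 2) / P.L));
    S.y.push_back(cells_in(i, 3) - P.L * std::floor(cells_in(i, 3) / P.L));
    S.a.push_back(cells_in(i, 4));
    S.b.push_back(cells_in(i, 5));
    S.phi.push_back(cells_in(i, 6));
    S.px.push_back(cells_in(i, 7));
    S.py.push_back(cells_in(i, 8));
  }
  int n = n0;
  S.ux.resize(n); S.uy.resize(n); S.l2.resize(n); S.d2.resize(n);
  S.gxx.resize(n); S.gxy.resize(n); S.gyy.resize(n);
  S.e_geom.resize(n); S.e_ridge.resize(n); S.accum.assign(n, 0.0);

  // feeler tables
  int npts = P.n_feeler_points;
  std::vector<double> ct(npts), st(npts), scales(P.n_feeler_rings);
  for (int k = 0; k < npts; ++k) {
    double t = 2.0 * M_PI * k / npts;
    ct[k] = std::cos(t); st[k] = std::sin(t);
  }
  for (int s = 0; s < P.n_feeler_rings; ++s)
    scales[s] = (double)(P.n_feeler_rings - s) / P.n_feeler_rings;

  auto ridge_en = [&](double x, double y, double a, double b, double cphi,
                      double sphi) {
    if (R.nrings <= 0 || R.k_r == 0.0) return 0.0;
    return R.k_r * ridge_frac(x, y, a, b, cphi, sphi, R, P.L, ct, st, scales);
  };

  for (int i = 0; i < n; ++i) {
    S.set_cache(i);
    S.e_geom[i] = shape_en(S.a[i], S.b[i], P) + core_en(S.a[i], S.b[i], P.k_core);
    S.e_ridge[i] = ridge_en(S.x[i], S.y[i], S.a[i], S.b[i], S.ux[i], S.uy[i]);
  }
  rebuild_nb(S, P);
  // candidate lists stay valid while 2*(max accum + delta_r) <= halo; the
  // published 25 um rule is an outer bound on top of this
  double rebuild_trigger = std::min(P.skin, 0.5 * NB_HALO - P.delta_r);

  int next_id = next_id0;
  std::vector<int> perm;
  std::vector<double> drx, dry; // polarity-feedback displacement this MCS

  // logs
  std::vector<double> acclog;            // g, N, prop[4], acc[4], mean|p|
  long prop_ct[4] = {0, 0, 0, 0}, acc_ct[4] = {0, 0, 0, 0};
  std::vector<double> divlog;            // g, parent, d1, d2, A, AR
  List frames;
  std::vector<std::string> frame_names;
  int snap_ptr = 0;
  int nsnap = snapshot_at.size();

  auto take_frame = [&](int g) {
    int nn = S.n();
    NumericMatrix fr(nn, 9);
    for (int i = 0; i < nn; ++i) {
      fr(i, 0) = S.id[i]; fr(i, 1) = S.parent[i];
      fr(i, 2) = S.x[i]; fr(i, 3) = S.y[i];
      fr(i, 4) = S.a[i]; fr(i, 5) = S.b[i]; fr(i, 6) = S.phi[i];
      fr(i, 7) = S.px[i]; fr(i, 8) = S.py[i];
    }
    fr.attr("mcs") = g;
    frames.push_back(fr);
    frame_names.push_back(std::to_string(g));
  };

  double tau_fac = 1.0 - 1.0 / P.tau_pol;

  for (int step = 1; step <= n_mcs; ++step) {
    int g = mcs0 + step;
    n = S.n();

    // 1. permutation
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i >= 1; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }

    drx.assign(n, 0.0);
    dry.assign(n, 0.0);

    // 2. moves
    for (int k = 0; k < n; ++k) {
      int c = perm[k];
      double u1 = unif_rand();
      int kind = (u1 < P.p_disp) ? 0 : (u1 < P.p_rot) ? 1
                 : (u1 < P.p_resa) ? 2 : 3;
      ++prop_ct[kind];

      if (kind == 0) { // displacement
        double X = unif_rand(), Y = unif_rand();
        double psi = 2.0 * M_PI * Y;
        double dx = P.delta_r * X * std::cos(psi);
        double dy = P.delta_r * X * std::sin(psi);
        double nx = wrap_f(S.x[c] + dx, P.L), ny = wrap_f(S.y[c] + dy, P.L);
        double er_new = ridge_en(nx, ny, S.a[c], S.b[c], S.ux[c], S.uy[c]);
        double dE = (er_new - S.e_ridge[c]) + pair_dE_move(S, c, nx, ny, P);
        double up = S.ux[c] * S.px[c] + S.uy[c] * S.py[c];
        if (up != 0.0 && P.k_move != 0.0) {
          double sgn = (up > 0.0) ? 1.0 : -1.0;
          dE -= P.k_move * sgn * (S.ux[c] * dx + S.uy[c] * dy);
        }
        double ua = unif_rand();
        if (dE <= 0.0 || ua < std::exp(-dE / P.T)) {
          S.x[c] = nx; S.y[c] = ny;
          S.e_ridge[c] = er_new;
          drx[c] = dx; dry[c] = dy;
          S.accum[c] += std::sqrt(dx * dx + dy * dy);
          ++acc_ct[0];
          if (S.accum[c] > rebuild_trigger) rebuild_nb(S, P);
        } else if (P.polarity_proposed) {
          drx[c] = dx; dry[c] = dy;
        }
      } else if (kind == 1) { // rotation
        double X = unif_rand();
        double dphi = 2.0 * P.delta_phi * (X - 0.5);
        double nphi = S.phi[c] + dphi;
        double nux = std::cos(nphi), nuy = std::sin(nphi);
        double diff = S.l2[c] - S.d2[c];
        double ngxx = diff * nux * nux + S.d2[c];
        double ngxy = diff * nux * nuy;
        double ngyy = diff * nuy * nuy + S.d2[c];
        double er_new = ridge_en(S.x[c], S.y[c], S.a[c], S.b[c], nux, nuy);
        double dE = (er_new - S.e_ridge[c]) +
                    pair_dE_rot(S, c, nux, nuy, ngxx, ngxy, ngyy, P);
        double ua = unif_rand();
        if (dE <= 0.0 || ua < std::exp(-dE / P.T)) {
          S.phi[c] = nphi;
          S.ux[c] = nux; S.uy[c] = nuy;
          S.gxx[c] = ngxx; S.gxy[c] = ngxy; S.gyy[c] = ngyy;
          S.e_ridge[c] = er_new;
          // polarity co-rotates with the cell body
          double cp = std::cos(dphi), sp = std::sin(dphi);
          double npx = cp * S.px[c] - sp * S.py[c];
          double npy = sp * S.px[c] + cp * S.py[c];
          S.px[c] = npx; S.py[c] = npy;
          ++acc_ct[1];
        }
      } else { // axis resize
        double X = unif_rand();
        double na = S.a[c], nb_ = S.b[c];
        if (kind == 2) na += P.delta_a * (X - 0.5);
        else nb_ += P.delta_b * (X - 0.5);
        double ua = unif_rand(); // always consumed
        if (na < nb_ || nb_ <= 0.0) continue; // invalid: auto-reject
        double nl2 = 2.0 * na * na, nd2 = 2.0 * nb_ * nb_;
        double diff = nl2 - nd2;
        double ngxx = diff * S.ux[c] * S.ux[c] + nd2;
        double ngxy = diff * S.ux[c] * S.uy[c];
        double ngyy = diff * S.uy[c] * S.uy[c] + nd2;
        double eg_new = shape_en(na, nb_, P) + core_en(na, nb_, P.k_core);
        double er_new = ridge_en(S.x[c], S.y[c], na, nb_, S.ux[c], S.uy[c]);
        double dE = (eg_new - S.e_geom[c]) + (er_new - S.e_ridge[c]) +
                    pair_dE_resize(S, c, nl2, nd2, ngxx, ngxy, ngyy, P);
        if (dE <= 0.0 || ua < std::exp(-dE / P.T)) {
          S.a[c] = na; S.b[c] = nb_;
          S.l2[c] = nl2; S.d2[c] = nd2;
          S.gxx[c] = ngxx; S.gxy[c] = ngxy; S.gyy[c] = ngyy;
          S.e_geom[c] = eg_new; S.e_ridge[c] = er_new;
          ++acc_ct[kind];
        }
      }
    }

    // 3. polarity feedback
    for (int c = 0; c < n; ++c) {
      S.px[c] = tau_fac * S.px[c] + drx[c];
      S.py[c] = tau_fac * S.py[c] + dry[c];
    }

    // 4. stochastic polarity reversals
    if (P.flip_period > 0 && g % P.flip_period == 0) {
      for (int c = 0; c < n; ++c) {
        if (unif_rand() < P.flip_prob) { S.px[c] = -S.px[c]; S.py[c] = -S.py[c]; }
      }
    }

    // 5. division
    if (P.division_period > 0 && g % P.division_period == 0 &&
        g >= P.relax_mcs && S.n() < P.terminal_count) {
      int idx;
      double u = unif_rand();
      if (P.uniform_division) {
        idx = (int)(u * n);
        if (idx >= n) idx = n - 1;
      } else {
        double m = -1e300;
        std::vector<double> ex(n);
        for (int i = 0; i < n; ++i) {
          ex[i] = M_PI * S.a[i] * S.b[i] / P.A_pref -
                  P.alpha * (S.a[i] / S.b[i]) / P.AR_pref;
          if (ex[i] > m) m = ex[i];
        }
        double W = 0.0;
        for (int i = 0; i < n; ++i) { ex[i] = std::exp(ex[i] - m); W += ex[i]; }
        double target = u * W, cum = 0.0;
        idx = n - 1;
        for (int i = 0; i < n; ++i) {
          cum += ex[i];
          if (cum >= target) { idx = i; break; }
        }
      }
      double pa = S.a[idx], pb = S.b[idx], pphi = S.phi[idx];
      double pux = S.ux[idx], puy = S.uy[idx];
      double off = P.daughter_factor * pa;
      double cx0 = S.x[idx], cy0 = S.y[idx];
      int pid = S.id[idx];
      double A_par = M_PI * pa * pb, AR_par = pa / pb;
      // daughter 1 replaces the parent slot
      S.x[idx] = wrap_f(cx0 + off * pux, P.L);
      S.y[idx] = wrap_f(cy0 + off * puy, P.L);
      S.a[idx] = P.daughter_factor * pa;
      S.b[idx] = P.daughter_factor * pb;
      S.parent[idx] = pid;
      S.id[idx] = next_id++;
      S.set_cache(idx);
      S.e_geom[idx] = shape_en(S.a[idx], S.b[idx], P) +
                      core_en(S.a[idx], S.b[idx], P.k_core);
      S.e_ridge[idx] = ridge_en(S.x[idx], S.y[idx], S.a[idx], S.b[idx],
                                S.ux[idx], S.uy[idx]);
      // daughter 2 appended
      S.x.push_back(wrap_f(cx0 - off * pux, P.L));
      S.y.push_back(wrap_f(cy0 - off * puy, P.L));
      S.a.push_back(P.daughter_factor * pa);
      S.b.push_back(P.daughter_factor * pb);
      S.phi.push_back(pphi);
      S.px.push_back(S.px[idx]);
      S.py.push_back(S.py[idx]);
      S.id.push_back(next_id++);
      S.parent.push_back(pid);
      int j = S.n() - 1;
      S.ux.push_back(0); S.uy.push_back(0); S.l2.push_back(0); S.d2.push_back(0);
      S.gxx.push_back(0); S.gxy.push_back(0); S.gyy.push_back(0);
      S.set_cache(j);
      S.e_geom.push_back(shape_en(S.a[j], S.b[j], P) +
                         core_en(S.a[j], S.b[j], P.k_core));
      S.e_ridge.push_back(ridge_en(S.x[j], S.y[j], S.a[j], S.b[j], S.ux[j],
                                   S.uy[j]));
      S.accum.push_back(0.0);
      rebuild_nb(S, P);
      double row[6] = {(double)g, (double)pid, (double)S.id[idx],
                       (double)S.id[j], A_par, AR_par};
      divlog.insert(divlog.end(), row, row + 6);
    }

    // 6. logging / snapshots
    if (g % 1000 == 0) {
      double psum = 0.0;
      int nn = S.n();
      for (int c = 0; c < nn; ++c)
        psum += std::sqrt(S.px[c] * S.px[c] + S.py[c] * S.py[c]);
      double row[11] = {(double)g, (double)nn,
                        (double)prop_ct[0], (double)prop_ct[1],
                        (double)prop_ct[2], (double)prop_ct[3],
                        (double)acc_ct[0], (double)acc_ct[1],
                        (double)acc_ct[2], (double)acc_ct[3],
                        psum / nn};
      acclog.insert(acclog.end(), row, row + 11);
      for (int q = 0; q < 4; ++q) { prop_ct[q] = 0; acc_ct[q] = 0; }
      checkUserInterrupt();
    }
    while (snap_ptr < nsnap && snapshot_at[snap_ptr] == g) {
      take_frame(g);
      ++snap_ptr;
    }
  }

  n = S.n();
  NumericMatrix cells_out(n, 9);
  for (int i = 0; i < n; ++i) {
    cells_out(i, 0) = S.id[i]; cells_out(i, 1) = S.parent[i];
    cells_out(i, 2) = S.x[i]; cells_out(i, 3) = S.y[i];
    cells_out(i, 4) = S.a[i]; cells_out(i, 5) = S.b[i];
    cells_out(i, 6) = S.phi[i];
    cells_out(i, 7) = S.px[i]; cells_out(i, 8) = S.py[i];
  }

  int nrow_acc = (int)acclog.size() / 11;
  NumericMatrix accm(nrow_acc, 11);
  for (int r = 0; r < nrow_acc; ++r)
    for (int cc = 0; cc < 11; ++cc) accm(r, cc) = acclog[r * 11 + cc];

  int nrow_div = (int)divlog.size() / 6;
  NumericMatrix divm(nrow_div, 6);
  for (int r = 0; r < nrow_div; ++r)
    for (int cc = 0; cc < 6; ++cc) divm(r, cc) = divlog[r * 6 + cc];

  frames.attr("names") = wrap(frame_names);

  return List::create(_["cells"] = cells_out, _["mcs"] = mcs0 + n_mcs,
                      _["next_id"] = next_id, _["frames"] = frames,
                      _["acclog"] = accm, _["divisions"] = divm);
}
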