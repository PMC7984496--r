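#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// TG-43 superposition kernel.
//
// Units: source geometry (L, r) in cm, patient space in mm, dwell times in
// seconds, dose in cGy.  Conversion mm -> cm happens here and nowhere else
// on the C++ side.

static const double MM_PER_CM = 10.0;

// Line-source geometry factor G_L(r, theta) = beta / (L r sin(theta)),
// beta the angle subtended at the field point by the active line.
// On-axis limit: 1 / (r^2 - L^2/4).  r in cm, theta in radians.
static double geom_line(double r, double theta, double L) {
  double st = std::sin(theta), ct = std::cos(theta);
  // field point at (r*st, r*ct), line from (0,-L/2) to (0,+L/2) in the
  // (transverse, axial) plane
  double x = r * st, z = r * ct;
  if (st < 1e-7) {
    double d2 = r * r - L * L / 4.0;
    if (d2 <= 0.0) return R_PosInf;
    return 1.0 / d2;
  }
  double v1x = -x, v1z = -L / 2.0 - z;   // to end 1
  double v2x = -x, v2z = L / 2.0 - z;    // to end 2
  double cross = v1x * v2z - v1z * v2x;
  double dot = v1x * v2x + v1z * v2z;
  double beta = std::fabs(std::atan2(cross, dot));
  return beta / (L * r * st);
}

// [[Rcpp::export(name = ".cpp_geometry_factor")]]
NumericVector cpp_geometry_factor(NumericVector r, NumericVector theta_deg,
                                  double L, bool line_mode) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ri = r[i];
    if (line_mode && L > 0.0) {
      double th = theta_deg[i % theta_deg.size()] * M_PI / 180.0;
      out[i] = geom_line(ri, th, L);
    } else {
      out[i] = 1.0 / (ri * ri);
    }
  }
  return out;
}

// log-linear interpolation of g_L(r): ln g piecewise linear in r.
// Below r_min: constant; above r_max: continue the last slope.
static double interp_g(double r, const NumericVector& rt, const NumericVector& lg) {
  int n = rt.size();
  if (r <= rt[0]) return std::exp(lg[0]);
  if (r >= rt[n - 1]) {
    double slope = (lg[n - 1] - lg[n - 2]) / (rt[n - 1] - rt[n - 2]);
    return std::exp(lg[n - 1] + slope * (r - rt[n - 1]));
  }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (rt[mid] <= r) lo = mid; else hi = mid; }
  double w = (r - rt[lo]) / (rt[lo + 1] - rt[lo]);
  return std::exp(lg[lo] * (1.0 - w) + lg[lo + 1] * w);
}

// bilinear interpolation of F(r, theta); r clamped to table bounds.
static inline int bsearch_idx(const NumericVector& v, double x, int n) {
  // largest i with v[i] <= x, clamped to [0, n-2]
  if (x <= v[0]) return 0;
  if (x >= v[n - 1]) return n - 2;
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int m = (lo + hi) / 2; if (v[m] <= x) lo = m; else hi = m; }
  return lo;
}

static double interp_F(double r, double th_deg,
                       const NumericVector& rF, const NumericVector& thF,
                       const NumericMatrix& F) {
  int nr = rF.size(), nt = thF.size();
  if (r < rF[0]) r = rF[0];
  if (r > rF[nr - 1]) r = rF[nr - 1];
  if (th_deg < thF[0]) th_deg = thF[0];
  if (th_deg > thF[nt - 1]) th_deg = thF[nt - 1];
  int i = bsearch_idx(rF, r, nr);
  int j = bsearch_idx(thF, th_deg, nt);
  double wr = (rF[i + 1] == rF[i]) ? 0.0 : (r - rF[i]) / (rF[i + 1] - rF[i]);
  double wt = (thF[j + 1] == thF[j]) ? 0.0 : (th_deg - thF[j]) / (thF[j + 1] - thF[j]);
  return F(i, j) * (1 - wr) * (1 - wt) + F(i + 1, j) * wr * (1 - wt) +
         F(i, j + 1) * (1 - wr) * wt + F(i + 1, j + 1) * wr * wt;
}

// Dose (cGy) at arbitrary points from a set of dwells.
// points: n x 3 (mm); dpos: m x 3 (mm); daxis: m x 3 unit vectors;
// times_s: m dwell times (s).  S_K in U, Lambda in cGy/h/U, L in cm.
// Points closer than r_cap_mm to a dwell are evaluated at r_cap_mm.
// [[Rcpp::export(name = ".cpp_dose_points")]]
NumericVector cpp_dose_points(NumericMatrix points, NumericMatrix dpos,
                              NumericMatrix daxis, NumericVector times_s,
                              double SK, double Lambda, double L,
                              bool line_mode,
                              NumericVector g_r, NumericVector g_logv,
                              NumericVector F_r, NumericVector F_th,
                              NumericMatrix F_val,
                              double r_cap_mm) {
  int n = points.nrow(), m = dpos.nrow();
  NumericVector out(n);
  long n_capped = 0;
  double Gref = line_mode && L > 0.0 ? geom_line(1.0, M_PI / 2.0, L) : 1.0;
  for (int k = 0; k < m; ++k) {
    double px = dpos(k, 0), py = dpos(k, 1), pz = dpos(k, 2);
    double ax = daxis(k, 0), ay = daxis(k, 1), az = daxis(k, 2);
    double tk = times_s[k] / 3600.0;  // hours
    if (tk <= 0.0) continue;
    for (int i = 0; i < n; ++i) {
      double dx = points(i, 0) - px, dy = points(i, 1) - py, dz = points(i, 2) - pz;
      double d0 = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d0 < r_cap_mm) ++n_capped;
      double dmm = d0 < r_cap_mm ? r_cap_mm : d0;
      double r = dmm / MM_PER_CM;
      double th_deg = 90.0;
      if (d0 > 1e-12) {
        double ca = (dx * ax + dy * ay + dz * az) / d0;
        if (ca > 1.0) ca = 1.0; if (ca < -1.0) ca = -1.0;
        th_deg = std::acos(ca) * 180.0 / M_PI;
      }
      double G;
      if (line_mode && L > 0.0) {
        G = geom_line(r, th_deg * M_PI / 180.0, L);
      } else {
        G = 1.0 / (r * r);
      }
      double g = interp_g(r, g_r, g_logv);
      double Fv = interp_F(r, th_deg, F_r, F_th, F_val);
      out[i] += SK * Lambda * (G / Gref) * g * Fv * tk;
    }
  }
  out.attr("n_capped") = (double)n_capped;
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1-D lower envelopes, anisotropic spacing.  f: flattened 3-D array
// (column-major, dims d), INF outside the seed set.  Returns squared distance
// in mm^2 to the nearest seed voxel center.
static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z,
                  int n, double step) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qs = q * step, vs = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * step;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<double> D(n);
  for (int i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : 1e30;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      int base = iy * nx + iz * nx * ny;
      for (int ix = 0; ix < nx; ++ix) f[ix] = D[base + ix];
      edt1d(f, d, v, z, nx, spacing[0]);
      for (int ix = 0; ix < nx; ++ix) D[base + ix] = d[ix];
    }
  // y pass
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      int base = ix + iz * nx * ny;
      for (int iy = 0; iy < ny; ++iy) f[iy] = D[base + iy * nx];
      edt1d(f, d, v, z, ny, spacing[1]);
      for (int iy = 0; iy < ny; ++iy) D[base + iy * nx] = d[iy];
    }
  // z pass
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      int base = ix + iy * nx;
      for (int iz = 0; iz < nz; ++iz) f[iz] = D[base + iz * nx * ny];
      edt1d(f, d, v, z, nz, spacing[2]);
      for (int iz = 0; iz < nz; ++iz) D[base + iz * nx * ny] = d[iz];
    }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = D[i];
  return out;
}
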