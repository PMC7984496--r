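#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Photon Monte Carlo for the tissue-air interface backscatter deficit.
//
// Analog transport in water (kerma approximation, no electron transport):
// exponential free paths from the tabulated total mu; Compton scattering on
// free electrons (Klein-Nishina, Kahn sampling); everything else
// (photoelectric + the ignored coherent part) is local absorption.  Point
// tallies use the next-event (point-detector) estimator of collision kerma,
// contribution E * muen(E)/rho * exp(-mu d) * p(omega->detector) / d^2.
//
// Dual tally: the full-water and half-space (water z>0, vacuum z<0)
// estimates come from the SAME histories.  A photon whose free flight ends
// at z<0 has left the half-space through the convex boundary and can never
// return, so the half-space tally simply stops crediting a history once it
// crosses; the full-water tally keeps it.  The deficit ratio is therefore
// estimated with fully correlated numerator and denominator.
//
// Geometry/tally coordinates in mm; energies in MeV; mu tables are mass
// coefficients in cm^2/g for unit-density water.

static const double MEC2 = 0.51099895;        // electron rest energy, MeV
static const double RE_CM = 2.8179403262e-13; // classical electron radius, cm
static const double NE_WATER = 3.342796e23;   // electrons per gram of water

struct MuTable {
  std::vector<double> loge, logmu, logmuen;
  double mu(double E) const { return std::exp(interp(logmu, E)); }
  double muen(double E) const { return std::exp(interp(logmuen, E)); }
  double interp(const std::vector<double>& y, double E) const {
    double le = std::log(E);
    int n = loge.size();
    if (le <= loge[0]) return y[0];
    if (le >= loge[n - 1]) return y[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int m = (lo + hi) / 2; if (loge[m] <= le) lo = m; else hi = m; }
    double w = (le - loge[lo]) / (loge[lo + 1] - loge[lo]);
    return y[lo] * (1 - w) + y[lo + 1] * w;
  }
};

// total Klein-Nishina cross-section per electron, cm^2
static double sigma_kn(double E) {
  double k = E / MEC2;
  double t1 = (1 + k) / (k * k) * (2 * (1 + k) / (1 + 2 * k) - std::log(1 + 2 * k) / k);
  double t2 = std::log(1 + 2 * k) / (2 * k);
  double t3 = (1 + 3 * k) / ((1 + 2 * k) * (1 + 2 * k));
  return 2 * M_PI * RE_CM * RE_CM * (t1 + t2 - t3);
}

// KN differential cross-section per electron, cm^2/sr, at scatter cosine ct
static double dsigma_kn(double E, double ct) {
  double k = E / MEC2;
  double ratio = 1.0 / (1.0 + k * (1.0 - ct)); // E'/E
  double s2 = 1.0 - ct * ct;
  return 0.5 * RE_CM * RE_CM * ratio * ratio * (ratio + 1.0 / ratio - s2);
}

// Kahn's rejection sampling of the KN scatter cosine; returns cos(theta)
static double sample_kn(double E) {
  double a = E / MEC2;
  for (;;) {
    double x1 = unif_rand(), x2 = unif_rand(), x3 = unif_rand();
    double eta;
    if (x1 <= (1 + 2 * a) / (9 + 2 * a)) {
      eta = 1 + 2 * a * x2;
      if (x3 <= 4 * (eta - 1) / (eta * eta)) return 1 - (eta - 1) / a;
    } else {
      eta = (1 + 2 * a) / (1 + 2 * a * x2);
      double ct = 1 - (eta - 1) / a;
      if (x3 <= 0.5 * (ct * ct + 1 / eta)) return ct;
    }
  }
}

static void rotate_dir(double& ux, double& uy, double& uz, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double norm = std::sqrt(ux * ux + uy * uy);
  double nx, ny, nz;
  if (norm > 1e-12) {
    nx = ux * ct + st * (ux * uz * cp - uy * sp) / norm;
    ny = uy * ct + st * (uy * uz * cp + ux * sp) / norm;
    nz = uz * ct - st * norm * cp;
  } else { // along +-z
    nx = st * cp;
    ny = st * sp;
    nz = (uz > 0 ? 1.0 : -1.0) * ct;
  }
  double inv = 1.0 / std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx * inv; uy = ny * inv; uz = nz * inv;
}

// [[Rcpp::export(name = ".cpp_mc_run")]]
List cpp_mc_run(NumericMatrix src_pos, NumericVector src_w,
                NumericMatrix tally, double E0, double cutoff,
                int n_hist, int n_batch,
                NumericVector tab_e, NumericVector tab_mu, NumericVector tab_muen,
                bool forced_absorption, bool has_interface, int max_scatter) {
  MuTable T;
  for (int i = 0; i < tab_e.size(); ++i) {
    T.loge.push_back(std::log(tab_e[i]));
    T.logmu.push_back(std::log(tab_mu[i]));
    T.logmuen.push_back(std::log(tab_muen[i]));
  }
  int ns = src_pos.nrow(), nt = tally.nrow();
  std::vector<double> cw(ns);
  double tot = 0;
  for (int i = 0; i < ns; ++i) { tot += src_w[i]; cw[i] = tot; }

  NumericMatrix full(n_batch, nt), half(n_batch, nt);
  NumericVector e_dep(n_batch), e_esc(n_batch), e_cut(n_batch);
  double max_acct_err = 0.0;
  int per_batch = n_hist / n_batch;
  if (per_batch < 1) per_batch = 1;

  GetRNGstate();
  for (int b = 0; b < n_batch; ++b) {
    for (int h = 0; h < per_batch; ++h) {
      // pick a dwell weighted by dwell time
      double u = unif_rand() * tot;
      int si = std::lower_bound(cw.begin(), cw.end(), u) - cw.begin();
      if (si >= ns) si = ns - 1;
      double x = src_pos(si, 0), y = src_pos(si, 1), z = src_pos(si, 2);
      // isotropic emission
      double ct0 = 2 * unif_rand() - 1, ph0 = 2 * M_PI * unif_rand();
      double st0 = std::sqrt(1 - ct0 * ct0);
      double ux = st0 * std::cos(ph0), uy = st0 * std::sin(ph0), uz = ct0;
      double E = E0;
      bool crossed = false;
      double hist_dep = 0.0, hist_esc = 0.0, hist_cut = 0.0;

      // next-event from the emission vertex (primary term, isotropic)
      {
        double mu_mm = T.mu(E) / 10.0;
        double muen = T.muen(E);
        for (int t = 0; t < nt; ++t) {
          double dx = tally(t, 0) - x, dy = tally(t, 1) - y, dz = tally(t, 2) - z;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < 0.5) d = 0.5;
          double c = E * muen * std::exp(-mu_mm * d) / (4 * M_PI * d * d);
          full(b, t) += c;
          if (!crossed || !has_interface) half(b, t) += c;
        }
      }

      int nscat = 0;
      for (;;) {
        double mu_cm = T.mu(E);
        double mu_mm = mu_cm / 10.0;
        double s = -std::log(unif_rand()) / mu_mm;
        x += s * ux; y += s * uy; z += s * uz;
        if (z < 0.0) crossed = true; // left the half-space (vacuum beyond)
        if (forced_absorption) { hist_dep += E; break; }
        double p_compton = NE_WATER * sigma_kn(E) / mu_cm;
        if (p_compton > 1.0) p_compton = 1.0;
        if (unif_rand() > p_compton) { hist_dep += E; break; } // photoelectric
        // Compton vertex: next-event toward each tally point
        double sig = sigma_kn(E);
        for (int t = 0; t < nt; ++t) {
          double dx = tally(t, 0) - x, dy = tally(t, 1) - y, dz = tally(t, 2) - z;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < 0.5) d = 0.5;
          double ctd = (dx * ux + dy * uy + dz * uz) / d;
          if (ctd > 1) ctd = 1; if (ctd < -1) ctd = -1;
          double Ed = E / (1 + (E / MEC2) * (1 - ctd));
          double c = (dsigma_kn(E, ctd) / sig) *
                     std::exp(-(T.mu(Ed) / 10.0) * d) / (d * d) *
                     Ed * T.muen(Ed);
          full(b, t) += c;
          if (!crossed || !has_interface) half(b, t) += c;
        }
        // analog continuation
        double ct = sample_kn(E);
        double Enew = E / (1 + (E / MEC2) * (1 - ct));
        hist_dep += E - Enew; // energy to the recoil electron (kerma approx)
        E = Enew;
        rotate_dir(ux, uy, uz, ct, 2 * M_PI * unif_rand());
        if (E <= cutoff) { hist_cut += E; break; }
        if (++nscat >= max_scatter) { hist_esc += E; break; }
      }
      // photons that terminated by absorption/cutoff still "carry" nothing;
      // in the half-space geometry a crossed photon's remaining interactions
      // happened in vacuum-side water of the full problem only.
      e_dep[b] += hist_dep; e_esc[b] += hist_esc; e_cut[b] += hist_cut;
      double err = std::fabs(hist_dep + hist_esc + hist_cut - E0);
      if (err > max_acct_err) max_acct_err = err;
    }
  }
  PutRNGstate();

  double nh = (double)per_batch;
  return List::create(_["full"] = full, _["half"] = half,
                      _["hist_per_batch"] = per_batch,
                      _["e_deposited"] = e_dep, _["e_escaped"] = e_esc,
                      _["e_below_cutoff"] = e_cut,
                      _["max_energy_accounting_error"] = max_acct_err,
                      _["n_histories"] = nh * n_batch);
}
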