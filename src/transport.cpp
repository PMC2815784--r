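// Monte Carlo coupled photon-electron transport of a planar microbeam
// through a cylindrical water phantom.
//
// Photons: free paths from the total linear attenuation coefficient,
// interaction channel from tabulated partial fractions, Compton scattering
// by rejection sampling of the Klein-Nishina cross-section, optional
// coherent (Rayleigh) scattering, photoelectric absorption with Sauter
// photoelectron angles.  Electrons: a condensed-history walk (stepwise CSDA
// slowing-down with screened-Rutherford first-moment-matched deflections;
// default) or an isotropic straight-line kernel bounded by the CSDA range.
// Energies are scored on a 2-D (transverse x depth) grid,
// collapsing the beam-height axis over a central scoring band; every keV
// emitted is accounted for as deposited inside or escaped from the phantom.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double ME_KEV = 510.99895;   // electron rest energy

// uniform-in-log lookup table
struct LogTable {
  const double *loge, *val;
  int n;
  double loge0, dloge;
  void init(const NumericVector &le, const NumericVector &v) {
    loge = le.begin(); val = v.begin(); n = le.size();
    loge0 = le[0]; dloge = le[1] - le[0];
  }
  double operator()(double e_keV) const {
    double x = std::log(e_keV);
    double fi = (x - loge0) / dloge;
    if (fi <= 0) return val[0];
    if (fi >= n - 1) return val[n - 1];
    int i = (int)fi;
    double w = fi - i;
    return val[i] * (1 - w) + val[i + 1] * w;
  }
};

struct Phantom {
  double radius, height;  // cm
  bool inside(double x, double y, double z) const {
    return z >= 0.0 && z <= height && (x * x + y * y) <= radius * radius;
  }
};

struct Scorer {
  const double *x_edges; int nx;
  double z0, dz; int nz;
  double yhalf;                 // scoring half-height (cm)
  std::vector<double> acc;     // per-batch energy (keV) per voxel
  double deposited, escaped;   // per-batch bookkeeping
  void reset_batch() { std::fill(acc.begin(), acc.end(), 0.0);
                       deposited = 0.0; escaped = 0.0; }
  void tally(double e, double x, double y, double z) {
    deposited += e;
    if (std::fabs(y) > yhalf) return;
    if (x < x_edges[0] || x >= x_edges[nx]) return;
    if (z < z0 || z >= z0 + nz * dz) return;
    int ix = (int)(std::upper_bound(x_edges, x_edges + nx + 1, x)
                   - x_edges) - 1;
    if (ix < 0 || ix >= nx) return;
    int iz = (int)((z - z0) / dz);
    if (iz < 0 || iz >= nz) return;
    acc[(size_t)ix * nz + iz] += e;
  }
};

// rotate direction d by polar angle (cost) and azimuth phi about itself
void rotate_dir(double *d, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  double norm = std::sqrt(ux * ux + uy * uy);
  if (norm < 1e-12) {
    double sgn = uz >= 0 ? 1.0 : -1.0;
    d[0] = sint * cphi; d[1] = sint * sphi; d[2] = cost * sgn;
  } else {
    d[0] = ux * cost + sint * (ux * uz * cphi - uy * sphi) / norm;
    d[1] = uy * cost + sint * (uy * uz * cphi + ux * sphi) / norm;
    d[2] = uz * cost - norm * sint * cphi;
  }
  double n2 = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  d[0] /= n2; d[1] /= n2; d[2] /= n2;
}

// Sauter photoelectron polar angle: f(c) ~ (1 - c^2) / (1 - beta*c)^4
// * [1 + k (1 - beta*c)], k = gamma (gamma-1)(gamma-2) / 2.  Rejection
// sampling against a scanned upper bound (the density is smooth in c).
double sample_sauter_cost(double t_keV) {
  double gamma = 1.0 + t_keV / ME_KEV;
  double beta = std::sqrt(1.0 - 1.0 / (gamma * gamma));
  double k = 0.5 * gamma * (gamma - 1.0) * (gamma - 2.0);
  auto f = [&](double c) {
    double d = 1.0 - beta * c;
    double g = 1.0 + k * d;
    if (g < 0) g = 0;
    return (1.0 - c * c) / (d * d * d * d) * g;
  };
  double fmax = 0.0;
  for (int i = 0; i <= 64; ++i) {
    double v = f(-1.0 + 2.0 * i / 64.0);
    if (v > fmax) fmax = v;
  }
  fmax *= 1.1;  // safety margin over the coarse scan
  double c;
  do { c = 2.0 * unif_rand() - 1.0; } while (unif_rand() * fmax > f(c));
  return c;
}

// Klein-Nishina sampling on a free electron; returns x = E'/E and sets cost
double sample_kn(double e_keV, double &cost) {
  double alpha = e_keV / ME_KEV;
  double xmin = 1.0 / (1.0 + 2.0 * alpha);
  double fmax = xmin + 1.0 / xmin;  // bound for x + 1/x - sin^2
  double x, f;
  do {
    x = xmin + unif_rand() * (1.0 - xmin);
    cost = 1.0 - (1.0 / x - 1.0) / alpha;
    double sin2 = 1.0 - cost * cost;
    f = x + 1.0 / x - sin2;
  } while (unif_rand() * fmax > f);
  return x;
}

// Electron elastic scattering: screened-Rutherford transport cross-section.
// For each element, sigma_tr = C [ln((1+eta)/eta) - 1 + eta/(1+eta)] with
// C = 2 pi Z(Z+1) re^2 (1-beta^2)/beta^4 and Moliere screening parameter
// eta = (1/4)(alpha Z^(1/3)/0.885)^2 (me c/p)^2 (1.13 + 3.76 (alpha Z/beta)^2).
// Returns the inverse transport mean free path 1/lambda_1 (cm^-1) of water
// (2 H + O per molecule, 3.343e22 molecules/cm^3).
double inv_lambda1_water(double t_keV) {
  double gamma = 1.0 + t_keV / ME_KEV;
  double inv_g2 = 1.0 / (gamma * gamma);
  double beta2 = 1.0 - inv_g2;
  if (beta2 <= 0) return 0.0;
  double p_ratio2 = beta2 * gamma * gamma;  // (p / me c)^2
  const double re2 = 7.9407e-26;            // cm^2
  const double alpha_fs = 7.2974e-3;
  const double zs[2] = { 1.0, 8.0 };
  const double nd[2] = { 6.686e22, 3.343e22 };  // atoms per cm^3
  double out = 0.0;
  for (int i = 0; i < 2; ++i) {
    double z = zs[i];
    double az = alpha_fs * std::cbrt(z) / 0.885;
    double eta = 0.25 * az * az / p_ratio2 *
                 (1.13 + 3.76 * alpha_fs * alpha_fs * z * z / beta2);
    double c = 2.0 * M_PI * z * (z + 1.0) * re2 * inv_g2 / (beta2 * beta2);
    double br = std::log((1.0 + eta) / eta) - 1.0 + eta / (1.0 + eta);
    out += nd[i] * c * br;
  }
  return out;
}

// Mean of the screened angular density P(u) ~ 1/(A + 1 - u)^2 on [-1, 1]
double screened_mean_cos(double a) {
  return (a + 1.0) - 0.5 * a * (a + 2.0) * std::log1p(2.0 / a);
}

// Step deflection: sample cos(theta) from P(u) ~ 1/(A + 1 - u)^2 with the
// screening A chosen so the mean equals exp(-s / lambda_1) (first-moment
// matched multiple scattering; carries the single-scattering tail).
// ln(A) as a function of ln(1 - m), tabulated once by bisection and then
// linearly interpolated (the map is smooth and monotone).
double screening_log_a(double m) {
  static std::vector<double> tab;
  const int n = 1024;
  const double x0 = std::log(1e-12), x1 = std::log(1.0 - 1e-12);
  const double dx = (x1 - x0) / (n - 1);
  if (tab.empty()) {
    tab.resize(n);
    for (int i = 0; i < n; ++i) {
      double mi = 1.0 - std::exp(x0 + i * dx);
      double lo = -30.0, hi = 30.0;
      for (int k = 0; k < 80; ++k) {
        double mid = 0.5 * (lo + hi);
        if (screened_mean_cos(std::exp(mid)) > mi) lo = mid; else hi = mid;
      }
      tab[i] = 0.5 * (lo + hi);
    }
  }
  double fi = (std::log(1.0 - m) - x0) / dx;
  if (fi <= 0) return tab[0];
  if (fi >= n - 1) return tab[n - 1];
  int i = (int)fi;
  double w = fi - i;
  return tab[i] * (1 - w) + tab[i + 1] * w;
}

double sample_step_cost(double s_over_l1) {
  double m = std::exp(-s_over_l1);
  if (m > 1.0 - 1e-12) return 1.0;
  if (m < 1e-12) return 2.0 * unif_rand() - 1.0;
  double a = std::exp(screening_log_a(m));
  double nrm = 0.5 * a * (a + 2.0);
  double r = unif_rand();
  double u = a + 1.0 - 1.0 / (r / nrm + 1.0 / (a + 2.0));
  if (u > 1.0) u = 1.0;
  if (u < -1.0) u = -1.0;
  return u;
}

struct ElectronCfg {
  int mode;        // 0 = kernel, 1 = condensed history, 2 = local
  int n_sub;       // kernel substeps
  double e_cut;    // keV
  double step_frac;// condensed-history fractional energy loss per step
  const LogTable *csda;  // cm vs energy
};

void transport_electron_one(double t_keV, const double pos0[3],
                            const double dir0[3], const Phantom &ph,
                            Scorer &sc, const ElectronCfg &cfg) {
  if (t_keV <= cfg.e_cut || cfg.mode == 2) {
    if (ph.inside(pos0[0], pos0[1], pos0[2])) sc.tally(t_keV, pos0[0],
        pos0[1], pos0[2]);
    else sc.escaped += t_keV;
    return;
  }
  if (cfg.mode == 0) {
    // isotropic straight-line kernel bounded by the CSDA range
    double cost = 2.0 * unif_rand() - 1.0;
    double phi = 2.0 * M_PI * unif_rand();
    double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
    double d[3] = { sint * std::cos(phi), sint * std::sin(phi), cost };
    double range = (*cfg.csda)(t_keV);
    double de = t_keV / cfg.n_sub;
    for (int i = 0; i < cfg.n_sub; ++i) {
      double s = range * (i + 0.5) / cfg.n_sub;
      double px = pos0[0] + d[0] * s, py = pos0[1] + d[1] * s,
             pz = pos0[2] + d[2] * s;
      if (ph.inside(px, py, pz)) sc.tally(de, px, py, pz);
      else sc.escaped += de;
    }
    return;
  }
  // condensed history: stepwise CSDA slowing-down with Highland deflections
  double t = t_keV;
  double pos[3] = { pos0[0], pos0[1], pos0[2] };
  double dir[3] = { dir0[0], dir0[1], dir0[2] };
  while (t > cfg.e_cut) {
    double dt = std::max(t * cfg.step_frac, 0.5 * cfg.e_cut);
    if (dt >= t) dt = t;
    double ds = (*cfg.csda)(t) - (*cfg.csda)(std::max(t - dt, 1.0));
    if (ds <= 0) ds = 1e-7;
    double mx = pos[0] + dir[0] * ds * 0.5,
           my = pos[1] + dir[1] * ds * 0.5,
           mz = pos[2] + dir[2] * ds * 0.5;
    if (ph.inside(mx, my, mz)) sc.tally(dt, mx, my, mz);
    else { sc.escaped += (t); return; }  // remainder leaves the phantom
    pos[0] += dir[0] * ds; pos[1] += dir[1] * ds; pos[2] += dir[2] * ds;
    t -= dt;
    if (t <= cfg.e_cut) break;
    double cost = sample_step_cost(ds * inv_lambda1_water(t + 0.5 * dt));
    rotate_dir(dir, cost, 2.0 * M_PI * unif_rand());
  }
  if (t > 0) {
    if (ph.inside(pos[0], pos[1], pos[2])) sc.tally(t, pos[0], pos[1],
        pos[2]);
    else sc.escaped += t;
  }
}

double sample_spectrum(const NumericVector &edges, const NumericVector &cdf) {
  double u = unif_rand();
  int n = cdf.size();
  int i = (int)(std::upper_bound(cdf.begin(), cdf.end(), u)
                - cdf.begin()) - 1;
  if (i < 0) i = 0;
  if (i >= n - 1) i = n - 2;
  double w = (cdf[i + 1] > cdf[i]) ? (u - cdf[i]) / (cdf[i + 1] - cdf[i])
                                   : 0.5;
  return edges[i] + w * (edges[i + 1] - edges[i]);
}

} // namespace

// [[Rcpp::export]]
List mc_microbeam_cpp(NumericVector spec_edges, NumericVector spec_cdf,
                      double radius_cm, double height_cm,
                      double beam_halfwidth_cm, double beam_halfheight_cm,
                      double y_score_half_cm,
                      NumericVector x_edges_cm, double z0_cm, double dz_cm,
                      int nz,
                      NumericVector tab_loge, NumericVector tab_mu,
                      NumericVector tab_fpe, NumericVector tab_fincoh,
                      NumericVector csda_loge, NumericVector csda_cm,
                      int n_hist, int n_batch,
                      double e_cut_keV, double p_cut_keV,
                      bool rayleigh, int electron_mode, bool absorb_first,
                      int n_sub, double step_frac) {
  Phantom ph { radius_cm, height_cm };
  LogTable mu_tab, fpe_tab, finc_tab, csda_tab;
  mu_tab.init(tab_loge, tab_mu);
  fpe_tab.init(tab_loge, tab_fpe);
  finc_tab.init(tab_loge, tab_fincoh);
  csda_tab.init(csda_loge, csda_cm);

  int nx = x_edges_cm.size() - 1;
  Scorer sc;
  sc.x_edges = x_edges_cm.begin(); sc.nx = nx;
  sc.z0 = z0_cm; sc.dz = dz_cm; sc.nz = nz;
  sc.yhalf = y_score_half_cm;
  sc.acc.assign((size_t)nx * nz, 0.0);

  ElectronCfg ecfg { electron_mode, n_sub, e_cut_keV, step_frac, &csda_tab };

  std::vector<double> s1((size_t)nx * nz, 0.0), s2((size_t)nx * nz, 0.0);
  NumericVector b_emitted(n_batch), b_deposited(n_batch), b_escaped(n_batch);

  int per_batch = n_hist / n_batch;
  for (int b = 0; b < n_batch; ++b) {
    sc.reset_batch();
    double emitted = 0.0;
    int nh = (b == n_batch - 1) ? n_hist - per_batch * (n_batch - 1)
                                : per_batch;
    for (int h = 0; h < nh; ++h) {
      double e = sample_spectrum(spec_edges, spec_cdf);
      emitted += e;
      double pos[3] = {
        beam_halfwidth_cm * (2.0 * unif_rand() - 1.0),
        beam_halfheight_cm * (2.0 * unif_rand() - 1.0),
        0.0 };
      double dir[3] = { 0.0, 0.0, 1.0 };
      for (;;) {
        double mu = mu_tab(e);
        double s = -std::log(unif_rand()) / mu;
        pos[0] += dir[0] * s; pos[1] += dir[1] * s; pos[2] += dir[2] * s;
        if (!ph.inside(pos[0], pos[1], pos[2])) { sc.escaped += e; break; }
        if (absorb_first) { sc.tally(e, pos[0], pos[1], pos[2]); break; }
        double fpe = fpe_tab(e), finc = finc_tab(e);
        if (!rayleigh) {  // renormalise over the enabled channels
          double tot = fpe + finc;
          fpe /= tot; finc /= tot;
        }
        double u = unif_rand();
        if (u < fpe) {  // photoelectric: electron carries the photon energy
          double edir[3] = { dir[0], dir[1], dir[2] };
          rotate_dir(edir, sample_sauter_cost(e), 2.0 * M_PI * unif_rand());
          transport_electron_one(e, pos, edir, ph, sc, ecfg);
          break;
        } else if (u < fpe + finc) {  // incoherent (Compton)
          double cost;
          double x = sample_kn(e, cost);
          double eprime = x * e;
          double t = e - eprime;
          double phi = 2.0 * M_PI * unif_rand();
          if (t > 0) {
            // kinematic electron direction, coplanar with (opposite
            // azimuth to) the scattered photon
            double tan_half = std::sqrt(std::max(0.0, (1.0 - cost) /
                                                       (1.0 + cost)));
            double alpha = e / ME_KEV;
            double te = (tan_half > 1e-12)
              ? std::atan(1.0 / ((1.0 + alpha) * tan_half)) : M_PI / 2;
            double edir[3] = { dir[0], dir[1], dir[2] };
            rotate_dir(edir, std::cos(te), phi + M_PI);
            transport_electron_one(t, pos, edir, ph, sc, ecfg);
          }
          if (eprime < p_cut_keV) {
            sc.tally(eprime, pos[0], pos[1], pos[2]);
            break;
          }
          e = eprime;
          rotate_dir(dir, cost, phi);
        } else {  // coherent (Rayleigh): Thomson-like angular distribution
          double cost;
          do { cost = 2.0 * unif_rand() - 1.0; }
          while (unif_rand() > 0.5 * (1.0 + cost * cost));
          rotate_dir(dir, cost, 2.0 * M_PI * unif_rand());
        }
      }
    }
    b_emitted[b] = emitted;
    b_deposited[b] = sc.deposited;
    b_escaped[b] = sc.escaped;
    for (size_t k = 0; k < sc.acc.size(); ++k) {
      s1[k] += sc.acc[k];
      s2[k] += sc.acc[k] * sc.acc[k];
    }
  }

  NumericMatrix energy(nx, nz), rel_unc(nx, nz);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < nz; ++j) {
      size_t k = (size_t)i * nz + j;
      double m = s1[k] / n_batch;
      energy(i, j) = s1[k];
      if (m > 0 && n_batch > 1) {
        double var = (s2[k] - s1[k] * s1[k] / n_batch) /
                     ((double)n_batch * (n_batch - 1));
        rel_unc(i, j) = std::sqrt(std::max(var, 0.0)) / m;
      } else {
        rel_unc(i, j) = (m > 0) ? 0.0 : 1.0;
      }
    }
  }
  return List::create(_["energy_keV"] = energy, _["rel_unc"] = rel_unc,
                      _["emitted"] = b_emitted,
                      _["deposited"] = b_deposited,
                      _["escaped"] = b_escaped);
}

// [[Rcpp::export]]
NumericMatrix sample_compton_cpp(double energy_keV, int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double cost;
    double x = sample_kn(energy_keV, cost);
    out(i, 0) = x * energy_keV;          // scattered photon energy
    out(i, 1) = cost;                    // cosine of the polar angle
    out(i, 2) = energy_keV * (1.0 - x);  // electron kinetic energy
  }
  return out;
}

// [[Rcpp::export]]
List electron_deposit_cpp(double energy_keV, NumericVector origin,
                          NumericVector direction,
                          double radius_cm, double height_cm,
                          NumericVector x_edges_cm, double z0_cm,
                          double dz_cm, int nz, double y_score_half_cm,
                          NumericVector csda_loge, NumericVector csda_cm,
                          int electron_mode, int n_sub, double e_cut_keV,
                          double step_frac) {
  Phantom ph { radius_cm, height_cm };
  LogTable csda_tab;
  csda_tab.init(csda_loge, csda_cm);
  int nx = x_edges_cm.size() - 1;
  Scorer sc;
  sc.x_edges = x_edges_cm.begin(); sc.nx = nx;
  sc.z0 = z0_cm; sc.dz = dz_cm; sc.nz = nz;
  sc.yhalf = y_score_half_cm;
  sc.acc.assign((size_t)nx * nz, 0.0);
  sc.reset_batch();
  ElectronCfg ecfg { electron_mode, n_sub, e_cut_keV, step_frac,
                     &csda_tab };
  double pos[3] = { origin[0], origin[1], origin[2] };
  double dir[3] = { direction[0], direction[1], direction[2] };
  transport_electron_one(energy_keV, pos, dir, ph, sc, ecfg);
  NumericMatrix energy(nx, nz);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < nz; ++j)
      energy(i, j) = sc.acc[(size_t)i * nz + j];
  return List::create(_["energy_keV"] = energy,
                      _["deposited"] = sc.deposited,
                      _["escaped"] = sc.escaped);
}
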