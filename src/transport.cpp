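// Simplified voxel transport of Lu-177 electrons and photons.
//
// Electrons: straight-line continuous-slowing-down (CSDA) condensed history
// with step <= half a voxel; per-step energy loss from the water CSDA range
// table scaled by local density and mass-stopping-power ratio.  No multiple
// scattering deflection.  Particles below the cut deposit locally.
//
// Photons: analog Monte Carlo by Woodcock (delta) tracking with two
// processes - photoelectric absorption (local deposit) and incoherent
// Compton scattering (Klein-Nishina via Kahn's rejection method; recoil
// electron deposited locally).  Photons below 10 keV deposit locally.
//
// RNG: std::mt19937_64 per batch seed; results are bit-identical for a
// fixed (seed, n) on one platform.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double J_PER_KEV = 1.602176634e-16;
static const double MEC2 = 510.99895;
static const double PHOTON_CUT_KEV = 10.0;

struct Grid {
  int nx, ny, nz;
  double h;                       // voxel edge, mm
  const int* mat;                 // material index per voxel, 0-based
  std::vector<double> rho, sps;   // per material
  // attenuation tables: log-energy grid, per-material mu (1/cm)
  std::vector<double> logE;
  std::vector<std::vector<double>> mu_pe, mu_co, mu_tot;
  std::vector<double> mu_max;     // max over materials, per energy node
  // range table (water): logE_r vs logR (g/cm2), both ways
  std::vector<double> logE_r, logR_r;

  inline bool inside(double x, double y, double z) const {
    return x >= 0 && y >= 0 && z >= 0 &&
           x < nx * h && y < ny * h && z < nz * h;
  }
  inline int voxel(double x, double y, double z) const {
    int i = (int)(x / h), j = (int)(y / h), k = (int)(z / h);
    if (i >= nx) i = nx - 1; if (j >= ny) j = ny - 1; if (k >= nz) k = nz - 1;
    return i + nx * (j + ny * k);
  }
};

static inline double lin_interp(const std::vector<double>& xs,
                                const std::vector<double>& ys, double x) {
  if (x <= xs.front()) return ys.front();
  if (x >= xs.back()) return ys.back();
  size_t hi = std::upper_bound(xs.begin(), xs.end(), x) - xs.begin();
  size_t lo = hi - 1;
  double t = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] + t * (ys[hi] - ys[lo]);
}

static inline double range_of_E(const Grid& g, double E) {  // g/cm2
  return std::exp(lin_interp(g.logE_r, g.logR_r, std::log(E)));
}
static inline double E_of_range(const Grid& g, double R) {  // keV
  return std::exp(lin_interp(g.logR_r, g.logE_r, std::log(R)));
}

typedef std::vector<std::pair<int, double>> Deposits;  // (voxel, keV)

// straight-line CSDA electron track; returns deposited keV
static double track_electron(const Grid& g, double E,
                             double x, double y, double z,
                             double ux, double uy, double uz,
                             double e_cut, Deposits& dep,
                             double step_mm = 0.0) {
  double deposited = 0.0;
  const double h_step = step_mm > 0 ? step_mm : 0.5 * g.h;  // mm
  double Rw = range_of_E(g, E);          // residual water range, g/cm2
  const double Rcut = range_of_E(g, e_cut);
  while (E > 0) {
    if (!g.inside(x, y, z)) break;       // escaped the grid
    int v = g.voxel(x, y, z);
    int m = g.mat[v];
    double dRw = h_step * 0.1 * g.rho[m] * g.sps[m];  // g/cm2 over this step
    if (E <= e_cut || Rw - dRw <= Rcut) {            // stop here
      dep.push_back({v, E});
      deposited += E;
      E = 0;
      break;
    }
    Rw -= dRw;
    double Enew = E_of_range(g, Rw);
    if (Enew > E) Enew = E;              // guard interpolation noise
    // deposit at the step midpoint voxel (second-order accurate)
    double mx = x + 0.5 * h_step * ux, my = y + 0.5 * h_step * uy,
           mz = z + 0.5 * h_step * uz;
    int vm = g.inside(mx, my, mz) ? g.voxel(mx, my, mz) : v;
    dep.push_back({vm, E - Enew});
    deposited += E - Enew;
    E = Enew;
    x += h_step * ux; y += h_step * uy; z += h_step * uz;
  }
  return deposited;
}

// Kahn's method for Klein-Nishina sampling; returns scattered/incident ratio
static double kahn_sample(double k, std::mt19937_64& rng,
                          std::uniform_real_distribution<double>& U) {
  // k = E/mec2
  double r;
  for (;;) {
    double u1 = U(rng), u2 = U(rng), u3 = U(rng);
    if (u1 <= (1.0 + 2.0 * k) / (9.0 + 2.0 * k)) {
      r = 1.0 + 2.0 * k * u2;
      if (u3 <= 4.0 * (1.0 / r - 1.0 / (r * r))) return 1.0 / r;
    } else {
      r = (1.0 + 2.0 * k) / (1.0 + 2.0 * k * u2);
      double c = 1.0 - (r - 1.0) / k;   // cos(theta)
      if (u3 <= 0.5 * (c * c + 1.0 / r)) return 1.0 / r;
    }
  }
}

static void isotropic_dir(std::mt19937_64& rng,
                          std::uniform_real_distribution<double>& U,
                          double& ux, double& uy, double& uz) {
  double c = 2.0 * U(rng) - 1.0, phi = 2.0 * M_PI * U(rng);
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  ux = s * std::cos(phi); uy = s * std::sin(phi); uz = c;
}

// rotate direction u by polar angle (cos ct) around it, uniform azimuth
static void rotate_dir(double ct, double phi,
                       double& ux, double& uy, double& uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double wx, wy, wz;  // build orthonormal frame
  if (std::fabs(uz) < 0.99) { wx = -uy; wy = ux; wz = 0.0; }
  else { wx = 0.0; wy = -uz; wz = uy; }
  double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
  wx /= wn; wy /= wn; wz /= wn;
  double vx = uy * wz - uz * wy, vy = uz * wx - ux * wz, vz = ux * wy - uy * wx;
  double nx = ct * ux + st * (std::cos(phi) * wx + std::sin(phi) * vx);
  double ny = ct * uy + st * (std::cos(phi) * wy + std::sin(phi) * vy);
  double nz = ct * uz + st * (std::cos(phi) * wz + std::sin(phi) * vz);
  double n = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / n; uy = ny / n; uz = nz / n;
}

// Woodcock-tracked photon; returns deposited keV
static double track_photon(const Grid& g, double E,
                           double x, double y, double z,
                           double ux, double uy, double uz,
                           std::mt19937_64& rng,
                           std::uniform_real_distribution<double>& U,
                           Deposits& dep) {
  double deposited = 0.0;
  for (;;) {
    if (E <= PHOTON_CUT_KEV) {
      if (g.inside(x, y, z)) {
        int v = g.voxel(x, y, z);
        dep.push_back({v, E});
        deposited += E;
      }
      return deposited;
    }
    double logE = std::log(E);
    double mu_max = lin_interp(g.logE, g.mu_max, logE);  // 1/cm
    if (mu_max <= 0) return deposited;
    double t_mm = -std::log(U(rng)) / mu_max * 10.0;
    x += t_mm * ux; y += t_mm * uy; z += t_mm * uz;
    if (!g.inside(x, y, z)) return deposited;            // escaped
    int v = g.voxel(x, y, z);
    int m = g.mat[v];
    double mu_t = lin_interp(g.logE, g.mu_tot[m], logE);
    if (U(rng) * mu_max > mu_t) continue;                // virtual collision
    double mu_pe = lin_interp(g.logE, g.mu_pe[m], logE);
    if (U(rng) * mu_t < mu_pe) {                         // photoelectric
      dep.push_back({v, E});
      deposited += E;
      return deposited;
    }
    // Compton: recoil electron deposited locally, photon continues
    double k = E / MEC2;
    double ratio = kahn_sample(k, rng, U);
    double Enew = E * ratio;
    double ct = 1.0 - (1.0 / ratio - 1.0) / k;
    if (ct < -1.0) ct = -1.0; if (ct > 1.0) ct = 1.0;
    dep.push_back({v, E - Enew});
    deposited += E - Enew;
    E = Enew;
    rotate_dir(ct, 2.0 * M_PI * U(rng), ux, uy, uz);
  }
}

static Grid unpack_grid(const List& pack) {
  Grid g;
  IntegerVector dims = pack["dims"];
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.h = as<double>(pack["voxel_mm"]);
  IntegerVector mat = pack["mat"];
  g.mat = INTEGER(mat);
  g.rho = as<std::vector<double>>(pack["density"]);
  g.sps = as<std::vector<double>>(pack["sps"]);
  NumericVector Eg = pack["mu_egrid"];
  for (double e : Eg) g.logE.push_back(std::log(e));
  NumericMatrix pe = pack["mu_pe"], co = pack["mu_co"];
  int nm = g.rho.size(), ne = Eg.size();
  g.mu_pe.assign(nm, std::vector<double>(ne));
  g.mu_co.assign(nm, std::vector<double>(ne));
  g.mu_tot.assign(nm, std::vector<double>(ne));
  g.mu_max.assign(ne, 0.0);
  for (int m = 0; m < nm; ++m)
    for (int e = 0; e < ne; ++e) {
      g.mu_pe[m][e] = pe(m, e);
      g.mu_co[m][e] = co(m, e);
      g.mu_tot[m][e] = pe(m, e) + co(m, e);
      g.mu_max[e] = std::max(g.mu_max[e], g.mu_tot[m][e]);
    }
  NumericVector rE = pack["range_egrid"], rR = pack["range_gcm2"];
  for (int i = 0; i < rE.size(); ++i) {
    if (rR[i] <= 0) continue;
    g.logE_r.push_back(std::log(rE[i]));
    g.logR_r.push_back(std::log(rR[i]));
  }
  return g;
}

// flush per-primary deposits into dose (Gy) and squared-dose accumulators
static void flush_deposits(const Grid& g, Deposits& dep,
                           std::vector<double>& dose_j,
                           std::vector<double>& dose2,
                           const std::vector<double>& inv_mass_kg) {
  if (dep.empty()) return;
  std::sort(dep.begin(), dep.end());
  size_t i = 0;
  while (i < dep.size()) {
    int v = dep[i].first;
    double e = 0.0;
    while (i < dep.size() && dep[i].first == v) { e += dep[i].second; ++i; }
    double gy = e * J_PER_KEV * inv_mass_kg[v];
    dose_j[v] += gy;
    dose2[v] += gy * gy;
  }
  dep.clear();
}

// [[Rcpp::export]]
List cpp_run_batch(List grid_pack, List emission_pack,
                   IntegerVector source_vox, NumericVector source_cdf,
                   double n_primaries, int seed, double e_cut_kev,
                   bool electrons_only, double step_mm) {
  Grid g = unpack_grid(grid_pack);
  long n = (long)n_primaries;
  NumericVector invcdf = emission_pack["beta_invcdf"];
  double beta_yield = as<double>(emission_pack["beta_yield"]);
  NumericVector line_E = emission_pack["line_energy"];
  NumericVector line_y = emission_pack["line_yield"];
  IntegerVector line_ph = emission_pack["line_is_photon"];
  int nlines = line_E.size(), ninv = invcdf.size();

  size_t nvox = (size_t)g.nx * g.ny * g.nz;
  std::vector<double> inv_mass(nvox);
  double voxvol_cm3 = std::pow(g.h / 10.0, 3);
  for (size_t v = 0; v < nvox; ++v)
    inv_mass[v] = 1.0 / (g.rho[g.mat[v]] * voxvol_cm3 * 1e-3);  // 1/kg

  std::vector<double> dose(nvox, 0.0), dose2(nvox, 0.0);
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  Deposits dep;
  dep.reserve(256);
  double emitted = 0.0, deposited = 0.0;

  const double* cdf = REAL(source_cdf);
  int nsrc = source_vox.size();

  for (long p = 0; p < n; ++p) {
    // decay site: voxel from the activity CDF, uniform position within it
    double u = U(rng);
    int lo = (int)(std::lower_bound(cdf, cdf + nsrc, u) - cdf);
    if (lo >= nsrc) lo = nsrc - 1;
    long v = source_vox[lo];                   // 0-based linear index
    long i = v % g.nx, j = (v / g.nx) % g.ny, k = v / ((long)g.nx * g.ny);
    double x = (i + U(rng)) * g.h, y = (j + U(rng)) * g.h, z = (k + U(rng)) * g.h;

    double ux, uy, uz;
    if (U(rng) < beta_yield) {                 // beta electron
      double uu = U(rng) * (ninv - 1);
      int ii = (int)uu;
      double E = invcdf[ii] + (uu - ii) * (invcdf[std::min(ii + 1, ninv - 1)] - invcdf[ii]);
      isotropic_dir(rng, U, ux, uy, uz);
      emitted += E;
      deposited += track_electron(g, E, x, y, z, ux, uy, uz, e_cut_kev, dep, step_mm);
    }
    for (int l = 0; l < nlines; ++l) {
      if (U(rng) >= line_y[l]) continue;
      if (electrons_only && line_ph[l]) continue;
      isotropic_dir(rng, U, ux, uy, uz);
      emitted += line_E[l];
      if (line_ph[l])
        deposited += track_photon(g, line_E[l], x, y, z, ux, uy, uz, rng, U, dep);
      else
        deposited += track_electron(g, line_E[l], x, y, z, ux, uy, uz, e_cut_kev, dep, step_mm);
    }
    flush_deposits(g, dep, dose, dose2, inv_mass);
  }

  // per-primary normalization of the dose grid; dose2 kept as raw sum
  NumericVector dose_out(nvox), dose2_out(nvox);
  for (size_t v = 0; v < nvox; ++v) {
    dose_out[v] = dose[v] / n;
    dose2_out[v] = dose2[v];
  }
  return List::create(_["dose"] = dose_out, _["dose_sq"] = dose2_out,
                      _["emitted_kev"] = emitted, _["deposited_kev"] = deposited);
}

// [[Rcpp::export]]
List cpp_transport_electron(List grid_pack, double energy_kev,
                            NumericVector position_mm, NumericVector direction,
                            double e_cut_kev, double step_mm) {
  Grid g = unpack_grid(grid_pack);
  size_t nvox = (size_t)g.nx * g.ny * g.nz;
  double un = std::sqrt(direction[0] * direction[0] + direction[1] * direction[1] +
                        direction[2] * direction[2]);
  Deposits dep;
  double got = track_electron(g, energy_kev, position_mm[0], position_mm[1],
                              position_mm[2], direction[0] / un,
                              direction[1] / un, direction[2] / un,
                              e_cut_kev, dep, step_mm);
  NumericVector dose_kev(nvox);
  for (auto& d : dep) dose_kev[d.first] += d.second;
  return List::create(_["deposited_kev"] = got, _["grid_kev"] = dose_kev);
}

// [[Rcpp::export]]
List cpp_transport_photon(List grid_pack, double energy_kev,
                          NumericVector position_mm, NumericVector direction,
                          int seed) {
  Grid g = unpack_grid(grid_pack);
  size_t nvox = (size_t)g.nx * g.ny * g.nz;
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double un = std::sqrt(direction[0] * direction[0] + direction[1] * direction[1] +
                        direction[2] * direction[2]);
  Deposits dep;
  double got = track_photon(g, energy_kev, position_mm[0], position_mm[1],
                            position_mm[2], direction[0] / un,
                            direction[1] / un, direction[2] / un, rng, U, dep);
  NumericVector dose_kev(nvox);
  for (auto& d : dep) dose_kev[d.first] += d.second;
  return List::create(_["deposited_kev"] = got, _["grid_kev"] = dose_kev);
}
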