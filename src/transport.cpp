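// Kilovoltage photon transport through a voxel phantom under the kerma
// approximation: photoelectric events absorb locally, Compton events deposit
// the transferred energy locally and continue with the Klein-Nishina-sampled
// scattered photon, Rayleigh events redirect without deposit (form-factor-
// free Thomson angular law).  Tracking is Woodcock (delta) tracking against
// the phantom-wide majorant by default, with a voxel-by-voxel ray-stepping
// mode kept as an independent cross-check of the tracking scheme.
//
// All lengths are mm; attenuation coefficients arrive as cm^2/g tables and
// are converted to per-mm inside.  RNG is a per-history splitmix64 substream
// derived from (seed, history index) so runs are reproducible and
// order-independent.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t sm64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double runif01(uint64_t &x) {
  return ((sm64_next(x) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline uint64_t history_stream(uint64_t seed, uint64_t idx) {
  uint64_t s = seed ^ (0xBF58476D1CE4E5B9ULL * (idx + 1));
  sm64_next(s);  // decorrelate nearby seeds
  return s;
}

struct Grid {
  const double *rho;
  const int *mat;   // 0-based
  int nx, ny, nz;
  double dx, dy, dz;
  double x0, y0, z0;  // min corner (voxel centres start half a step in)
  double x1, y1, z1;
  size_t nvox() const { return (size_t)nx * ny * nz; }
};

struct Xs {
  const double *photo, *incoh, *coh;  // nE x nmat, column major
  int nE, nmat;
  double emin;
  std::vector<double> majorant;  // per-mm majorant attenuation vs energy
};

static inline double col_interp(const double *col, int nE, double emin,
                                double E) {
  double f = E - emin;
  if (f <= 0.0) return col[0];
  int i = (int)f;
  if (i >= nE - 1) return col[nE - 1];
  double w = f - i;
  return col[i] * (1.0 - w) + col[i + 1] * w;
}

// partial mass attenuation coefficients (cm^2/g) at energy E for material m
static inline void mu_parts(const Xs &xs, int m, double E, double &ph,
                            double &ic, double &co) {
  const double *pc = xs.photo + (size_t)m * xs.nE;
  const double *icc = xs.incoh + (size_t)m * xs.nE;
  const double *cc = xs.coh + (size_t)m * xs.nE;
  ph = col_interp(pc, xs.nE, xs.emin, E);
  ic = col_interp(icc, xs.nE, xs.emin, E);
  co = col_interp(cc, xs.nE, xs.emin, E);
}

static inline double majorant_mu(const Xs &xs, double E) {
  return col_interp(xs.majorant.data(), xs.nE, xs.emin, E);
}

// slab-method ray/box intersection; returns false on miss
static bool ray_box(const Grid &g, const double p[3], const double d[3],
                    double &tmin, double &tmax) {
  tmin = 0.0;
  tmax = 1e300;
  const double lo[3] = {g.x0, g.y0, g.z0};
  const double hi[3] = {g.x1, g.y1, g.z1};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] <= lo[a] || p[a] >= hi[a]) return false;
    } else {
      double t1 = (lo[a] - p[a]) / d[a];
      double t2 = (hi[a] - p[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  return tmax > tmin && tmax > 0.0;
}

static inline long voxel_index(const Grid &g, const double p[3]) {
  int ix = (int)std::floor((p[0] - g.x0) / g.dx);
  int iy = (int)std::floor((p[1] - g.y0) / g.dy);
  int iz = (int)std::floor((p[2] - g.z0) / g.dz);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= g.nx || iy >= g.ny || iz >= g.nz)
    return -1;
  return (long)ix + (long)g.nx * (iy + (long)g.ny * iz);
}

// Kahn's rejection sampler for the Klein-Nishina ratio x = E/E' in [1, 1+2k]
static inline double kahn_x(double k, uint64_t &st) {
  const double a = (1.0 + 2.0 * k) / (9.0 + 2.0 * k);
  for (;;) {
    double r1 = runif01(st), r2 = runif01(st), r3 = runif01(st);
    if (r1 <= a) {
      double x = 1.0 + 2.0 * k * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return x;
    } else {
      double x = (1.0 + 2.0 * k) / (1.0 + 2.0 * k * r2);
      double ct = 1.0 - (x - 1.0) / k;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) return x;
    }
  }
}

// Thomson (1 + cos^2) angular law for coherent scatter
static inline double thomson_ct(uint64_t &st) {
  for (;;) {
    double ct = 2.0 * runif01(st) - 1.0;
    if (runif01(st) <= 0.5 * (1.0 + ct * ct)) return ct;
  }
}

// rotate unit vector u by polar angle (cos ct) and uniform azimuth
static inline void rotate_dir(double u[3], double ct, uint64_t &st) {
  double stheta = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * runif01(st);
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.999999) {
    u[0] = stheta * cp;
    u[1] = stheta * sp;
    u[2] = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double r = std::sqrt(1.0 - uz * uz);
    u[0] = ux * ct + stheta * (ux * uz * cp - uy * sp) / r;
    u[1] = uy * ct + stheta * (uy * uz * cp + ux * sp) / r;
    u[2] = uz * ct - r * stheta * cp;
  }
  double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= n; u[1] /= n; u[2] /= n;
}

struct TrackResult {
  double deposited = 0.0;
  double escaped = 0.0;
  double first_depth = -1.0;  // distance to first real interaction, or -1
  bool bad = false;
};

// transport a photon; deposits go into dep[voxel] (+= keV)
static TrackResult track_photon(const Grid &g, const Xs &xs, double pos[3],
                                double dir[3], double E, double pcut,
                                bool woodcock, uint64_t &st, double *dep) {
  TrackResult res;
  double start[3] = {pos[0], pos[1], pos[2]};
  bool entered = false;
  for (int nscat = 0; nscat < 10000; ++nscat) {
    if (!std::isfinite(pos[0] + pos[1] + pos[2] + dir[0] + dir[1] + dir[2]) ||
        !std::isfinite(E) || E <= 0.0) {
      res.bad = true;
      return res;
    }
    double tmin, tmax;
    if (!ray_box(g, pos, dir, tmin, tmax)) {
      res.escaped += E;
      return res;
    }
    double t = (tmin > 0.0) ? tmin + 1e-9 : 1e-9;
    if (!entered) {
      // first-interaction depth is measured from the phantom entry point
      start[0] = pos[0] + t * dir[0];
      start[1] = pos[1] + t * dir[1];
      start[2] = pos[2] + t * dir[2];
      entered = true;
    }
    long v = -1;
    bool interacted = false;
    if (woodcock) {
      double mu_maj = majorant_mu(xs, E);
      for (;;) {
        t += -std::log(runif01(st)) / mu_maj;
        if (t >= tmax) break;
        double p[3] = {pos[0] + t * dir[0], pos[1] + t * dir[1],
                       pos[2] + t * dir[2]};
        v = voxel_index(g, p);
        if (v < 0) break;
        int m = g.mat[v];
        double ph, ic, co;
        mu_parts(xs, m, E, ph, ic, co);
        double mu_vox = g.rho[v] * (ph + ic + co) * 0.1;  // per mm
        if (runif01(st) * mu_maj <= mu_vox) {
          interacted = true;
          break;
        }
      }
    } else {
      // voxel-by-voxel ray stepping: accumulate optical depth to a sampled
      // target, independent of the majorant
      double tau = -std::log(runif01(st));
      double tcur = t;
      while (tcur < tmax) {
        double p[3] = {pos[0] + tcur * dir[0], pos[1] + tcur * dir[1],
                       pos[2] + tcur * dir[2]};
        long vv = voxel_index(g, p);
        if (vv < 0) break;
        // distance to next voxel boundary along each axis
        double texit = tmax;
        const double lo[3] = {g.x0, g.y0, g.z0};
        const double dd[3] = {g.dx, g.dy, g.dz};
        for (int a = 0; a < 3; ++a) {
          if (std::fabs(dir[a]) < 1e-12) continue;
          double rel = (p[a] - lo[a]) / dd[a];
          double bnd = (dir[a] > 0) ? (std::floor(rel) + 1.0) * dd[a] + lo[a]
                                    : std::floor(rel) * dd[a] + lo[a];
          double ta = tcur + (bnd - p[a]) / dir[a];
          if (ta > tcur && ta < texit) texit = ta;
        }
        texit += 1e-9;
        int m = g.mat[vv];
        double ph, ic, co;
        mu_parts(xs, m, E, ph, ic, co);
        double mu_vox = g.rho[vv] * (ph + ic + co) * 0.1;
        double seg = texit - tcur;
        if (mu_vox * seg >= tau) {
          t = tcur + tau / std::max(mu_vox, 1e-300);
          v = vv;
          interacted = true;
          break;
        }
        tau -= mu_vox * seg;
        tcur = texit;
      }
    }
    if (!interacted) {
      res.escaped += E;
      return res;
    }
    double p[3] = {pos[0] + t * dir[0], pos[1] + t * dir[1],
                   pos[2] + t * dir[2]};
    if (res.first_depth < 0.0) {
      double ddx = p[0] - start[0], ddy = p[1] - start[1],
             ddz = p[2] - start[2];
      res.first_depth = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
    }
    int m = g.mat[v];
    double ph, ic, co;
    mu_parts(xs, m, E, ph, ic, co);
    double total = ph + ic + co;
    double u = runif01(st) * total;
    if (u < ph) {
      // photoelectric: local absorption
      dep[v] += E;
      res.deposited += E;
      return res;
    } else if (u < ph + ic) {
      // Compton: kerma approximation, deposit transferred energy locally
      double k = E / 510.99895;
      double x = kahn_x(k, st);
      double Eprime = E / x;
      double ct = 1.0 - (x - 1.0) / k;
      dep[v] += E - Eprime;
      res.deposited += E - Eprime;
      if (Eprime <= pcut) {
        dep[v] += Eprime;
        res.deposited += Eprime;
        return res;
      }
      E = Eprime;
      rotate_dir(dir, ct, st);
    } else {
      // Rayleigh: redirect, no energy loss
      rotate_dir(dir, thomson_ct(st), st);
    }
    pos[0] = p[0]; pos[1] = p[1]; pos[2] = p[2];
  }
  res.bad = true;
  return res;
}

static Grid make_grid(const NumericVector &rho, const IntegerVector &mat,
                      const IntegerVector &dims, const NumericVector &spacing,
                      const NumericVector &origin) {
  Grid g;
  g.rho = rho.begin();
  g.mat = mat.begin();
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = spacing[0]; g.dy = spacing[1]; g.dz = spacing[2];
  g.x0 = origin[0] - g.dx / 2; g.y0 = origin[1] - g.dy / 2;
  g.z0 = origin[2] - g.dz / 2;
  g.x1 = g.x0 + g.nx * g.dx;
  g.y1 = g.y0 + g.ny * g.dy;
  g.z1 = g.z0 + g.nz * g.dz;
  return g;
}

static Xs make_xs(const NumericMatrix &photo, const NumericMatrix &incoh,
                  const NumericMatrix &coh, double emin,
                  const NumericVector &rho_max) {
  Xs xs;
  xs.photo = photo.begin();
  xs.incoh = incoh.begin();
  xs.coh = coh.begin();
  xs.nE = photo.nrow();
  xs.nmat = photo.ncol();
  xs.emin = emin;
  xs.majorant.resize(xs.nE);
  for (int e = 0; e < xs.nE; ++e) {
    double mx = 0.0;
    for (int m = 0; m < xs.nmat; ++m) {
      double mu = (photo(e, m) + incoh(e, m) + coh(e, m)) * rho_max[m] * 0.1;
      if (mu > mx) mx = mu;
    }
    xs.majorant[e] = std::max(mx, 1e-12);
  }
  return xs;
}

// [[Rcpp::export]]
List cpp_run_scan(NumericVector rho, IntegerVector mat0, IntegerVector dims,
                  NumericVector spacing, NumericVector origin,
                  NumericMatrix xs_photo, NumericMatrix xs_incoh,
                  NumericMatrix xs_coh, double xs_emin,
                  NumericVector rho_max, NumericVector spec_e,
                  NumericVector spec_cdf, NumericMatrix fields,
                  NumericVector field_cdf, double sad, double fan_half_deg,
                  double focal_r, double beam_w, double iso_cx, double iso_cy,
                  int n_hist, int n_batches, double pcut, double seed,
                  bool woodcock) {
  Grid g = make_grid(rho, mat0, dims, spacing, origin);
  Xs xs = make_xs(xs_photo, xs_incoh, xs_coh, xs_emin, rho_max);
  size_t nvox = g.nvox();
  NumericMatrix deposit(nvox, n_batches);
  NumericVector emitted(n_batches), deposited(n_batches), escaped(n_batches);
  int n_bad = 0;
  int nf = fields.nrow();
  double tan_fan = std::tan(fan_half_deg * M_PI / 180.0);
  uint64_t seed_u = (uint64_t)seed;

  for (int h = 0; h < n_hist; ++h) {
    int b = (int)(((long long)h * n_batches) / n_hist);
    uint64_t st = history_stream(seed_u, (uint64_t)h);
    double *dep = &deposit(0, b);

    // field selection proportional to weight
    double uf = runif01(st);
    int f = (int)(std::lower_bound(field_cdf.begin(), field_cdf.end(), uf) -
                  field_cdf.begin());
    if (f >= nf) f = nf - 1;
    double th = fields(f, 0) * M_PI / 180.0;
    double iso_z = fields(f, 1);

    // energy from the spectrum's discrete distribution
    double ue = runif01(st);
    int ei = (int)(std::lower_bound(spec_cdf.begin(), spec_cdf.end(), ue) -
                   spec_cdf.begin());
    if (ei >= spec_e.size()) ei = spec_e.size() - 1;
    double E = spec_e[ei];

    // focal disc emission point
    double e1x = -std::sin(th), e1y = std::cos(th);
    double r = focal_r * std::sqrt(runif01(st));
    double psi = 2.0 * M_PI * runif01(st);
    double fx = r * std::cos(psi), fz = r * std::sin(psi);
    double pos[3] = {iso_cx + sad * std::cos(th) + fx * e1x,
                     iso_cy + sad * std::sin(th) + fx * e1y, iso_z + fz};
    // aim point uniform over the collimated aperture at the isocenter plane
    double t_off = (2.0 * runif01(st) - 1.0) * sad * tan_fan;
    double z_off = (runif01(st) - 0.5) * beam_w;
    double dir[3] = {iso_cx + t_off * e1x - pos[0],
                     iso_cy + t_off * e1y - pos[1], iso_z + z_off - pos[2]};
    double nrm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                           dir[2] * dir[2]);
    dir[0] /= nrm; dir[1] /= nrm; dir[2] /= nrm;

    emitted[b] += E;
    TrackResult tr = track_photon(g, xs, pos, dir, E, pcut, woodcock, st,
                                  dep);
    deposited[b] += tr.deposited;
    escaped[b] += tr.escaped;
    if (tr.bad) {
      ++n_bad;
      escaped[b] += E - tr.deposited;  // keep the energy balance closed
    }
  }
  return List::create(_["deposit"] = deposit, _["emitted"] = emitted,
                      _["deposited"] = deposited, _["escaped"] = escaped,
                      _["n_bad"] = n_bad);
}

// [[Rcpp::export]]
List cpp_pencil(NumericVector rho, IntegerVector mat0, IntegerVector dims,
                NumericVector spacing, NumericVector origin,
                NumericMatrix xs_photo, NumericMatrix xs_incoh,
                NumericMatrix xs_coh, double xs_emin, NumericVector rho_max,
                double energy, int n, double seed, NumericVector start,
                NumericVector direction, double pcut, bool woodcock) {
  Grid g = make_grid(rho, mat0, dims, spacing, origin);
  Xs xs = make_xs(xs_photo, xs_incoh, xs_coh, xs_emin, rho_max);
  NumericVector deposit(g.nvox());
  NumericVector depths(n, NA_REAL);
  double emitted = 0.0, dep_tot = 0.0, esc_tot = 0.0;
  int n_bad = 0;
  uint64_t seed_u = (uint64_t)seed;
  for (int h = 0; h < n; ++h) {
    uint64_t st = history_stream(seed_u, (uint64_t)h);
    double pos[3] = {start[0], start[1], start[2]};
    double dir[3] = {direction[0], direction[1], direction[2]};
    emitted += energy;
    TrackResult tr = track_photon(g, xs, pos, dir, energy, pcut, woodcock,
                                  st, deposit.begin());
    dep_tot += tr.deposited;
    esc_tot += tr.escaped;
    if (tr.first_depth >= 0.0) depths[h] = tr.first_depth;
    if (tr.bad) ++n_bad;
  }
  return List::create(_["deposit"] = deposit, _["first_depth"] = depths,
                      _["emitted"] = emitted, _["deposited"] = dep_tot,
                      _["escaped"] = esc_tot, _["n_bad"] = n_bad);
}

// [[Rcpp::export]]
NumericVector cpp_sample_compton(double energy, int n, double seed) {
  NumericVector out(n);
  double k = energy / 510.99895;
  uint64_t seed_u = (uint64_t)seed;
  for (int i = 0; i < n; ++i) {
    uint64_t st = history_stream(seed_u, (uint64_t)i);
    out[i] = energy / kahn_x(k, st);
  }
  return out;
}
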