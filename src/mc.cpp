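// Time-resolved voxelized fluorescence Monte Carlo engine.
//
// Models excitation photons launched from a fiber on the z = 0 surface of a
// homogeneous turbid box, Henyey-Greenstein scattering, continuous
// Beer-Lambert weight attenuation along exact voxel traversals, Fresnel
// reflection/refraction at the refractive-index-mismatched top surface and
// absorbing lateral/bottom boundaries. Wherever an excitation trajectory
// crosses a fluorophore voxel a fluorescent photon is spawned isotropically
// with statistical weight (upstream survival) * mua * (crossing length) --
// the first-order expansion of 1 - exp(-mua L). Detected fluorescent photons
// feed either a temporal point-spread-function histogram (with exponential
// emission delay and quantum yield) or per-voxel sensitivity volumes gated
// at the requested times (no delay, no yield: decay and yield live in the
// FPDF factorization).
//
// All randomness comes from a private 64-bit Mersenne Twister seeded from R,
// so runs are bitwise reproducible for a fixed seed and single-threaded.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double C0 = 0.299792458;  // mm/ps
constexpr double EPS = 1e-12;
constexpr double GEOM_EPS = 1e-9;

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  // uniform in (0, 1]
  double runif_oc() {
    return (static_cast<double>(eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // uniform in [0, 1)
  double runif_co() {
    return static_cast<double>(eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  double rnorm() {
    // Box-Muller; one value per call (the spare is discarded for simplicity
    // and reproducibility of the call sequence).
    double u1 = runif_oc(), u2 = runif_co();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  double rexp(double mean) { return -mean * std::log(runif_oc()); }
};

struct Grid {
  int nx, ny, nz;
  double h;
  double ox, oy, oz;
  int nvox() const { return nx * ny * nz; }
  int clampi(double x, double o, int n) const {
    int i = static_cast<int>(std::floor((x - o) / h));
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
  int index(int ix, int iy, int iz) const { return ix + nx * (iy + ny * iz); }
};

struct Params {
  Grid grid;
  const int* mask;        // fluorophore mask, length nvox
  double mua, mus, g, n;  // background optics
  double gamma, tau;      // fluorophore
  double c;               // mm/ps in medium
  double src_x, src_y, det_x, det_y;
  double fiber_radius;
  double theta_cr;        // radians, in-medium
  double sigma_launch;    // radians, std of truncated-Gaussian polar angle
  double max_time;        // ps
  double roulette_threshold, roulette_survive;
  double cos_theta_cr;    // cached acceptance cosine
  double disk_area;       // detector disk area (mm^2)
  double omega_cone;      // acceptance-cone solid angle 2 pi (1 - cos)
  double nee_dmin;        // hybrid split distance (mm): final legs shorter
                          // than this are scored by analog detection, longer
                          // ones by the analytic next-event estimate
  double adj_Q;           // adjoint source strength: Area * 2pi int T cos sin
  std::vector<int> cid;   // voxel -> compact fluorophore index (-1 outside)
  int n_mask;
  // fluorophore-mask bounding box (mm), for fast leg advancement
  bool mask_empty;
  double bx0, bx1, by0, by1, bz0, bz1;
};

// Accumulation context for next-event estimation: at every fluorescent
// emission or scattering vertex inside the acceptance cone over the detector
// the analytic probability of an unscattered flight to the detector disk is
// scored, with the Fresnel transmission and the solid angle of the disk.
struct NeeCtx {
  bool want_hist, want_sens;
  double* hist;
  int nbins;
  double bin_width;
  double* sens;      // nvox x ngates, column-major
  int nvox, ngates;
  const double* gates;
  double gamma;
  // per-photon state
  double delay;
  int voxel;
  // tallies
  double contrib_weight;
  double n_contrib;
};

inline double fresnel_reflectance(double ci, double n);

inline double hg_phase(double c, double g) {
  double den = 1.0 + g * g - 2.0 * g * c;
  return (1.0 - g * g) / (4.0 * M_PI * den * std::sqrt(den));
}

// Track-length deposition tally: per fluorophore voxel and time bin, the
// attenuated path length of the photon. Used by the factorized (pair)
// estimator of the sensitivity function: the excitation fluence from the
// source and the adjoint fluence from the detector are tallied in separate
// runs and combined by temporal convolution per voxel.
struct DepositCtx {
  double* dep;  // n_mask x nbins, column-major
  int n_mask, nbins;
  double bin_width;
};

inline void nee_tally(const Params& P, NeeCtx& N, double contrib,
                      double t_arr) {
  if (contrib <= 0) return;
  N.contrib_weight += contrib;
  N.n_contrib += 1.0;
  if (N.want_sens) {
    for (int gi = 0; gi < N.ngates; ++gi)
      if (t_arr <= N.gates[gi]) N.sens[N.voxel + N.nvox * gi] += contrib;
  }
  if (N.want_hist) {
    double ta = t_arr + N.delay;
    int b = static_cast<int>(ta / N.bin_width);
    if (b >= 0 && b < N.nbins) N.hist[b] += contrib * N.gamma;
  }
}

inline void nee_score(const Params& P, NeeCtx& N, double x, double y,
                      double z, double t, double w, double ux, double uy,
                      double uz, bool isotropic) {
  double dxd = P.det_x - x, dyd = P.det_y - y, dz = z - P.grid.oz;
  if (dz <= 0) return;
  double d2 = dxd * dxd + dyd * dyd + dz * dz;
  double d = std::sqrt(d2);
  double cos_i = dz / d;  // internal angle with the surface normal
  if (cos_i < P.cos_theta_cr) return;  // outside the acceptance cone
  if (d < P.nee_dmin) return;          // short final legs are scored analog
  double phase;
  if (isotropic) {
    phase = 1.0 / (4.0 * M_PI);
  } else {
    double c = (ux * dxd + uy * dyd - uz * dz) / d;  // cos to detector dir
    // direction to the detector is (dxd, dyd, -dz)/d
    phase = hg_phase(c, P.g);
  }
  // Solid angle of accepted directions: the detector disk seen from the
  // vertex, capped by the acceptance cone (the point-disk formula diverges
  // at small distances; nearby the cone is the binding constraint).
  double dOmega = std::min(P.disk_area * cos_i / d2, P.omega_cone);
  double T = 1.0 - fresnel_reflectance(cos_i, P.n);
  double contrib =
      w * phase * dOmega * T * std::exp(-(P.mus + P.mua) * d);
  nee_tally(P, N, contrib, t + d / P.c);
}

struct Photon {
  double x, y, z;
  double ux, uy, uz;
  double w;
  double t;
  double t_cap;  // photon-specific tracking limit (ps)
};

struct Spawn {
  double x, y, z;
  double t;
  double w;   // upstream survival * mua * crossing length
  int voxel;  // conversion voxel index
};

// Optional per-history recorder used by the trace entry point.
struct Recorder {
  std::vector<double> vx, vy, vz, vt, vw;               // excitation vertices
  std::vector<double> sx, sy, sz, st, sw, sdelay;       // spawns
  std::vector<int> svox;
  std::vector<int> det_spawn;                            // 1-based spawn index
  std::vector<double> det_t, det_w, det_x, det_y, det_angle;
  std::vector<double> exit_xyzt;                         // excitation exit x,y,z,t,w
};

inline void record_vertex(Recorder* rec, const Photon& p) {
  if (!rec) return;
  rec->vx.push_back(p.x); rec->vy.push_back(p.y); rec->vz.push_back(p.z);
  rec->vt.push_back(p.t); rec->vw.push_back(p.w);
}

// Henyey-Greenstein deflection cosine.
inline double hg_cos(Rng& rng, double g) {
  if (std::fabs(g) < 1e-12) return 2.0 * rng.runif_co() - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif_co());
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Rotate direction u by polar angle (cos ct) and azimuth phi.
inline void rotate_direction(double ct, double phi, double& ux, double& uy,
                             double& uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    double sign = uz >= 0 ? 1.0 : -1.0;
    ux = st * cp;
    uy = st * sp;
    uz = sign * ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// Unpolarized Fresnel reflectance for internal incidence cosine ci,
// medium index n -> external index 1.
inline double fresnel_reflectance(double ci, double n) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n * si;  // Snell: n sin(theta_i) = 1 * sin(theta_t)
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n * ci - ct) / (n * ci + ct);
  double rp = (n * ct - ci) / (n * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

inline void advance_simple(const Params& P, Photon& p, double len) {
  p.x += p.ux * len; p.y += p.uy * len; p.z += p.uz * len;
  p.w *= std::exp(-P.mua * len);
  p.t += len / P.c;
}

// Clip the ray segment [0, len] from p to the mask bounding box; returns
// false when there is no intersection.
inline bool clip_to_bbox(const Params& P, const Photon& p, double len,
                         double& t0, double& t1) {
  t0 = 0.0; t1 = len;
  const double pos[3] = {p.x, p.y, p.z};
  const double dir[3] = {p.ux, p.uy, p.uz};
  const double lo[3] = {P.bx0, P.by0, P.bz0};
  const double hi[3] = {P.bx1, P.by1, P.bz1};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < EPS) {
      if (pos[a] < lo[a] || pos[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - pos[a]) / dir[a];
      double tb = (hi[a] - pos[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
  }
  return t1 > t0;
}

// Traverse voxels from p along (ux,uy,uz) for distance len inside the grid
// box, attenuating the photon weight and advancing time. When `spawns` is
// non-null, a fluorescent spawn is emitted for every fluorophore-voxel
// crossing with weight = (weight at segment start) * mua * segment length.
// Voxel stepping is only needed where spawning can occur, so legs (or leg
// portions) outside the fluorophore bounding box are advanced in one step;
// the medium is homogeneous, so the attenuation is identical.
// Returns false if max_time was exceeded.
inline bool traverse_leg(const Params& P, Photon& p, double len,
                         std::vector<Spawn>* spawns,
                         DepositCtx* dep = nullptr) {
  const Grid& G = P.grid;
  if ((spawns == nullptr && dep == nullptr) || P.mask_empty) {
    advance_simple(P, p, len);
    return p.t <= p.t_cap;
  }
  double c0, c1;
  if (!clip_to_bbox(P, p, len, c0, c1)) {
    advance_simple(P, p, len);
    return p.t <= p.t_cap;
  }
  if (c0 > 0) advance_simple(P, p, c0);
  double tail = len - c1;
  len = c1 - c0;
  double remaining = len;
  // Current voxel (nudge inward to be robust on boundaries).
  double px = p.x + p.ux * GEOM_EPS, py = p.y + p.uy * GEOM_EPS,
         pz = p.z + p.uz * GEOM_EPS;
  int ix = G.clampi(px, G.ox, G.nx);
  int iy = G.clampi(py, G.oy, G.ny);
  int iz = G.clampi(pz, G.oz, G.nz);
  int sx = p.ux > 0 ? 1 : -1, sy = p.uy > 0 ? 1 : -1, sz = p.uz > 0 ? 1 : -1;
  double inv_ux = std::fabs(p.ux) > EPS ? 1.0 / p.ux : 0.0;
  double inv_uy = std::fabs(p.uy) > EPS ? 1.0 / p.uy : 0.0;
  double inv_uz = std::fabs(p.uz) > EPS ? 1.0 / p.uz : 0.0;
  auto tmax_axis = [&](double pos, double o, int i, int s, double inv) {
    if (inv == 0.0) return std::numeric_limits<double>::infinity();
    double edge = o + (i + (s > 0 ? 1 : 0)) * G.h;
    return (edge - pos) * inv;
  };
  double tx = tmax_axis(p.x, G.ox, ix, sx, inv_ux);
  double ty = tmax_axis(p.y, G.oy, iy, sy, inv_uy);
  double tz = tmax_axis(p.z, G.oz, iz, sz, inv_uz);
  double tdx = inv_ux == 0.0 ? std::numeric_limits<double>::infinity()
                             : std::fabs(G.h * inv_ux);
  double tdy = inv_uy == 0.0 ? std::numeric_limits<double>::infinity()
                             : std::fabs(G.h * inv_uy);
  double tdz = inv_uz == 0.0 ? std::numeric_limits<double>::infinity()
                             : std::fabs(G.h * inv_uz);
  double traveled = 0.0;
  while (remaining > GEOM_EPS) {
    double tnext = std::min(tx, std::min(ty, tz));
    double seg = std::min(tnext - traveled, remaining);
    if (seg < 0) seg = 0;
    int vox = G.index(ix, iy, iz);
    if (dep && P.mask[vox] && seg > 0) {
      int b = static_cast<int>((p.t + 0.5 * seg / P.c) / dep->bin_width);
      if (b >= 0 && b < dep->nbins)
        dep->dep[P.cid[vox] + dep->n_mask * b] += p.w * seg;
    }
    if (spawns && P.mask[vox] && seg > 0) {
      Spawn s;
      double half = 0.5 * seg;
      s.x = p.x + p.ux * half;
      s.y = p.y + p.uy * half;
      s.z = p.z + p.uz * half;
      s.t = p.t + half / P.c;
      s.w = p.w * P.mua * seg;  // first-order conversion factor
      s.voxel = vox;
      spawns->push_back(s);
    }
    // advance over the segment
    p.x += p.ux * seg; p.y += p.uy * seg; p.z += p.uz * seg;
    p.w *= std::exp(-P.mua * seg);
    p.t += seg / P.c;
    traveled += seg;
    remaining -= seg;
    if (p.t > p.t_cap) return false;
    if (remaining <= GEOM_EPS) break;
    // step into the next voxel
    if (tx <= ty && tx <= tz) { ix += sx; tx += tdx; }
    else if (ty <= tz) { iy += sy; ty += tdy; }
    else { iz += sz; tz += tdz; }
    if (ix < 0 || ix >= G.nx || iy < 0 || iy >= G.ny || iz < 0 || iz >= G.nz)
      break;  // numerically at the box boundary; caller handles it
  }
  if (tail > 0) advance_simple(P, p, tail);
  return p.t <= p.t_cap;
}

enum class Fate { Absorbed, EscapedTop, EscapedOther, TimedOut, Detected };

// Propagate a photon until it leaves the box, is rouletted away, or runs out
// of time. For excitation photons (spawns != nullptr) fluorescent spawns are
// collected. For fluorescent photons (detect == true) a successful exit
// through the detector disk within the acceptance cone counts as detection;
// exit position/angle are reported through out_*.
Fate propagate(const Params& P, Rng& rng, Photon& p,
               std::vector<Spawn>* spawns, bool detect, Recorder* rec,
               bool rec_vertices, NeeCtx* nee = nullptr,
               DepositCtx* dep = nullptr, double* out_x = nullptr,
               double* out_y = nullptr, double* out_angle = nullptr) {
  const Grid& G = P.grid;
  const double xmax = G.ox + G.nx * G.h, ymax = G.oy + G.ny * G.h,
               zmax = G.oz + G.nz * G.h;
  if (rec && rec_vertices) record_vertex(rec, p);
  double lvx = p.x, lvy = p.y, lvz = p.z;  // last direction-change vertex
  bool clean_leg = true;                   // no reflection since then
  for (;;) {
    double s = rng.rexp(1.0 / P.mus);  // free path, scattering only
    while (s > GEOM_EPS) {
      // Distance to the box boundary along the current direction.
      double tb = std::numeric_limits<double>::infinity();
      int bface = 0;  // 1 top (z=0), 2 other
      auto upd = [&](double t, int face) {
        if (t > GEOM_EPS && t < tb) { tb = t; bface = face; }
      };
      if (p.uz < -EPS) upd((G.oz - p.z) / p.uz, 1);
      if (p.uz > EPS) upd((zmax - p.z) / p.uz, 2);
      if (p.ux < -EPS) upd((G.ox - p.x) / p.ux, 2);
      if (p.ux > EPS) upd((xmax - p.x) / p.ux, 2);
      if (p.uy < -EPS) upd((G.oy - p.y) / p.uy, 2);
      if (p.uy > EPS) upd((ymax - p.y) / p.uy, 2);
      bool hit_boundary = std::isfinite(tb) && tb <= s;
      double leg = hit_boundary ? tb : s;
      bool alive = traverse_leg(P, p, leg, spawns, dep);
      if (rec && rec_vertices) record_vertex(rec, p);
      if (!alive) return Fate::TimedOut;
      s -= leg;
      if (hit_boundary) {
        // reached a boundary before completing the free path
        if (bface == 1) {
          double ci = -p.uz;  // internal incidence cosine
          double R = fresnel_reflectance(ci, P.n);
          if (rng.runif_co() < R) {
            p.uz = -p.uz;  // specular reflection, continue remaining path
            p.z = G.oz + GEOM_EPS;
            clean_leg = false;
            continue;
          }
          // escape through the top surface
          if (nee && clean_leg) {
            // analog completion of the hybrid estimator: final legs shorter
            // than the split distance were excluded from next-event scoring
            double ddx = p.x - P.det_x, ddy = p.y - P.det_y;
            double ci = -p.uz;
            double lx = p.x - lvx, ly = p.y - lvy, lz = p.z - lvz;
            double dleg = std::sqrt(lx * lx + ly * ly + lz * lz);
            if (ddx * ddx + ddy * ddy <=
                    P.fiber_radius * P.fiber_radius &&
                ci >= P.cos_theta_cr && dleg < P.nee_dmin)
              nee_tally(P, *nee, p.w, p.t);
          }
          if (detect) {
            double dx = p.x - P.det_x, dy = p.y - P.det_y;
            double theta = std::acos(std::min(1.0, std::max(-1.0, ci)));
            bool in_disk =
                dx * dx + dy * dy <= P.fiber_radius * P.fiber_radius;
            if (out_x) { *out_x = p.x; *out_y = p.y; *out_angle = theta; }
            if (in_disk && theta <= P.theta_cr) return Fate::Detected;
          }
          return Fate::EscapedTop;
        }
        return Fate::EscapedOther;  // absorbing lateral/bottom boundaries
      }
    }
    // scattering event; next-event estimate with the incoming direction
    if (nee)
      nee_score(P, *nee, p.x, p.y, p.z, p.t, p.w, p.ux, p.uy, p.uz, false);
    lvx = p.x; lvy = p.y; lvz = p.z; clean_leg = true;
    double ct = hg_cos(rng, P.g);
    double phi = 2.0 * M_PI * rng.runif_co();
    rotate_direction(ct, phi, p.ux, p.uy, p.uz);
    // Russian roulette
    if (p.w < P.roulette_threshold) {
      if (rng.runif_co() < P.roulette_survive) p.w /= P.roulette_survive;
      else return Fate::Absorbed;
    }
  }
}

// Launch an excitation photon: position uniform on the source disk, polar
// angle from a zero-mean Gaussian truncated at theta_cr (rejection), azimuth
// uniform, weight 1, time 0.
Photon launch(const Params& P, Rng& rng) {
  Photon p;
  double r = P.fiber_radius * std::sqrt(rng.runif_co());
  double a = 2.0 * M_PI * rng.runif_co();
  p.x = P.src_x + r * std::cos(a);
  p.y = P.src_y + r * std::sin(a);
  p.z = P.grid.oz;
  double theta;
  if (P.sigma_launch <= 0) {
    theta = 0.0;
  } else {
    do {
      theta = std::fabs(P.sigma_launch * rng.rnorm());
    } while (theta > P.theta_cr);
  }
  double phi = 2.0 * M_PI * rng.runif_co();
  p.ux = std::sin(theta) * std::cos(phi);
  p.uy = std::sin(theta) * std::sin(phi);
  p.uz = std::cos(theta);
  p.w = 1.0;
  p.t = 0.0;
  p.t_cap = P.max_time;
  return p;
}

// Launch an adjoint photon from the detector: position uniform on the
// detector disk, polar angle with density proportional to
// T(theta) cos(theta) sin(theta) on [0, theta_cr] (rejection sampling),
// heading into the medium. Represents the detector response by reciprocity.
Photon launch_adjoint(const Params& P, Rng& rng) {
  Photon p;
  double r = P.fiber_radius * std::sqrt(rng.runif_co());
  double a = 2.0 * M_PI * rng.runif_co();
  p.x = P.det_x + r * std::cos(a);
  p.y = P.det_y + r * std::sin(a);
  p.z = P.grid.oz;
  double fmax = (1.0 - fresnel_reflectance(std::cos(P.theta_cr), P.n)) *
                std::sin(P.theta_cr) + 1e-12;
  double theta;
  for (;;) {
    theta = P.theta_cr * rng.runif_co();
    double f = (1.0 - fresnel_reflectance(std::cos(theta), P.n)) *
               std::cos(theta) * std::sin(theta);
    if (rng.runif_co() * fmax <= f) break;
  }
  double phi = 2.0 * M_PI * rng.runif_co();
  p.ux = std::sin(theta) * std::cos(phi);
  p.uy = std::sin(theta) * std::sin(phi);
  p.uz = std::cos(theta);
  p.w = 1.0;
  p.t = 0.0;
  p.t_cap = P.max_time;
  return p;
}

Params make_params(List grid, IntegerVector mask, List medium, List fluor,
                   List probe_link, double max_time) {
  Params P;
  IntegerVector shp = grid["shape"];
  NumericVector org = grid["origin"];
  P.grid.nx = shp[0]; P.grid.ny = shp[1]; P.grid.nz = shp[2];
  P.grid.h = as<double>(grid["voxel_size"]);
  P.grid.ox = org[0]; P.grid.oy = org[1]; P.grid.oz = org[2];
  if (mask.size() != P.grid.nvox()) stop("mask size does not match grid");
  P.mask = INTEGER(mask);
  P.mua = as<double>(medium["mua"]);
  P.mus = as<double>(medium["mus"]);
  P.g = as<double>(medium["g"]);
  P.n = as<double>(medium["n"]);
  P.c = C0 / P.n;
  P.gamma = as<double>(fluor["gamma"]);
  P.tau = as<double>(fluor["tau"]);
  P.src_x = as<double>(probe_link["sx"]);
  P.src_y = as<double>(probe_link["sy"]);
  P.det_x = as<double>(probe_link["dx"]);
  P.det_y = as<double>(probe_link["dy"]);
  P.fiber_radius = as<double>(probe_link["fiber_radius"]);
  P.theta_cr = as<double>(probe_link["theta_cr"]);  // radians
  P.sigma_launch = as<double>(probe_link["sigma_launch"]);
  P.max_time = max_time;
  P.roulette_threshold = 1e-4;
  P.roulette_survive = 0.1;
  P.cos_theta_cr = std::cos(P.theta_cr);
  P.disk_area = M_PI * P.fiber_radius * P.fiber_radius;
  P.omega_cone = 2.0 * M_PI * (1.0 - P.cos_theta_cr);
  P.nee_dmin = 1.0;  // mm, about 2.6 scattering mean free paths
  P.cid.assign(P.grid.nvox(), -1);
  P.n_mask = 0;
  for (int i = 0; i < P.grid.nvox(); ++i)
    if (P.mask[i]) P.cid[i] = P.n_mask++;
  // adjoint detector-source strength: disk area times the angular integral
  // of T(theta) cos(theta) over the acceptance cone (Simpson's rule)
  {
    const int M = 128;
    double hth = P.theta_cr / M, s = 0.0;
    for (int k = 0; k <= M; ++k) {
      double th = k * hth;
      double f = (1.0 - fresnel_reflectance(std::cos(th), P.n)) *
                 std::cos(th) * std::sin(th);
      double wgt = (k == 0 || k == M) ? 1.0 : (k % 2 ? 4.0 : 2.0);
      s += wgt * f;
    }
    P.adj_Q = P.disk_area * 2.0 * M_PI * (s * hth / 3.0);
  }
  // fluorophore bounding box (in mm), padded by one voxel
  P.mask_empty = true;
  int x0 = P.grid.nx, x1 = -1, y0 = P.grid.ny, y1 = -1, z0 = P.grid.nz,
      z1 = -1;
  for (int iz = 0; iz < P.grid.nz; ++iz)
    for (int iy = 0; iy < P.grid.ny; ++iy)
      for (int ix = 0; ix < P.grid.nx; ++ix)
        if (P.mask[P.grid.index(ix, iy, iz)]) {
          P.mask_empty = false;
          if (ix < x0) x0 = ix;
          if (ix > x1) x1 = ix;
          if (iy < y0) y0 = iy;
          if (iy > y1) y1 = iy;
          if (iz < z0) z0 = iz;
          if (iz > z1) z1 = iz;
        }
  if (!P.mask_empty) {
    P.bx0 = P.grid.ox + x0 * P.grid.h; P.bx1 = P.grid.ox + (x1 + 1) * P.grid.h;
    P.by0 = P.grid.oy + y0 * P.grid.h; P.by1 = P.grid.oy + (y1 + 1) * P.grid.h;
    P.bz0 = P.grid.oz + z0 * P.grid.h; P.bz1 = P.grid.oz + (z1 + 1) * P.grid.h;
  }
  return P;
}

}  // namespace

// Core simulation. mode: 1 = ftpsf histogram, 2 = sensitivity volumes,
// 3 = both. Detection uses next-event estimation: every fluorescent emission
// or scattering vertex scores the analytic probability of an unscattered
// flight into the detector disk within the acceptance cone (times Fresnel
// transmission), which removes the variance of analog detection through a
// sub-millimetre fiber. The sensitivity tally gates on the transport arrival
// time; the histogram additionally carries the exponential emission delay
// and the quantum yield. walk_prob < 1 thins the scattered fluorescent walks
// (weight-compensated, unbiased); the direct emission-vertex estimate is
// always scored for every spawn.
// [[Rcpp::export]]
List mc_run(List grid, IntegerVector mask, List medium, List fluor,
            List probe_link, double n_histories, int seed, int mode,
            NumericVector gates, double bin_width, double max_time,
            double walk_prob, double nee_split) {
  if (n_histories < 1) stop("mc_run: n_histories must be >= 1");
  if (walk_prob <= 0 || walk_prob > 1)
    stop("mc_run: walk_prob must lie in (0, 1]");
  Params P = make_params(grid, mask, medium, fluor, probe_link, max_time);
  if (nee_split > 0) P.nee_dmin = nee_split;
  Rng rng(static_cast<uint64_t>(seed));

  const bool want_hist = (mode == 1 || mode == 3);
  const bool want_sens = (mode == 2 || mode == 3);
  const int ngates = gates.size();
  int nbins = want_hist ? static_cast<int>(std::ceil(max_time / bin_width)) : 0;
  NumericVector hist(std::max(nbins, 0));
  NumericMatrix sens(want_sens ? P.grid.nvox() : 0, want_sens ? ngates : 0);

  NeeCtx N{};
  N.want_hist = want_hist;
  N.want_sens = want_sens;
  N.hist = want_hist ? REAL(hist) : nullptr;
  N.nbins = nbins;
  N.bin_width = bin_width;
  N.sens = want_sens ? REAL(sens) : nullptr;
  N.nvox = P.grid.nvox();
  N.ngates = ngates;
  N.gates = ngates ? REAL(gates) : nullptr;
  N.gamma = P.gamma;
  N.contrib_weight = 0.0;
  N.n_contrib = 0.0;

  double launched_w = 0.0;
  std::vector<Spawn> spawns;
  const long long NH = static_cast<long long>(n_histories);

  for (long long h = 0; h < NH; ++h) {
    if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    Photon p = launch(P, rng);
    launched_w += p.w;
    spawns.clear();
    propagate(P, rng, p, &spawns, false, nullptr, false);
    for (const Spawn& s : spawns) {
      N.voxel = s.voxel;
      N.delay = (want_hist && P.tau > 0) ? rng.rexp(P.tau) : 0.0;
      // direct (emission-vertex) estimate, isotropic phase, for every spawn
      nee_score(P, N, s.x, s.y, s.z, s.t, s.w, 0, 0, 0, true);
      // scattered contributions: walk the photon, possibly thinned
      if (walk_prob < 1.0 && rng.runif_co() >= walk_prob) continue;
      Photon f;
      f.x = s.x; f.y = s.y; f.z = s.z;
      f.t = s.t; f.w = s.w / walk_prob;
      // in pure-histogram mode arrivals later than max_time never bin, so
      // the walk can stop once transport time + delay passes the range
      f.t_cap = want_sens ? max_time : max_time - N.delay;
      if (f.t_cap <= f.t) continue;
      double ct = 2.0 * rng.runif_co() - 1.0;
      double phi = 2.0 * M_PI * rng.runif_co();
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      f.ux = st * std::cos(phi); f.uy = st * std::sin(phi); f.uz = ct;
      propagate(P, rng, f, nullptr, false, nullptr, false, &N);
    }
  }

  // per-launched-history normalization: estimates are independent of the
  // history budget (up to MC noise)
  for (int b = 0; b < nbins; ++b) hist[b] /= n_histories;
  if (want_sens)
    for (int gi = 0; gi < ngates; ++gi)
      for (int i = 0; i < N.nvox; ++i) sens(i, gi) /= n_histories;
  List out = List::create(
      _["launched_weight"] = launched_w,
      _["detected_weight"] = N.contrib_weight / n_histories,
      _["n_detected"] = N.n_contrib);
  if (want_hist) out["hist"] = hist;
  if (want_sens) out["sens"] = sens;
  return out;
}


// Track-length deposition run for the factorized sensitivity estimator.
// adjoint = false: excitation photons from the source fiber; true: adjoint
// photons from the detector fiber (reciprocity). Returns the per-history
// normalized deposit matrix (fluorophore voxel x time bin), the 1-based
// voxel indices of the fluorophore voxels, and the adjoint source strength.
// [[Rcpp::export]]
List mc_deposit_run(List grid, IntegerVector mask, List medium, List fluor,
                    List probe_link, double n_histories, int seed,
                    double bin_width, double max_time, bool adjoint) {
  if (n_histories < 1) stop("mc_deposit_run: n_histories must be >= 1");
  Params P = make_params(grid, mask, medium, fluor, probe_link, max_time);
  if (P.n_mask == 0) stop("mc_deposit_run: empty fluorophore mask");
  Rng rng(static_cast<uint64_t>(seed));
  int nbins = static_cast<int>(std::ceil(max_time / bin_width));
  NumericMatrix dep(P.n_mask, nbins);
  DepositCtx D{REAL(dep), P.n_mask, nbins, bin_width};
  const long long NH = static_cast<long long>(n_histories);
  for (long long h = 0; h < NH; ++h) {
    if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    Photon p = adjoint ? launch_adjoint(P, rng) : launch(P, rng);
    propagate(P, rng, p, nullptr, false, nullptr, false, nullptr, &D);
  }
  for (int b = 0; b < nbins; ++b)
    for (int i = 0; i < P.n_mask; ++i) dep(i, b) /= n_histories;
  IntegerVector cids(P.n_mask);
  for (int i = 0; i < P.grid.nvox(); ++i)
    if (P.cid[i] >= 0) cids[P.cid[i]] = i + 1;
  return List::create(_["dep"] = dep, _["voxel"] = cids,
                      _["Q"] = P.adj_Q, _["nbins"] = nbins);
}

// Combine a forward (source) and an adjoint (detector) deposit matrix into
// gated sensitivity values per voxel and/or a temporal point spread
// function. Per voxel the two time series are convolved; the sensitivity at
// a gate is mua * Q / (4 pi V_vox) times either the partial sum of products
// with combined transport time at or below the gate (cumulative gating,
// instant = false) or the product density in the gate's own bin scaled to a
// per-bin value (instantaneous gating, instant = true). The FTPSF
// additionally convolves the summed series with the exponential
// emission-decay density and applies the quantum yield.
// [[Rcpp::export]]
List mc_pair_combine(NumericMatrix dep_fwd, NumericMatrix dep_adj,
                     IntegerVector voxel, int nvox, double voxel_volume,
                     double Q, double mua, double gamma, double tau,
                     NumericVector gates, double bin_width, int mode,
                     bool instant = false, int window_bins = 11) {
  const int nm = dep_fwd.nrow(), B = dep_fwd.ncol();
  if (dep_adj.nrow() != nm || dep_adj.ncol() != B)
    stop("mc_pair_combine: deposit shapes differ");
  const bool want_hist = (mode == 1 || mode == 3);
  const bool want_sens = (mode == 2 || mode == 3);
  const int ngates = gates.size();
  const double scale = mua * Q / (4.0 * M_PI * voxel_volume);
  std::vector<int> gate_bin(ngates);
  for (int gi = 0; gi < ngates; ++gi)
    gate_bin[gi] = static_cast<int>(std::floor(gates[gi] / bin_width));
  NumericMatrix sens(want_sens ? nvox : 0, want_sens ? ngates : 0);
  std::vector<double> S(want_hist ? B : 0, 0.0);
  std::vector<double> a(B), b(B), conv(B);
  for (int v = 0; v < nm; ++v) {
    for (int k = 0; k < B; ++k) { a[k] = dep_fwd(v, k); b[k] = dep_adj(v, k); }
    std::fill(conv.begin(), conv.end(), 0.0);
    for (int j = 0; j < B; ++j) {
      double aj = a[j];
      if (aj == 0.0) continue;
      int kmax = B - 1 - j;
      for (int k = 0; k <= kmax; ++k) conv[j + k] += aj * b[k];
    }
    if (want_hist)
      for (int k = 0; k < B; ++k) S[k] += conv[k];
    if (want_sens) {
      int vi = voxel[v] - 1;
      for (int gi = 0; gi < ngates; ++gi) {
        // combined transport time of bins j and k is about (j + k + 1) bins
        int kb = gate_bin[gi] - 1;
        if (kb >= B) kb = B - 1;
        if (instant) {
          // density in a window matching the measurement chain's smoothing
          // bandwidth, centred on the gate bin
          int half = window_bins / 2;
          int lo = kb - half, hi = kb + half;
          if (lo < 0) lo = 0;
          if (hi >= B) hi = B - 1;
          if (hi >= lo) {
            double s = 0.0;
            for (int k = lo; k <= hi; ++k) s += conv[k];
            sens(vi, gi) = scale * s / (hi - lo + 1);
          }
        } else {
          double scum = 0.0;
          for (int k = 0; k <= kb; ++k) scum += conv[k];
          sens(vi, gi) = scale * scum;
        }
      }
    }
  }
  List out = List::create(_["nbins"] = B);
  if (want_sens) out["sens"] = sens;
  if (want_hist) {
    NumericVector hist(B);
    if (tau > 0) {
      // discrete exponential emission-delay density per bin
      std::vector<double> pd(B);
      double e1 = std::exp(-bin_width / tau);
      pd[0] = 1.0 - e1;
      for (int d = 1; d < B; ++d) pd[d] = pd[d - 1] * e1;
      for (int k = 0; k < B; ++k) {
        if (S[k] == 0.0) continue;
        double sk = gamma * scale * S[k];
        for (int d = 0; d + k < B; ++d) hist[k + d] += sk * pd[d];
      }
    } else {
      for (int k = 0; k < B; ++k) hist[k] = gamma * scale * S[k];
    }
    out["hist"] = hist;
  }
  return out;
}

// Trace a handful of histories, returning full event logs so that R-side
// oracles can recompute attenuation, timing and spawn weights independently.
// [[Rcpp::export]]
List mc_trace(List grid, IntegerVector mask, List medium, List fluor,
              List probe_link, int n_histories, int seed, bool with_delay,
              double max_time) {
  Params P = make_params(grid, mask, medium, fluor, probe_link, max_time);
  Rng rng(static_cast<uint64_t>(seed));
  List histories(n_histories);
  for (int h = 0; h < n_histories; ++h) {
    Recorder rec;
    Photon p = launch(P, rng);
    std::vector<Spawn> spawns;
    propagate(P, rng, p, &spawns, false, &rec, true);
    for (size_t k = 0; k < spawns.size(); ++k) {
      const Spawn& s = spawns[k];
      Photon f;
      f.x = s.x; f.y = s.y; f.z = s.z; f.t = s.t; f.w = s.w;
      f.t_cap = P.max_time;
      double ct = 2.0 * rng.runif_co() - 1.0;
      double phi = 2.0 * M_PI * rng.runif_co();
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      f.ux = st * std::cos(phi); f.uy = st * std::sin(phi); f.uz = ct;
      double delay = (with_delay && P.tau > 0) ? rng.rexp(P.tau) : 0.0;
      rec.sx.push_back(s.x); rec.sy.push_back(s.y); rec.sz.push_back(s.z);
      rec.st.push_back(s.t); rec.sw.push_back(s.w);
      rec.sdelay.push_back(delay);
      rec.svox.push_back(s.voxel + 1);  // 1-based for R
      double ex = NA_REAL, ey = NA_REAL, ang = NA_REAL;
      Fate fate = propagate(P, rng, f, nullptr, true, nullptr, false,
                            nullptr, nullptr, &ex, &ey, &ang);
      if (fate == Fate::Detected) {
        rec.det_spawn.push_back(static_cast<int>(k) + 1);
        rec.det_t.push_back(f.t + delay);
        rec.det_w.push_back(f.w);
        rec.det_x.push_back(ex);
        rec.det_y.push_back(ey);
        rec.det_angle.push_back(ang);
      }
    }
    histories[h] = List::create(
        _["vertices"] = DataFrame::create(_["x"] = rec.vx, _["y"] = rec.vy,
                                          _["z"] = rec.vz, _["t"] = rec.vt,
                                          _["w"] = rec.vw),
        _["spawns"] = DataFrame::create(
            _["x"] = rec.sx, _["y"] = rec.sy, _["z"] = rec.sz,
            _["t"] = rec.st, _["w"] = rec.sw, _["delay"] = rec.sdelay,
            _["voxel"] = rec.svox),
        _["detections"] = DataFrame::create(
            _["spawn"] = rec.det_spawn, _["t"] = rec.det_t,
            _["w"] = rec.det_w, _["x"] = rec.det_x, _["y"] = rec.det_y,
            _["angle"] = rec.det_angle));
  }
  return histories;
}

// Exact voxel traversal of the straight segment p0 -> p1 (test surface).
// [[Rcpp::export]]
List mc_traverse_segment(NumericVector p0, NumericVector p1, List grid) {
  Grid G;
  IntegerVector shp = grid["shape"];
  NumericVector org = grid["origin"];
  G.nx = shp[0]; G.ny = shp[1]; G.nz = shp[2];
  G.h = as<double>(grid["voxel_size"]);
  G.ox = org[0]; G.oy = org[1]; G.oz = org[2];
  double xmax = G.ox + G.nx * G.h, ymax = G.oy + G.ny * G.h,
         zmax = G.oz + G.nz * G.h;
  for (int k = 0; k < 2; ++k) {
    NumericVector p = (k == 0) ? p0 : p1;
    if (p[0] < G.ox - GEOM_EPS || p[0] > xmax + GEOM_EPS ||
        p[1] < G.oy - GEOM_EPS || p[1] > ymax + GEOM_EPS ||
        p[2] < G.oz - GEOM_EPS || p[2] > zmax + GEOM_EPS)
      stop("traverse: segment endpoint outside the grid bounding box");
  }
  double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  std::vector<int> vix, viy, viz;
  std::vector<double> vlen;
  if (len > GEOM_EPS) {
    Photon p;
    p.x = p0[0]; p.y = p0[1]; p.z = p0[2];
    p.ux = dx / len; p.uy = dy / len; p.uz = dz / len;
    p.w = 1.0; p.t = 0.0;
    // reuse traverse_leg with a recording mask trick: walk manually here
    double remaining = len, traveled = 0.0;
    double qx = p.x + p.ux * GEOM_EPS, qy = p.y + p.uy * GEOM_EPS,
           qz = p.z + p.uz * GEOM_EPS;
    int ix = G.clampi(qx, G.ox, G.nx);
    int iy = G.clampi(qy, G.oy, G.ny);
    int iz = G.clampi(qz, G.oz, G.nz);
    int sx = p.ux > 0 ? 1 : -1, sy = p.uy > 0 ? 1 : -1,
        sz = p.uz > 0 ? 1 : -1;
    auto tmax_axis = [&](double pos, double o, int i, int s, double u) {
      if (std::fabs(u) < EPS) return std::numeric_limits<double>::infinity();
      double edge = o + (i + (s > 0 ? 1 : 0)) * G.h;
      return (edge - pos) / u;
    };
    double tx = tmax_axis(p.x, G.ox, ix, sx, p.ux);
    double ty = tmax_axis(p.y, G.oy, iy, sy, p.uy);
    double tz = tmax_axis(p.z, G.oz, iz, sz, p.uz);
    double tdx = std::fabs(p.ux) < EPS
                     ? std::numeric_limits<double>::infinity()
                     : std::fabs(G.h / p.ux);
    double tdy = std::fabs(p.uy) < EPS
                     ? std::numeric_limits<double>::infinity()
                     : std::fabs(G.h / p.uy);
    double tdz = std::fabs(p.uz) < EPS
                     ? std::numeric_limits<double>::infinity()
                     : std::fabs(G.h / p.uz);
    while (remaining > GEOM_EPS) {
      double tnext = std::min(tx, std::min(ty, tz));
      double seg = std::min(tnext - traveled, remaining);
      if (seg > GEOM_EPS) {
        vix.push_back(ix + 1); viy.push_back(iy + 1); viz.push_back(iz + 1);
        vlen.push_back(seg);
      }
      traveled += std::max(seg, 0.0);
      remaining -= std::max(seg, 0.0);
      if (remaining <= GEOM_EPS) break;
      if (tx <= ty && tx <= tz) { ix += sx; tx += tdx; }
      else if (ty <= tz) { iy += sy; ty += tdy; }
      else { iz += sz; tz += tdz; }
      if (ix < 0 || ix >= G.nx || iy < 0 || iy >= G.ny || iz < 0 ||
          iz >= G.nz)
        break;
    }
  }
  return List::create(_["ix"] = vix, _["iy"] = viy, _["iz"] = viz,
                      _["length"] = vlen);
}

// Sampling test surfaces -------------------------------------------------

// [[Rcpp::export]]
NumericVector mc_sample_hg(int n, double g, int seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(rng, g);
  return out;
}

// [[Rcpp::export]]
NumericMatrix mc_sample_launch(int n, double fiber_radius, double theta_cr,
                               double sigma_launch, int seed) {
  Params P{};
  P.grid.oz = 0.0;
  P.src_x = 0.0; P.src_y = 0.0;
  P.fiber_radius = fiber_radius;
  P.theta_cr = theta_cr;
  P.sigma_launch = sigma_launch;
  Rng rng(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    Photon p = launch(P, rng);
    out(i, 0) = p.x; out(i, 1) = p.y; out(i, 2) = p.z;
    out(i, 3) = p.ux; out(i, 4) = p.uy; out(i, 5) = p.uz;
  }
  colnames(out) = CharacterVector::create("x", "y", "z", "ux", "uy", "uz");
  return out;
}

// One relaxed Kaczmarz sweep over all rows of the system W f = g.
// Wt is the transposed sensitivity matrix (I x J, one *column* per SR-link
// row) so each row access is contiguous; row_norms2 holds ||w_j||^2.
// Zero-norm rows are skipped. Returns the updated f.
// [[Rcpp::export]]
NumericVector art_sweep_t(NumericMatrix Wt, NumericVector g, NumericVector f,
                          double lam, NumericVector row_norms2) {
  const int I = Wt.nrow(), J = Wt.ncol();
  if (g.size() != J || f.size() != I || row_norms2.size() != J)
    stop("art_sweep: inconsistent shapes");
  NumericVector out = clone(f);
  double* fp = REAL(out);
  for (int j = 0; j < J; ++j) {
    double nrm2 = row_norms2[j];
    if (nrm2 <= 0) continue;
    const double* wj = &Wt(0, j);
    double dot = 0.0;
    for (int i = 0; i < I; ++i) dot += wj[i] * fp[i];
    double step = lam * (g[j] - dot) / nrm2;
    for (int i = 0; i < I; ++i) fp[i] += step * wj[i];
  }
  return out;
}
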