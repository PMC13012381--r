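// Monte Carlo photon transport for kV-CBCT dosimetry.
//
// Woodcock (delta) tracking through a voxel grid with three interaction
// channels: photoelectric absorption (full local deposit), incoherent
// scattering (Klein-Nishina free-electron sampling, electron energy
// deposited locally under the collision-kerma approximation), and
// coherent scattering (Thomson angular law, no deposit).  Photons below
// the 5 keV cutoff deposit locally; escaping photons are dropped.
// Lengths are cm, energies keV.  The RNG is a counter-seeded PCG32 with
// one independent stream per batch, so results are deterministic for a
// fixed seed and batch structure.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Pcg32 {
  uint64_t state, inc;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uniform() {  // in (0,1)
    return (next() + 1.0) * 2.328306435454494e-10;
  }
};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 vnorm(const Vec3 &a) {
  double n = std::sqrt(vdot(a, a));
  return {a.x / n, a.y / n, a.z / n};
}

// linear interpolation on the uniform 1 keV grid starting at e0
inline double egrid_interp(const double *tab, int ne, double e0, double e) {
  double x = e - e0;
  if (x <= 0) return tab[0];
  int i = static_cast<int>(x);
  if (i >= ne - 1) return tab[ne - 1];
  double f = x - i;
  return tab[i] * (1 - f) + tab[i + 1] * f;
}

// rotate direction d by polar angle with cosine c and uniform azimuth
inline Vec3 rotate_dir(const Vec3 &d, double c, double phi) {
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  Vec3 u, v;
  if (std::fabs(d.z) < 0.99999) {
    double n = std::sqrt(d.x * d.x + d.y * d.y);
    u = {-d.y / n, d.x / n, 0.0};
    v = {-d.z * d.x / n, -d.z * d.y / n, n};
  } else {
    u = {1.0, 0.0, 0.0};
    v = {0.0, (d.z > 0 ? 1.0 : -1.0), 0.0};
  }
  return vnorm({d.x * c + s * (cphi * u.x + sphi * v.x),
                d.y * c + s * (cphi * u.y + sphi * v.y),
                d.z * c + s * (cphi * u.z + sphi * v.z)});
}

// Klein-Nishina scattering-angle sampling by rejection on cos(theta);
// the acceptance function is the differential cross-section normalised
// by its forward-direction maximum.
inline double sample_kn_cos(double e_keV, Pcg32 &rng) {
  double a = e_keV / 510.999;
  for (;;) {
    double c = 2.0 * rng.uniform() - 1.0;
    double x = 1.0 / (1.0 + a * (1.0 - c));        // E'/E
    double g = x * x * (x + 1.0 / x - (1.0 - c * c)) / 2.0;
    if (rng.uniform() <= g) return c;
  }
}

inline double sample_thomson_cos(Pcg32 &rng) {
  for (;;) {
    double c = 2.0 * rng.uniform() - 1.0;
    if (rng.uniform() <= 0.5 * (1.0 + c * c)) return c;
  }
}

struct SourceModel {
  double sid;
  const double *gantry;  // radians
  int n_gantry;
  double u_min, u_max, v_half;
  const double *spec_e;  // spectrum bin energies
  int n_spec;
  const double *src_cdf; // n_spec x n_psi, column-major cumulative
  const double *psi_w;   // per-fan-bin transmitted weight
  int n_psi;

  // sample one photon; returns weight, energy, position, direction
  void sample(Pcg32 &rng, double &w, double &e, Vec3 &pos, Vec3 &dir) const {
    int gi = std::min(static_cast<int>(rng.uniform() * n_gantry),
                      n_gantry - 1);
    double g = gantry[gi];
    double u = u_min + rng.uniform() * (u_max - u_min);
    double v = -v_half + rng.uniform() * 2.0 * v_half;
    int j = std::min(static_cast<int>((u - u_min) / (u_max - u_min) * n_psi),
                     n_psi - 1);
    const double *cdf = src_cdf + static_cast<size_t>(j) * n_spec;
    double r = rng.uniform();
    int lo = 0, hi = n_spec - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < r) lo = mid + 1; else hi = mid;
    }
    e = spec_e[lo];
    w = psi_w[j];
    double sg = std::sin(g), cg = std::cos(g);
    pos = {sid * sg, sid * cg, 0.0};
    Vec3 target = {u * cg, -u * sg, v};
    dir = vnorm(vsub(target, pos));
  }

  Vec3 axis_dir(int gi) const {  // central-axis direction for projection gi
    double g = gantry[gi];
    return {-std::sin(g), -std::cos(g), 0.0};
  }
};

struct Grid {
  const double *den;
  const int *mat;  // 1-based material indices
  int nx, ny, nz;
  double sx, sy, sz;       // spacing, cm
  double ox, oy, oz;       // corner of voxel (0,0,0)
  double ex, ey, ez;       // opposite corner

  bool enter(const Vec3 &p, const Vec3 &d, double &t) const {
    double t0 = 0.0, t1 = 1e30;
    const double lo[3] = {ox, oy, oz}, hi[3] = {ex, ey, ez};
    const double pp[3] = {p.x, p.y, p.z}, dd[3] = {d.x, d.y, d.z};
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(dd[k]) < 1e-12) {
        if (pp[k] < lo[k] || pp[k] > hi[k]) return false;
      } else {
        double ta = (lo[k] - pp[k]) / dd[k], tb = (hi[k] - pp[k]) / dd[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    if (t0 > t1) return false;
    t = t0;
    return true;
  }

  bool inside(const Vec3 &p) const {
    return p.x > ox && p.x < ex && p.y > oy && p.y < ey &&
           p.z > oz && p.z < ez;
  }

  long voxel(const Vec3 &p) const {
    int i = static_cast<int>((p.x - ox) / sx);
    int j = static_cast<int>((p.y - oy) / sy);
    int k = static_cast<int>((p.z - oz) / sz);
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    return i + static_cast<long>(nx) * (j + static_cast<long>(ny) * k);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate_dose(NumericVector den, IntegerVector mat,
                       IntegerVector dims, NumericVector spacing_cm,
                       NumericVector origin_cm, NumericMatrix mu,
                       NumericMatrix cum_photo, NumericMatrix cum_compton,
                       double egrid0, NumericVector mu_majorant,
                       NumericVector spec_e, NumericMatrix src_cdf,
                       NumericVector psi_w, double sid,
                       NumericVector gantry_rad, double u_min, double u_max,
                       double v_half, IntegerVector labels, int n_labels,
                       NumericVector label_count, double n_photons,
                       int n_batches, int seed, double e_cut,
                       bool rayleigh_on) {
  const int ne = mu.nrow(), nmat = mu.ncol();
  Grid grid;
  grid.den = den.begin();
  grid.mat = mat.begin();
  grid.nx = dims[0]; grid.ny = dims[1]; grid.nz = dims[2];
  grid.sx = spacing_cm[0]; grid.sy = spacing_cm[1]; grid.sz = spacing_cm[2];
  grid.ox = origin_cm[0]; grid.oy = origin_cm[1]; grid.oz = origin_cm[2];
  grid.ex = grid.ox + grid.nx * grid.sx;
  grid.ey = grid.oy + grid.ny * grid.sy;
  grid.ez = grid.oz + grid.nz * grid.sz;
  const double voxvol = grid.sx * grid.sy * grid.sz;

  SourceModel src;
  src.sid = sid;
  src.gantry = gantry_rad.begin();
  src.n_gantry = gantry_rad.size();
  src.u_min = u_min; src.u_max = u_max; src.v_half = v_half;
  src.spec_e = spec_e.begin();
  src.n_spec = spec_e.size();
  src.src_cdf = src_cdf.begin();
  src.psi_w = psi_w.begin();
  src.n_psi = src_cdf.ncol();

  const long nvox = static_cast<long>(grid.nx) * grid.ny * grid.nz;
  NumericVector dose(nvox);
  NumericMatrix batch_org(n_batches, std::max(n_labels, 1));
  NumericVector emitted(n_batches), deposited(n_batches);
  const bool have_labels = labels.size() == nvox && n_labels > 0;

  const double per_batch = n_photons / n_batches;

  for (int b = 0; b < n_batches; ++b) {
    Pcg32 rng;
    rng.seed(splitmix64(static_cast<uint64_t>(seed) * 1000003ULL + b),
             splitmix64(0xda3e39cb94b95bdbULL ^ (static_cast<uint64_t>(b)
                                                 << 17) ^ seed));
    long nb = static_cast<long>(std::floor(per_batch * (b + 1)) -
                                std::floor(per_batch * b));
    for (long ip = 0; ip < nb; ++ip) {
      double w, e;
      Vec3 pos, dir;
      src.sample(rng, w, e, pos, dir);
      emitted[b] += w * e;

      double t0;
      if (!grid.enter(pos, dir, t0)) continue;
      pos = {pos.x + dir.x * (t0 + 1e-9), pos.y + dir.y * (t0 + 1e-9),
             pos.z + dir.z * (t0 + 1e-9)};

      for (;;) {
        double maj = egrid_interp(mu_majorant.begin(), ne, egrid0, e);
        if (maj <= 0.0) break;  // vacuum grid: free flight out
        double step = -std::log(rng.uniform()) / maj;
        pos = {pos.x + dir.x * step, pos.y + dir.y * step,
               pos.z + dir.z * step};
        if (!grid.inside(pos)) break;
        long v = grid.voxel(pos);
        int m = grid.mat[v] - 1;
        double mu_v = egrid_interp(&mu(0, m), ne, egrid0, e) * grid.den[v];
        if (rng.uniform() * maj > mu_v) continue;  // virtual collision

        double r2 = rng.uniform();
        double c1 = egrid_interp(&cum_photo(0, m), ne, egrid0, e);
        double c2 = egrid_interp(&cum_compton(0, m), ne, egrid0, e);
        double edep = -1.0;
        if (r2 < c1) {
          edep = e;  // photoelectric: terminate
        } else if (r2 < c2) {
          double c = sample_kn_cos(e, rng);
          double ep = e / (1.0 + e / 510.999 * (1.0 - c));
          double elec = e - ep;
          if (ep < e_cut) {
            edep = e;  // scattered photon below cutoff: deposit all
          } else {
            double dd = w * elec / (grid.den[v] * voxvol);
            dose[v] += dd;
            deposited[b] += w * elec;
            if (have_labels && labels[v] > 0)
              batch_org(b, labels[v] - 1) +=
                dd / label_count[labels[v] - 1];
            e = ep;
            dir = rotate_dir(dir, c, 2.0 * M_PI * rng.uniform());
            continue;
          }
        } else {
          // coherent: Thomson angular law; with rayleigh_on = false the
          // photon passes through undeflected (forward approximation)
          if (rayleigh_on) {
            double c = sample_thomson_cos(rng);
            dir = rotate_dir(dir, c, 2.0 * M_PI * rng.uniform());
          }
          continue;
        }
        // terminal deposit
        double dd = w * edep / (grid.den[v] * voxvol);
        dose[v] += dd;
        deposited[b] += w * edep;
        if (have_labels && labels[v] > 0)
          batch_org(b, labels[v] - 1) += dd / label_count[labels[v] - 1];
        break;
      }
    }
  }
  return List::create(_["dose"] = dose, _["batch_organ"] = batch_org,
                      _["emitted_keV"] = emitted,
                      _["deposited_keV"] = deposited);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(int n, double energy_keV, int seed) {
  Pcg32 rng;
  rng.seed(splitmix64(static_cast<uint64_t>(seed)), 0x853c49e6748fea9bULL);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double c = sample_kn_cos(energy_keV, rng);
    out(i, 0) = energy_keV / (1.0 + energy_keV / 510.999 * (1.0 - c));
    out(i, 1) = c;
  }
  colnames(out) = CharacterVector::create("scattered_keV", "cos_theta");
  return out;
}

// Free-in-air collision kerma at a point: surface-crossing fluence
// estimator over a tally disc perpendicular to the central beam axis.
// [[Rcpp::export]]
double cpp_air_kerma(NumericVector spec_e, NumericMatrix src_cdf,
                     NumericVector psi_w, double sid,
                     NumericVector gantry_rad, double u_min, double u_max,
                     double v_half, NumericVector point_cm,
                     double tally_radius_cm, NumericVector muen_air,
                     double egrid0, double n_photons, int seed) {
  SourceModel src;
  src.sid = sid;
  src.gantry = gantry_rad.begin();
  src.n_gantry = gantry_rad.size();
  src.u_min = u_min; src.u_max = u_max; src.v_half = v_half;
  src.spec_e = spec_e.begin();
  src.n_spec = spec_e.size();
  src.src_cdf = src_cdf.begin();
  src.psi_w = psi_w.begin();
  src.n_psi = src_cdf.ncol();

  Pcg32 rng;
  rng.seed(splitmix64(static_cast<uint64_t>(seed) * 2718281ULL),
           0x5851f42d4c957f2dULL);
  const int ne = muen_air.size();
  const Vec3 p0 = {point_cm[0], point_cm[1], point_cm[2]};
  const double area = M_PI * tally_radius_cm * tally_radius_cm;
  const long n = static_cast<long>(n_photons);
  double kerma = 0.0;
  for (long i = 0; i < n; ++i) {
    double w, e;
    Vec3 pos, dir;
    src.sample(rng, w, e, pos, dir);
    // the central axis of this projection is from the source through the
    // isocentre; the tally disc is perpendicular to it
    Vec3 ax = vnorm({-pos.x, -pos.y, 0.0});
    double denom = vdot(dir, ax);
    if (denom < 1e-9) continue;
    double t = vdot(vsub(p0, pos), ax) / denom;
    if (t <= 0) continue;
    Vec3 hit = {pos.x + dir.x * t, pos.y + dir.y * t, pos.z + dir.z * t};
    Vec3 dp = vsub(hit, p0);
    if (vdot(dp, dp) <= tally_radius_cm * tally_radius_cm)
      kerma += w * e * egrid_interp(muen_air.begin(), ne, egrid0, e) /
               (area * denom);
  }
  return kerma / n_photons;
}

// Fraction of pencil-beam photons crossing the grid without a real
// interaction (narrow-beam transmission; validation surface for the
// Woodcock tracker).
// [[Rcpp::export]]
double cpp_transmission(NumericVector den, IntegerVector mat,
                        IntegerVector dims, NumericVector spacing_cm,
                        NumericVector origin_cm, NumericMatrix mu,
                        double egrid0, NumericVector mu_majorant,
                        double energy_keV, NumericVector src_cm,
                        NumericVector dir_in, double n_photons, int seed) {
  const int ne = mu.nrow();
  Grid grid;
  grid.den = den.begin();
  grid.mat = mat.begin();
  grid.nx = dims[0]; grid.ny = dims[1]; grid.nz = dims[2];
  grid.sx = spacing_cm[0]; grid.sy = spacing_cm[1]; grid.sz = spacing_cm[2];
  grid.ox = origin_cm[0]; grid.oy = origin_cm[1]; grid.oz = origin_cm[2];
  grid.ex = grid.ox + grid.nx * grid.sx;
  grid.ey = grid.oy + grid.ny * grid.sy;
  grid.ez = grid.oz + grid.nz * grid.sz;
  Vec3 s = {src_cm[0], src_cm[1], src_cm[2]};
  Vec3 d = vnorm({dir_in[0], dir_in[1], dir_in[2]});
  Pcg32 rng;
  rng.seed(splitmix64(static_cast<uint64_t>(seed) * 7919ULL),
           0x9e3779b97f4a7c15ULL);
  const long n = static_cast<long>(n_photons);
  long through = 0;
  double maj = egrid_interp(mu_majorant.begin(), ne, egrid0, energy_keV);
  for (long i = 0; i < n; ++i) {
    double t0;
    Vec3 pos = s;
    if (!grid.enter(pos, d, t0)) { ++through; continue; }
    pos = {pos.x + d.x * (t0 + 1e-9), pos.y + d.y * (t0 + 1e-9),
           pos.z + d.z * (t0 + 1e-9)};
    bool survived = true;
    if (maj > 0) {
      for (;;) {
        double step = -std::log(rng.uniform()) / maj;
        pos = {pos.x + d.x * step, pos.y + d.y * step, pos.z + d.z * step};
        if (!grid.inside(pos)) break;
        long v = grid.voxel(pos);
        int m = grid.mat[v] - 1;
        double mu_v = egrid_interp(&mu(0, m), ne, egrid0, energy_keV) *
                      grid.den[v];
        if (rng.uniform() * maj <= mu_v) { survived = false; break; }
      }
    }
    if (survived) ++through;
  }
  return static_cast<double>(through) / n_photons;
}
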