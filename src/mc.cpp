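// Trajectory-level Monte Carlo of keV electrons in light-element resin
// containing heavy-atom stain.  Single-scattering model:
//   - screened-Rutherford total elastic cross section with relativistic
//     correction factor,
//   - continuous slowing down via the Joy-Luo modified Bethe expression,
//   - exponential free paths, truncated (and re-sampled, which is unbiased
//     by memorylessness) at material boundaries and at a step cap that
//     guards against overshooting thin layers.
// Units: energy keV, length nm, number density atoms/nm^3, density g/cm^3.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double INF = 1e300;
static const double BEPS = 1e-6;   // nm, push across a boundary
static const int MAXIT = 1000000;  // safety bound on substeps

// ---------------------------------------------------------------- RNG ----
// xorshift64* seeded through splitmix64; small, fast, reproducible, and
// cheap to substream per pixel.
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) {
    // splitmix64 scramble; guarantees a nonzero state
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  inline double unif() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return ((s * 0x2545F4914F6CDD1DULL) >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline uint64_t mix_seed(uint64_t root, uint64_t a, uint64_t b) {
  return root ^ (a * 0x9E3779B97F4A7C15ULL) ^ (b * 0xC2B2AE3D27D4EB4FULL);
}

// ----------------------------------------------------------- material ----
struct MaterialC {
  std::vector<double> Z, A, n, cmass; // per element
  std::vector<double> z067, zz, J, czoa;
  double rho;
  double k; // Joy-Luo low-energy correction constant
};

static MaterialC material_from_list(List m, double k) {
  MaterialC mc;
  NumericVector Z = m["Z"], A = m["A_w"], n = m["n"], cm = m["mass_fraction"];
  mc.rho = as<double>(m["mass_density"]);
  mc.k = k;
  for (int i = 0; i < Z.size(); ++i) {
    mc.Z.push_back(Z[i]); mc.A.push_back(A[i]);
    mc.n.push_back(n[i]); mc.cmass.push_back(cm[i]);
    mc.z067.push_back(std::pow(Z[i], 0.67));
    mc.zz.push_back(Z[i] * Z[i]);
    mc.J.push_back((9.76 * Z[i] + 58.5 * std::pow(Z[i], -0.19)) * 1e-3);
    mc.czoa.push_back(cm[i] * Z[i] / A[i]);
  }
  return mc;
}

// screened-Rutherford total elastic cross section, nm^2 per atom
static inline double sigma_el(double zz, double z067, double E) {
  double alpha = 3.4e-3 * z067 / E;
  double rel = (E + 511.0) / (E + 1024.0);
  return 5.21e-7 * zz / (E * E) * (4.0 * M_PI) / (alpha * (1.0 + alpha))
         * rel * rel;
}

// Sum of n_i * sigma_i, inverse elastic mean free path (1/nm)
static inline double sum_nsigma(const MaterialC& m, double E) {
  double s = 0.0;
  for (size_t i = 0; i < m.n.size(); ++i)
    s += m.n[i] * sigma_el(m.zz[i], m.z067[i], E);
  return s;
}

// Joy-Luo stopping power, keV/nm (positive)
static inline double dEds(const MaterialC& m, double E) {
  double s = 0.0;
  for (size_t i = 0; i < m.J.size(); ++i)
    s += m.czoa[i] * std::log(1.166 * (E + m.k * m.J[i]) / m.J[i]);
  return 7.85e-3 * m.rho / E * s;
}

// sample elastic polar deflection for element i of material m
static inline double sample_cos(const MaterialC& m, size_t i, double E,
                                double u) {
  double alpha = 3.4e-3 * m.z067[i] / E;
  return 1.0 - 2.0 * alpha * u / (1.0 + alpha - u);
}

static inline size_t pick_element(const MaterialC& m, double E, double u,
                                  double total) {
  double r = u * total, acc = 0.0;
  for (size_t i = 0; i + 1 < m.n.size(); ++i) {
    acc += m.n[i] * sigma_el(m.zz[i], m.z067[i], E);
    if (r <= acc) return i;
  }
  return m.n.size() - 1;
}

static inline void rotate_dir(double* u, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double w = u[2];
  if (std::fabs(w) > 0.9999999) {
    u[0] = st * cp; u[1] = st * sp; u[2] = (w > 0 ? ct : -ct);
  } else {
    double d = std::sqrt(1.0 - w * w);
    double a = u[0], b = u[1];
    u[0] = a * ct + st * (a * w * cp - b * sp) / d;
    u[1] = b * ct + st * (b * w * cp + a * sp) / d;
    u[2] = w * ct - d * st * cp;
  }
  double nrm = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;
}

// --------------------------------------------------------- geometries ----
// Outcomes
enum { BACKSCATTERED = 0, ABSORBED = 1, ESCAPED = 2 };

// Semi-infinite bulk of one material (z > 0)
struct GeomBulk {
  double step_cap;
  int mat_at(const double*) const { return 0; }
  double dist_boundary(const double* p, const double* u) const {
    if (u[2] < 0.0) return -p[2] / u[2]; // top surface plane z = 0
    return INF;
  }
  bool inside(const double*) const { return true; }
};

// Laterally infinite stained slab [z0, z1) in a bulk matrix
struct GeomSlab {
  double z0, z1, step_cap;
  int mat_at(const double* p) const {
    return (p[2] >= z0 && p[2] < z1) ? 1 : 0;
  }
  double dist_boundary(const double* p, const double* u) const {
    double best = INF;
    const double planes[3] = {0.0, z0, z1};
    if (u[2] != 0.0) {
      for (int i = 0; i < 3; ++i) {
        double t = (planes[i] - p[2]) / u[2];
        if (t > 0.0 && t < best) best = t;
      }
    }
    return best;
  }
  bool inside(const double*) const { return true; }
};

// Finite voxel grid; material index per voxel
struct GeomVoxel {
  const int* idx; int nx, ny, nz;
  double dx, dy, dz, step_cap;
  int mat_at(const double* p) const {
    int ix = (int)std::floor(p[0] / dx);
    int iy = (int)std::floor(p[1] / dy);
    int iz = (int)std::floor(p[2] / dz);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      return -1;
    return idx[ix + (size_t)nx * (iy + (size_t)ny * iz)];
  }
  double dist_boundary(const double* p, const double* u) const {
    double best = INF;
    const double d[3] = {dx, dy, dz};
    for (int a = 0; a < 3; ++a) {
      if (u[a] == 0.0) continue;
      double cell = std::floor(p[a] / d[a]);
      double face = (u[a] > 0.0 ? (cell + 1.0) : cell) * d[a];
      double t = (face - p[a]) / u[a];
      if (t > 0.0 && t < best) best = t;
    }
    return best;
  }
  bool inside(const double* p) const {
    return p[0] >= 0.0 && p[1] >= 0.0 && p[2] >= 0.0 &&
           p[0] < nx * dx && p[1] < ny * dy && p[2] < nz * dz;
  }
};

// ------------------------------------------------------------ stepper ----
template <class Geom>
static int run_trajectory(const Geom& g,
                          const std::vector<MaterialC>& mats,
                          RNG& rng, double x0, double y0,
                          double E0, double cutoff,
                          double& exitE, double* exitdir,
                          std::vector<double>* path) {
  double p[3] = {x0, y0, BEPS};
  double u[3] = {0.0, 0.0, 1.0};
  double E = E0;
  if (path) { path->push_back(p[0]); path->push_back(p[1]); path->push_back(p[2]); }
  for (int it = 0; it < MAXIT; ++it) {
    int m = g.mat_at(p);
    if (m < 0) return ESCAPED; // numerical corner: already outside
    const MaterialC& mat = mats[m];
    double sn = sum_nsigma(mat, E);
    double s = -std::log(1.0 - rng.unif()) / sn;
    double db = g.dist_boundary(p, u);
    bool scatter;
    double adv;
    if (s <= db && s <= g.step_cap) { adv = s; scatter = true; }
    else { adv = std::min(db + BEPS, g.step_cap); scatter = false; }
    double loss = adv * dEds(mat, E);
    if (E - loss <= cutoff) {        // ranged out within this substep
      exitE = cutoff;
      return ABSORBED;
    }
    p[0] += adv * u[0]; p[1] += adv * u[1]; p[2] += adv * u[2];
    E -= loss;
    if (path) { path->push_back(p[0]); path->push_back(p[1]); path->push_back(p[2]); }
    if (p[2] <= 0.0) {               // crossed the block face
      exitE = E;
      exitdir[0] = u[0]; exitdir[1] = u[1]; exitdir[2] = u[2];
      return (E > cutoff) ? BACKSCATTERED : ABSORBED;
    }
    if (!g.inside(p)) return ESCAPED;
    if (scatter) {
      size_t i = pick_element(mat, E, rng.unif(), sn);
      double ct = sample_cos(mat, i, E, rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      rotate_dir(u, ct, phi);
    }
  }
  exitE = E;
  return ABSORBED;
}

// ------------------------------------------------------------ exports ----

// [[Rcpp::export]]
double sigma_el_cpp(double Z, double E) {
  return sigma_el(Z * Z, std::pow(Z, 0.67), E);
}

// [[Rcpp::export]]
double dEds_cpp(List material, double E, double k) {
  MaterialC m = material_from_list(material, k);
  return dEds(m, E);
}

// [[Rcpp::export]]
double inv_mfp_cpp(List material, double E) {
  MaterialC m = material_from_list(material, 0.77);
  return sum_nsigma(m, E);
}

// [[Rcpp::export]]
List mc_bulk_cpp(List material, double E0, int n_electrons, double cutoff,
                 double k, double seed, bool collect_exits = false) {
  std::vector<MaterialC> mats(1, material_from_list(material, k));
  GeomBulk g; g.step_cap = INF;
  RNG rng((uint64_t)seed);
  int nb = 0;
  std::vector<double> exE, exU, exV, exW;
  double exitE, exd[3];
  for (int i = 0; i < n_electrons; ++i) {
    int out = run_trajectory(g, mats, rng, 0.0, 0.0, E0, cutoff,
                             exitE, exd, nullptr);
    if (out == BACKSCATTERED) {
      ++nb;
      if (collect_exits) {
        exE.push_back(exitE);
        exU.push_back(exd[0]); exV.push_back(exd[1]); exW.push_back(exd[2]);
      }
    }
  }
  List res = List::create(_["n_backscattered"] = nb,
                          _["n_electrons"] = n_electrons);
  if (collect_exits) {
    res["exit_energy"] = wrap(exE);
    res["exit_ux"] = wrap(exU);
    res["exit_uy"] = wrap(exV);
    res["exit_uz"] = wrap(exW);
  }
  return res;
}

// [[Rcpp::export]]
List mc_slab_cpp(List matrix_material, List stained_material,
                 double z0, double z1, double E0, int n_electrons,
                 double cutoff, double k, double seed, double step_cap) {
  std::vector<MaterialC> mats;
  mats.push_back(material_from_list(matrix_material, k));
  mats.push_back(material_from_list(stained_material, k));
  GeomSlab g; g.z0 = z0; g.z1 = z1;
  g.step_cap = (step_cap > 0.0) ? step_cap : INF;
  RNG rng((uint64_t)seed);
  int nb = 0;
  double exitE, exd[3];
  for (int i = 0; i < n_electrons; ++i) {
    int out = run_trajectory(g, mats, rng, 0.0, 0.0, E0, cutoff,
                             exitE, exd, nullptr);
    if (out == BACKSCATTERED) ++nb;
  }
  return List::create(_["n_backscattered"] = nb,
                      _["n_electrons"] = n_electrons);
}

// [[Rcpp::export]]
IntegerMatrix mc_image_cpp(IntegerVector matidx, IntegerVector dims,
                           NumericVector voxel_nm, List materials,
                           double E0, int electrons_per_pixel,
                           double px0, double py0, double pixel_nm,
                           int npx, int npy,
                           double cutoff, double k, double eps_det,
                           double seed) {
  std::vector<MaterialC> mats;
  for (int i = 0; i < materials.size(); ++i)
    mats.push_back(material_from_list(materials[i], k));
  GeomVoxel g;
  g.idx = INTEGER(matidx);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = voxel_nm[0]; g.dy = voxel_nm[1]; g.dz = voxel_nm[2];
  double mind = std::min(g.dx, std::min(g.dy, g.dz));
  g.step_cap = mind / 4.0;
  IntegerMatrix counts(npx, npy);
  double exitE, exd[3];
  for (int j = 0; j < npy; ++j) {
    for (int i = 0; i < npx; ++i) {
      RNG rng(mix_seed((uint64_t)seed, (uint64_t)(i + 1), (uint64_t)(j + 1)));
      double bx = px0 + (i + 0.5) * pixel_nm;
      double by = py0 + (j + 0.5) * pixel_nm;
      int nb = 0;
      for (int e = 0; e < electrons_per_pixel; ++e) {
        int out = run_trajectory(g, mats, rng, bx, by, E0, cutoff,
                                 exitE, exd, nullptr);
        if (out == BACKSCATTERED) {
          if (eps_det >= 1.0 || rng.unif() < eps_det) ++nb;
        }
      }
      counts(i, j) = nb;
    }
  }
  return counts;
}

// [[Rcpp::export]]
List mc_trajectory_cpp(IntegerVector matidx, IntegerVector dims,
                       NumericVector voxel_nm, List materials,
                       double E0, double x, double y,
                       double cutoff, double k, double seed,
                       bool record_path = true) {
  std::vector<MaterialC> mats;
  for (int i = 0; i < materials.size(); ++i)
    mats.push_back(material_from_list(materials[i], k));
  GeomVoxel g;
  g.idx = INTEGER(matidx);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.dx = voxel_nm[0]; g.dy = voxel_nm[1]; g.dz = voxel_nm[2];
  double mind = std::min(g.dx, std::min(g.dy, g.dz));
  g.step_cap = mind / 4.0;
  RNG rng((uint64_t)seed);
  std::vector<double> path;
  double exitE = NA_REAL, exd[3] = {NA_REAL, NA_REAL, NA_REAL};
  int out = run_trajectory(g, mats, rng, x, y, E0, cutoff, exitE, exd,
                           record_path ? &path : nullptr);
  List res = List::create(
    _["outcome"] = out, // 0 backscattered, 1 absorbed, 2 escaped
    _["exit_energy"] = (out == BACKSCATTERED) ? exitE : NA_REAL,
    _["exit_direction"] = NumericVector::create(exd[0], exd[1], exd[2]));
  if (record_path) {
    int nv = path.size() / 3;
    NumericMatrix pm(nv, 3);
    for (int i = 0; i < nv; ++i) {
      pm(i, 0) = path[3 * i]; pm(i, 1) = path[3 * i + 1];
      pm(i, 2) = path[3 * i + 2];
    }
    res["path"] = pm;
  }
  return res;
}
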