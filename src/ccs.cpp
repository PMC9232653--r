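// Monte Carlo collision cross section estimators on hard-sphere bead
// models: projection approximation (PA) and exact hard-sphere
// scattering (EHSS). A private 64-bit Mersenne Twister keyed by the
// caller's seed makes results reproducible across platforms
// independently of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

namespace {

struct Basis {
  double u[3];   // view direction
  double e1[3];  // projection axes
  double e2[3];
};

// Area-uniform random orientation on the sphere.
Basis random_basis(std::mt19937_64 &rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double z = 2.0 * unif(rng) - 1.0;
  double phi = 2.0 * M_PI * unif(rng);
  double st = std::sqrt(std::max(0.0, 1.0 - z * z));
  Basis b;
  b.u[0] = st * std::cos(phi); b.u[1] = st * std::sin(phi); b.u[2] = z;
  b.e1[0] = -std::sin(phi); b.e1[1] = std::cos(phi); b.e1[2] = 0.0;
  b.e2[0] = b.u[1] * b.e1[2] - b.u[2] * b.e1[1];
  b.e2[1] = b.u[2] * b.e1[0] - b.u[0] * b.e1[2];
  b.e2[2] = b.u[0] * b.e1[1] - b.u[1] * b.e1[0];
  return b;
}

// Quasi-uniform orientation set: spherical Fibonacci lattice, randomly
// rotated as a whole by a seed-derived rotation. Integrates smooth
// orientation dependence with much lower variance than iid sampling.
std::vector<std::array<double, 3>> fibonacci_sphere(int n, std::mt19937_64 &rng) {
  std::normal_distribution<double> norm(0.0, 1.0);
  // random rotation from a uniform unit quaternion
  double q0 = norm(rng), q1 = norm(rng), q2 = norm(rng), q3 = norm(rng);
  double qn = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
  q0 /= qn; q1 /= qn; q2 /= qn; q3 /= qn;
  double R[3][3] = {
    {1 - 2 * (q2 * q2 + q3 * q3), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2)},
    {2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1 * q1 + q3 * q3), 2 * (q2 * q3 - q0 * q1)},
    {2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1 * q1 + q2 * q2)}};
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  std::vector<std::array<double, 3>> out(n);
  for (int i = 0; i < n; ++i) {
    double z = (2.0 * i + 1.0) / n - 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * i;
    double v[3] = {st * std::cos(phi), st * std::sin(phi), z};
    for (int r = 0; r < 3; ++r)
      out[i][r] = R[r][0] * v[0] + R[r][1] * v[1] + R[r][2] * v[2];
  }
  return out;
}

Basis basis_from_u(double ux, double uy, double uz) {
  Basis b;
  b.u[0] = ux; b.u[1] = uy; b.u[2] = uz;
  // any vector not parallel to u
  double ax = 0.0, ay = 0.0, az = 1.0;
  if (std::fabs(uz) > 0.9) { ax = 1.0; az = 0.0; }
  // e1 = normalize(a x u)
  double e1x = ay * uz - az * uy, e1y = az * ux - ax * uz, e1z = ax * uy - ay * ux;
  double n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  b.e1[0] = e1x / n; b.e1[1] = e1y / n; b.e1[2] = e1z / n;
  b.e2[0] = b.u[1] * b.e1[2] - b.u[2] * b.e1[1];
  b.e2[1] = b.u[2] * b.e1[0] - b.u[0] * b.e1[2];
  b.e2[2] = b.u[0] * b.e1[1] - b.u[1] * b.e1[0];
  return b;
}

// Projected bead coordinates for one orientation, sorted by px to allow
// a windowed candidate scan per sample point.
struct Projection {
  std::vector<double> px, py, r2;
  std::vector<int> order;       // indices sorted by px
  std::vector<double> px_sorted;
  double lox, hix, loy, hiy;
  double rmax;
};

Projection project(const NumericMatrix &xyz, const NumericVector &radii,
                   const Basis &b) {
  int n = xyz.nrow();
  Projection p;
  p.px.resize(n); p.py.resize(n); p.r2.resize(n);
  p.rmax = 0.0;
  double lox = R_PosInf, hix = R_NegInf, loy = R_PosInf, hiy = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double x = xyz(i, 0), y = xyz(i, 1), z = xyz(i, 2);
    double u = x * b.e1[0] + y * b.e1[1] + z * b.e1[2];
    double v = x * b.e2[0] + y * b.e2[1] + z * b.e2[2];
    p.px[i] = u; p.py[i] = v;
    double r = radii[i];
    p.r2[i] = r * r;
    if (r > p.rmax) p.rmax = r;
    lox = std::min(lox, u - r); hix = std::max(hix, u + r);
    loy = std::min(loy, v - r); hiy = std::max(hiy, v + r);
  }
  p.lox = lox; p.hix = hix; p.loy = loy; p.hiy = hiy;
  p.order.resize(n);
  for (int i = 0; i < n; ++i) p.order[i] = i;
  std::sort(p.order.begin(), p.order.end(),
            [&p](int a, int c) { return p.px[a] < p.px[c]; });
  p.px_sorted.resize(n);
  for (int i = 0; i < n; ++i) p.px_sorted[i] = p.px[p.order[i]];
  return p;
}

bool hit_any(const Projection &p, double sx, double sy) {
  double lo = sx - p.rmax, hi = sx + p.rmax;
  size_t i0 = std::lower_bound(p.px_sorted.begin(), p.px_sorted.end(), lo) -
              p.px_sorted.begin();
  for (size_t j = i0; j < p.px_sorted.size() && p.px_sorted[j] <= hi; ++j) {
    int i = p.order[j];
    double dx = sx - p.px[i], dy = sy - p.py[i];
    if (dx * dx + dy * dy <= p.r2[i]) return true;
  }
  return false;
}

}  // namespace

// Per-orientation projected areas by uniform rejection sampling over the
// bounding rectangle of the projected disks. Returns one area estimate
// per orientation; if `orientations` has rows, those unit vectors are
// used instead of random ones (for validation against deterministic
// projection oracles).
// [[Rcpp::export(name = ".ccs_pa_cpp")]]
NumericVector ccs_pa_cpp(NumericMatrix xyz, NumericVector radii,
                         int n_orientations, int n_samples, double seed,
                         Nullable<NumericMatrix> orientations = R_NilValue,
                         bool quasi = true) {
  if (xyz.nrow() < 1) stop("empty model");
  if (xyz.nrow() != radii.size()) stop("radii length != bead count");
  bool fixed = orientations.isNotNull();
  NumericMatrix ori;
  if (fixed) {
    ori = orientations.get();
    n_orientations = ori.nrow();
  }
  if (n_orientations < 1 || n_samples < 1) stop("non-positive sampling parameters");
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<std::array<double, 3>> lattice;
  if (!fixed && quasi) lattice = fibonacci_sphere(n_orientations, rng);
  NumericVector areas(n_orientations);
  for (int o = 0; o < n_orientations; ++o) {
    Basis b = fixed ? basis_from_u(ori(o, 0), ori(o, 1), ori(o, 2))
                    : (quasi ? basis_from_u(lattice[o][0], lattice[o][1], lattice[o][2])
                             : random_basis(rng));
    Projection p = project(xyz, radii, b);
    double box = (p.hix - p.lox) * (p.hiy - p.loy);
    long hits = 0;
    for (int s = 0; s < n_samples; ++s) {
      double sx = p.lox + (p.hix - p.lox) * unif(rng);
      double sy = p.loy + (p.hiy - p.loy) * unif(rng);
      if (hit_any(p, sx, sy)) ++hits;
    }
    areas[o] = box * (double)hits / (double)n_samples;
  }
  return areas;
}

// EHSS: per orientation, parallel trajectories sampled over the bounding
// rectangle undergo specular hard-sphere reflections; each contributes
// its momentum-transfer weight (1 - cos(total deflection)). Returns one
// cross-section estimate per orientation.
// [[Rcpp::export(name = ".ccs_ehss_cpp")]]
NumericVector ccs_ehss_cpp(NumericMatrix xyz, NumericVector radii,
                           int n_orientations, int n_samples, double seed,
                           int max_bounces = 30, bool quasi = true) {
  int n = xyz.nrow();
  if (n < 1) stop("empty model");
  if (n != radii.size()) stop("radii length != bead count");
  if (n_orientations < 1 || n_samples < 1) stop("non-positive sampling parameters");
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<std::array<double, 3>> lattice;
  if (quasi) lattice = fibonacci_sphere(n_orientations, rng);
  NumericVector cs(n_orientations);
  std::vector<double> cx(n), cy(n), cz(n);
  for (int o = 0; o < n_orientations; ++o) {
    Basis b = quasi ? basis_from_u(lattice[o][0], lattice[o][1], lattice[o][2])
                    : random_basis(rng);
    // rotate beads into the view frame: view direction is +z'
    double lox = R_PosInf, hix = R_NegInf, loy = R_PosInf, hiy = R_NegInf,
           loz = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double x = xyz(i, 0), y = xyz(i, 1), z = xyz(i, 2);
      cx[i] = x * b.e1[0] + y * b.e1[1] + z * b.e1[2];
      cy[i] = x * b.e2[0] + y * b.e2[1] + z * b.e2[2];
      cz[i] = x * b.u[0] + y * b.u[1] + z * b.u[2];
      double r = radii[i];
      lox = std::min(lox, cx[i] - r); hix = std::max(hix, cx[i] + r);
      loy = std::min(loy, cy[i] - r); hiy = std::max(hiy, cy[i] + r);
      loz = std::min(loz, cz[i] - r);
    }
    double box = (hix - lox) * (hiy - loy);
    double wsum = 0.0;
    for (int s = 0; s < n_samples; ++s) {
      double p0x = lox + (hix - lox) * unif(rng);
      double p0y = loy + (hiy - loy) * unif(rng);
      double px = p0x, py = p0y, pz = loz - 1.0;
      double dx = 0.0, dy = 0.0, dz = 1.0;   // initial direction +z'
      bool scattered = false;
      for (int bounce = 0; bounce < max_bounces; ++bounce) {
        // nearest sphere intersection along (d) from (p)
        double tbest = R_PosInf; int ibest = -1;
        for (int i = 0; i < n; ++i) {
          double ox = px - cx[i], oy = py - cy[i], oz = pz - cz[i];
          double bq = ox * dx + oy * dy + oz * dz;
          double cq = ox * ox + oy * oy + oz * oz - radii[i] * radii[i];
          if (cq <= 0.0) continue;  // ray origin inside sphere i: its
                                    // surface is interior to the union
          double disc = bq * bq - cq;
          if (disc < 0.0) continue;
          double t = -bq - std::sqrt(disc);  // entry intersection only
          if (t > 1e-9 && t < tbest) { tbest = t; ibest = i; }
        }
        if (ibest < 0) break;
        scattered = true;
        px += tbest * dx; py += tbest * dy; pz += tbest * dz;
        double nx = px - cx[ibest], ny = py - cy[ibest], nz = pz - cz[ibest];
        double nlen = std::sqrt(nx * nx + ny * ny + nz * nz);
        nx /= nlen; ny /= nlen; nz /= nlen;
        // snap the hit point onto the sphere surface and keep the
        // direction unit-length: tiny off-surface errors otherwise
        // amplify multiplicatively along deep bounce chains
        px = cx[ibest] + radii[ibest] * nx;
        py = cy[ibest] + radii[ibest] * ny;
        pz = cz[ibest] + radii[ibest] * nz;
        double dn = dx * nx + dy * ny + dz * nz;
        dx -= 2.0 * dn * nx; dy -= 2.0 * dn * ny; dz -= 2.0 * dn * nz;
        double dlen = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= dlen; dy /= dlen; dz /= dlen;
        // nudge off the surface to avoid re-intersecting at t ~ 0
        px += 1e-9 * dx; py += 1e-9 * dy; pz += 1e-9 * dz;
      }
      if (scattered) wsum += 1.0 - dz;   // 1 - cos(theta_total)
    }
    cs[o] = box * wsum / (double)n_samples;
  }
  return cs;
}
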