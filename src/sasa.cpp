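#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-spiral test-point lattice (no RNG, bit-reproducible).
// Neighbour candidates are atoms within r_i + r_j + 2*probe of atom i.
//
// Each atom's lattice is expressed in a local frame built from its two
// nearest neighbours, so the frame co-rotates with the molecule and the
// computed areas are invariant under rigid motion (up to floating point),
// not just under translation.

// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int npoints) {
  const int n = coords.nrow();
  if (npoints < 1) stop("npoints must be positive");

  // quasi-uniform unit sphere lattice (golden spiral)
  std::vector<double> sx(npoints), sy(npoints), sz(npoints);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    sx[k] = r * std::cos(phi); sy[k] = r * std::sin(phi); sz[k] = z;
  }

  NumericVector area(n);
  std::vector<int> nb; nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double cut = radii[i] + radii[j] + 2.0 * probe;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi, dz = coords(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    // local frame from the two nearest neighbours (falls back to the global
    // axes for isolated atoms or collinear neighbourhoods)
    double e1[3] = {1, 0, 0}, e2[3] = {0, 1, 0}, e3[3] = {0, 0, 1};
    if (!nb.empty()) {
      int j1 = -1; double best = R_PosInf;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi, dz = coords(j, 2) - zi;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) { best = d2; j1 = j; }
      }
      double v1[3] = {coords(j1, 0) - xi, coords(j1, 1) - yi, coords(j1, 2) - zi};
      double n1 = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
      for (int k = 0; k < 3; ++k) e1[k] = v1[k] / n1;
      // second-nearest neighbour not collinear with the first
      int j2 = -1; best = R_PosInf;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        if (j == j1) continue;
        double v[3] = {coords(j, 0) - xi, coords(j, 1) - yi, coords(j, 2) - zi};
        double d2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
        double dot = v[0] * e1[0] + v[1] * e1[1] + v[2] * e1[2];
        double perp2 = d2 - dot * dot;
        if (perp2 > 1e-6 * d2 && d2 < best) { best = d2; j2 = j; }
      }
      double v2[3];
      if (j2 >= 0) {
        for (int k = 0; k < 3; ++k) v2[k] = coords(j2, k) - coords(i, k);
      } else {
        // global axis least aligned with e1
        int ax = 0;
        if (std::fabs(e1[1]) < std::fabs(e1[ax])) ax = 1;
        if (std::fabs(e1[2]) < std::fabs(e1[ax])) ax = 2;
        v2[0] = v2[1] = v2[2] = 0.0; v2[ax] = 1.0;
      }
      double dot = v2[0] * e1[0] + v2[1] * e1[1] + v2[2] * e1[2];
      for (int k = 0; k < 3; ++k) v2[k] -= dot * e1[k];
      double n2 = std::sqrt(v2[0] * v2[0] + v2[1] * v2[1] + v2[2] * v2[2]);
      for (int k = 0; k < 3; ++k) e2[k] = v2[k] / n2;
      e3[0] = e1[1] * e2[2] - e1[2] * e2[1];
      e3[1] = e1[2] * e2[0] - e1[0] * e2[2];
      e3[2] = e1[0] * e2[1] - e1[1] * e2[0];
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double lx = sx[k], ly = sy[k], lz = sz[k];
      double ux = lx * e1[0] + ly * e2[0] + lz * e3[0];
      double uy = lx * e1[1] + ly * e2[1] + lz * e3[1];
      double uz = lx * e1[2] + ly * e2[2] + lz * e3[2];
      double px = xi + Ri * ux, py = yi + Ri * uy, pz = zi + Ri * uz;
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double Rj = radii[j] + probe;
        double dx = px - coords(j, 0), dy = py - coords(j, 1), dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)npoints;
  }
  return area;
}

// Volume of a union of spheres by voxel-centre counting on a grid whose
// voxel corners sit at global multiples of `step` (translation-consistent
// to within one voxel shell).

// [[Rcpp::export]]
double union_sphere_volume_cpp(NumericMatrix coords, NumericVector radii,
                               double step) {
  const int n = coords.nrow();
  if (step <= 0) stop("grid step must be positive");
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], coords(i, k) - radii[i]);
      hi[k] = std::max(hi[k], coords(i, k) + radii[i]);
    }
  long long i0[3], dim[3];
  for (int k = 0; k < 3; ++k) {
    i0[k] = (long long)std::floor(lo[k] / step) - 1;
    dim[k] = (long long)std::floor(hi[k] / step) + 2 - i0[k] + 1;
  }
  std::vector<bool> occ((size_t)(dim[0] * dim[1] * dim[2]), false);
  long long count = 0;
  for (int i = 0; i < n; ++i) {
    const double r2 = radii[i] * radii[i];
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    long long ax0 = (long long)std::floor((xi - radii[i]) / step);
    long long ax1 = (long long)std::floor((xi + radii[i]) / step) + 1;
    long long ay0 = (long long)std::floor((yi - radii[i]) / step);
    long long ay1 = (long long)std::floor((yi + radii[i]) / step) + 1;
    long long az0 = (long long)std::floor((zi - radii[i]) / step);
    long long az1 = (long long)std::floor((zi + radii[i]) / step) + 1;
    for (long long ix = ax0; ix <= ax1; ++ix) {
      double cx = (ix + 0.5) * step - xi;
      for (long long iy = ay0; iy <= ay1; ++iy) {
        double cy = (iy + 0.5) * step - yi;
        for (long long iz = az0; iz <= az1; ++iz) {
          double cz = (iz + 0.5) * step - zi;
          if (cx * cx + cy * cy + cz * cz > r2) continue;
          size_t key = (size_t)(((ix - i0[0]) * dim[1] + (iy - i0[1])) * dim[2] +
                                (iz - i0[2]));
          if (!occ[key]) { occ[key] = true; ++count; }
        }
      }
    }
  }
  return (double)count * step * step * step;
}
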