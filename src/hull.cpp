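#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Incremental 3-D convex hull over point rows of `pts`.
// Returns 1-based indices of the points that are hull vertices.
// Visibility tolerance is an absolute distance (Angstrom here) scaled to the
// coordinate range, so near-coplanar jitter at the 1e-3 coordinate precision
// of PDB files does not create sliver faces.

struct Face {
  int a, b, c;          // vertex indices, outward (counter-clockwise) order
  double nx, ny, nz, d; // unit outward normal and plane offset
  bool alive;
};

static inline void set_plane(Face &f, const NumericMatrix &P) {
  double ax = P(f.a, 0), ay = P(f.a, 1), az = P(f.a, 2);
  double ux = P(f.b, 0) - ax, uy = P(f.b, 1) - ay, uz = P(f.b, 2) - az;
  double vx = P(f.c, 0) - ax, vy = P(f.c, 1) - ay, vz = P(f.c, 2) - az;
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nrm < 1e-300) nrm = 1e-300;
  f.nx = nx / nrm; f.ny = ny / nrm; f.nz = nz / nrm;
  f.d = f.nx * ax + f.ny * ay + f.nz * az;
}

static inline double face_dist(const Face &f, const NumericMatrix &P, int i) {
  return f.nx * P(i, 0) + f.ny * P(i, 1) + f.nz * P(i, 2) - f.d;
}

// [[Rcpp::export]]
IntegerVector hull_vertices_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      if (pts(i, k) < lo[k]) lo[k] = pts(i, k);
      if (pts(i, k) > hi[k]) hi[k] = pts(i, k);
    }
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) scale = std::max(scale, hi[k] - lo[k]);
  if (scale <= 0) stop("degenerate input: all points coincide");
  const double eps = 1e-9 * scale;

  // initial simplex: farthest pair along the widest axis, then farthest from
  // the line, then farthest from the plane
  int i0 = 0, i1 = 0;
  {
    int axis = 0;
    for (int k = 1; k < 3; ++k) if (hi[k] - lo[k] > hi[axis] - lo[axis]) axis = k;
    for (int i = 1; i < n; ++i) {
      if (pts(i, axis) < pts(i0, axis)) i0 = i;
      if (pts(i, axis) > pts(i1, axis)) i1 = i;
    }
  }
  double dx = pts(i1, 0) - pts(i0, 0), dy = pts(i1, 1) - pts(i0, 1),
         dz = pts(i1, 2) - pts(i0, 2);
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0) - pts(i0, 0), py = pts(i, 1) - pts(i0, 1),
           pz = pts(i, 2) - pts(i0, 2);
    double cx = dy * pz - dz * py, cy = dz * px - dx * pz, cz = dx * py - dy * px;
    double d2 = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0) stop("degenerate input: points are collinear");
  Face f0; f0.a = i0; f0.b = i1; f0.c = i2; f0.alive = true;
  set_plane(f0, pts);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(face_dist(f0, pts, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate input: points are coplanar");

  std::vector<Face> faces;
  faces.reserve(8 * (size_t)std::sqrt((double)n) + 64);
  {
    int v[4] = {i0, i1, i2, i3};
    double cx = 0, cy = 0, cz = 0;
    for (int k = 0; k < 4; ++k) { cx += pts(v[k], 0); cy += pts(v[k], 1); cz += pts(v[k], 2); }
    cx /= 4; cy /= 4; cz /= 4;
    int tri[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
    for (int t = 0; t < 4; ++t) {
      Face f; f.a = tri[t][0]; f.b = tri[t][1]; f.c = tri[t][2]; f.alive = true;
      set_plane(f, pts);
      if (f.nx * cx + f.ny * cy + f.nz * cz - f.d > 0) { // flip outward
        std::swap(f.b, f.c); set_plane(f, pts);
      }
      faces.push_back(f);
    }
  }

  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (!faces[fi].alive) continue;
      if (face_dist(faces[fi], pts, i) > eps) visible.push_back((int)fi);
    }
    if (visible.empty()) continue; // inside or on the current hull

    // horizon = directed edges of visible faces whose reverse edge is not
    // also on a visible face
    std::set<std::pair<int, int> > edges;
    for (size_t k = 0; k < visible.size(); ++k) {
      const Face &f = faces[visible[k]];
      edges.insert(std::make_pair(f.a, f.b));
      edges.insert(std::make_pair(f.b, f.c));
      edges.insert(std::make_pair(f.c, f.a));
    }
    for (size_t k = 0; k < visible.size(); ++k) faces[visible[k]].alive = false;
    for (std::set<std::pair<int, int> >::const_iterator it = edges.begin();
         it != edges.end(); ++it) {
      if (edges.count(std::make_pair(it->second, it->first))) continue;
      Face f; f.a = it->first; f.b = it->second; f.c = i; f.alive = true;
      set_plane(f, pts);
      faces.push_back(f);
    }
  }

  std::set<int> verts;
  for (size_t fi = 0; fi < faces.size(); ++fi)
    if (faces[fi].alive) { verts.insert(faces[fi].a); verts.insert(faces[fi].b); verts.insert(faces[fi].c); }
  IntegerVector out(verts.size());
  int j = 0;
  for (std::set<int>::const_iterator it = verts.begin(); it != verts.end(); ++it)
    out[j++] = *it + 1;
  return out;
}
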