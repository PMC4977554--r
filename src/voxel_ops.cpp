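// Low-level 3D voxel kernels: connected-component labelling, anisotropic
// Euclidean distance transform, and voxelised convex hulls. Arrays follow the
// package convention dim = c(Z, Y, X) with the first index varying fastest,
// i.e. linear index = z + nz * (y + ny * x).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur / (nz * ny);
      int rem = cur - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int nb = idx3(zz, yy, xx, nz, ny);
            if (mask[nb] && !lab[nb]) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// sample spacing d along the scanned axis.
static void edt1d(std::vector<double> &f, std::vector<double> &out,
                  std::vector<int> &v, std::vector<double> &zb, double d) {
  const int n = (int)f.size();
  const double INF = 1e30;
  // envelope over sites with finite f only
  int k = -1;
  const double d2 = d * d;
  for (int q = 0; q < n; ++q) {
    if (f[q] >= INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + (double)q * q * d2) - (f[v[k]] + (double)v[k] * v[k] * d2)) /
          (2.0 * d2 * (q - v[k]));
      if (s <= zb[k] && k > 0) { --k; } else break;
    }
    if (s <= zb[k] && k == 0) {
      v[0] = q; zb[0] = -INF; zb[1] = INF;
    } else {
      ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
    }
  }
  if (k < 0) { // no finite site on this line
    for (int q = 0; q < n; ++q) out[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[j + 1] < q) ++j;
    double dq = (double)(q - v[j]) * d;
    out[q] = dq * dq + f[v[j]];
  }
}

// Squared Euclidean distance from every voxel to the nearest zero (false)
// voxel of `mask`, with per-axis voxel spacings (dz, dy, dx). Voxels of an
// all-true mask get a large finite sentinel.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  const double INF = 1e30;
  if (mask.size() != n) stop("mask length does not match dims");
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), out(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      f.assign(nz, 0.0);
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(z, y, x, nz, ny)];
      out.assign(nz, 0.0);
      edt1d(f, out, v, zb, spacing[0]);
      for (int z = 0; z < nz; ++z) g[idx3(z, y, x, nz, ny)] = out[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      f.assign(ny, 0.0);
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(z, y, x, nz, ny)];
      out.assign(ny, 0.0);
      edt1d(f, out, v, zb, spacing[1]);
      for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = out[y];
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      f.assign(nx, 0.0);
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(z, y, x, nz, ny)];
      out.assign(nx, 0.0);
      edt1d(f, out, v, zb, spacing[2]);
      for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = out[x];
    }
  g.attr("dim") = dims;
  return g;
}

// ---------------------------------------------------------------------------
// Quickhull in 3D. Returns outward facet normals and offsets so that a point
// p is inside the hull iff dot(n_i, p) <= off_i + eps for all facets i.

struct Face {
  int a, b, c;
  double nx, ny, nz, off;
  bool alive;
  std::vector<int> out; // indices of points outside this face
  int far_idx;
  double far_dist;
};

static inline void face_plane(Face &f, const std::vector<double> &px,
                              const std::vector<double> &py,
                              const std::vector<double> &pz) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  double nrm = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  if (nrm > 0) { f.nx /= nrm; f.ny /= nrm; f.nz /= nrm; }
  f.off = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
}

static inline double face_dist(const Face &f, double x, double y, double z) {
  return f.nx * x + f.ny * y + f.nz * z - f.off;
}

// [[Rcpp::export(name = ".quickhull3d")]]
List quickhull3d(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  std::vector<double> px(n), py(n), pz(n);
  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    double c[3] = {px[i], py[i], pz[i]};
    for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], c[k]); hi[k] = std::max(hi[k], c[k]); }
  }
  double diam = 0;
  for (int k = 0; k < 3; ++k) diam = std::max(diam, hi[k] - lo[k]);
  const double eps = 1e-9 * std::max(diam, 1.0);

  // initial extreme pair: most separated along the widest axis
  int wax = 0;
  for (int k = 1; k < 3; ++k) if (hi[k] - lo[k] > hi[wax] - lo[wax]) wax = k;
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    double c = (wax == 0 ? px[i] : (wax == 1 ? py[i] : pz[i]));
    double c0 = (wax == 0 ? px[i0] : (wax == 1 ? py[i0] : pz[i0]));
    double c1 = (wax == 0 ? px[i1] : (wax == 1 ? py[i1] : pz[i1]));
    if (c < c0) i0 = i;
    if (c > c1) i1 = i;
  }
  if (i0 == i1) stop("degenerate point set (all points coincident along widest axis)");
  // farthest from the line i0-i1
  double ex = px[i1] - px[i0], ey = py[i1] - py[i0], ez = pz[i1] - pz[i0];
  double el2 = ex * ex + ey * ey + ez * ez;
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double wx = px[i] - px[i0], wy = py[i] - py[i0], wz = pz[i] - pz[i0];
    double cxn = wy * ez - wz * ey, cyn = wz * ex - wx * ez, czn = wx * ey - wy * ex;
    double d2 = (cxn * cxn + cyn * cyn + czn * czn) / el2;
    double d = std::sqrt(d2);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set (collinear)");
  // farthest from the plane i0-i1-i2
  Face base{i0, i1, i2, 0, 0, 0, 0, true, {}, -1, 0};
  face_plane(base, px, py, pz);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(face_dist(base, px[i], py[i], pz[i]));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set (coplanar)");

  std::vector<Face> faces;
  faces.reserve(256);
  double cx = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  double cy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  double cz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;
  int tetra[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int t = 0; t < 4; ++t) {
    Face f{tetra[t][0], tetra[t][1], tetra[t][2], 0, 0, 0, 0, true, {}, -1, 0};
    face_plane(f, px, py, pz);
    if (face_dist(f, cx, cy, cz) > 0) { std::swap(f.b, f.c); face_plane(f, px, py, pz); }
    faces.push_back(f);
  }
  // initial outside sets
  for (int i = 0; i < n; ++i) {
    for (auto &f : faces) {
      double d = face_dist(f, px[i], py[i], pz[i]);
      if (d > eps) {
        f.out.push_back(i);
        if (d > f.far_dist) { f.far_dist = d; f.far_idx = i; }
        break;
      }
    }
  }

  std::queue<int> work;
  for (int t = 0; t < (int)faces.size(); ++t)
    if (!faces[t].out.empty()) work.push(t);

  while (!work.empty()) {
    int fi = work.front(); work.pop();
    if (!faces[fi].alive || faces[fi].out.empty()) continue;
    int p = faces[fi].far_idx;
    double ppx = px[p], ppy = py[p], ppz = pz[p];
    // visible faces
    std::vector<int> vis;
    for (int t = 0; t < (int)faces.size(); ++t)
      if (faces[t].alive && face_dist(faces[t], ppx, ppy, ppz) > eps) vis.push_back(t);
    if (vis.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::unordered_set<int64_t> edges;
    auto key = [](int u, int v) { return ((int64_t)u << 32) | (uint32_t)v; };
    for (int t : vis) {
      const Face &f = faces[t];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) edges.insert(key(e[j][0], e[j][1]));
    }
    std::vector<std::pair<int, int>> horizon;
    for (int t : vis) {
      const Face &f = faces[t];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j)
        if (!edges.count(key(e[j][1], e[j][0]))) horizon.emplace_back(e[j][0], e[j][1]);
    }
    // pool of points to redistribute
    std::vector<int> pool;
    for (int t : vis) {
      for (int q : faces[t].out) if (q != p) pool.push_back(q);
      faces[t].alive = false;
      faces[t].out.clear();
    }
    // build new faces
    std::vector<int> created;
    for (auto &e : horizon) {
      Face f{e.first, e.second, p, 0, 0, 0, 0, true, {}, -1, 0};
      face_plane(f, px, py, pz);
      if (face_dist(f, cx, cy, cz) > 0) { std::swap(f.a, f.b); face_plane(f, px, py, pz); }
      faces.push_back(f);
      created.push_back((int)faces.size() - 1);
    }
    for (int q : pool) {
      for (int t : created) {
        double d = face_dist(faces[t], px[q], py[q], pz[q]);
        if (d > eps) {
          faces[t].out.push_back(q);
          if (d > faces[t].far_dist) { faces[t].far_dist = d; faces[t].far_idx = q; }
          break;
        }
      }
    }
    for (int t : created)
      if (!faces[t].out.empty()) work.push(t);
  }

  int m = 0;
  for (auto &f : faces) if (f.alive) ++m;
  NumericMatrix normals(m, 3);
  NumericVector offsets(m);
  int r = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    normals(r, 0) = f.nx; normals(r, 1) = f.ny; normals(r, 2) = f.nz;
    offsets[r] = f.off;
    ++r;
  }
  return List::create(_["normals"] = normals, _["offsets"] = offsets);
}

// [[Rcpp::export(name = ".points_in_hull")]]
LogicalVector points_in_hull(NumericMatrix pts, NumericMatrix normals,
                             NumericVector offsets, double eps) {
  const int n = pts.nrow(), m = normals.nrow();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    bool in = true;
    for (int j = 0; j < m; ++j) {
      if (normals(j, 0) * x + normals(j, 1) * y + normals(j, 2) * z > offsets[j] + eps) {
        in = false;
        break;
      }
    }
    inside[i] = in;
  }
  return inside;
}
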