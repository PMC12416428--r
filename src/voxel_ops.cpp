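// 3D voxel primitives: connected labeling, Euclidean distance transform,
// grayscale reconstruction, regional maxima, marker watershed, label growth,
// separable Gaussian, local thickness, marching-tetrahedra surface tensor.
//
// All arrays are column-major with dim = (nz, ny, nx): linear index
// i = z + nz*(y + ny*x), matching R arrays indexed [z, y, x].

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct Grid {
  int nz, ny, nx;
  Grid(const IntegerVector &dim) : nz(dim[0]), ny(dim[1]), nx(dim[2]) {}
  inline int idx(int z, int y, int x) const { return z + nz * (y + ny * x); }
  inline void coords(int i, int &z, int &y, int &x) const {
    z = i % nz; int r = i / nz; y = r % ny; x = r / ny;
  }
  inline int n() const { return nz * ny * nx; }
};

// neighbor offsets for 6- or 26-connectivity
static void neighbor_offsets(int connectivity,
                             std::vector<int> &dz, std::vector<int> &dy,
                             std::vector<int> &dx) {
  dz.clear(); dy.clear(); dx.clear();
  if (connectivity == 6) {
    int oz[] = {-1, 1, 0, 0, 0, 0};
    int oy[] = {0, 0, -1, 1, 0, 0};
    int ox[] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) { dz.push_back(oz[k]); dy.push_back(oy[k]); dx.push_back(ox[k]); }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dz.push_back(a); dy.push_back(b); dx.push_back(c);
        }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  Grid g(dim);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  IntegerVector lab(g.n(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < g.n(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int z, y, x; g.coords(p, z, y, x);
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
          continue;
        int q = g.idx(zz, yy, xx);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &zbnd) {
  int k = 0;
  v[0] = 0;
  zbnd[0] = -1e30; zbnd[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbnd[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbnd[k] = s; zbnd[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbnd[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// 3-pass separable squared EDT over a raw buffer with dims (nz, ny, nx)
static void edt_sq_buffer(std::vector<double> &D, int nz, int ny, int nx) {
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zbnd(nmax + 1);
  std::vector<int> v(nmax);
  #define IDX(z, y, x) ((z) + nz * ((y) + ny * (x)))
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = D[IDX(z, y, x)];
      dt1d(f, d, nz, v, zbnd);
      for (int z = 0; z < nz; ++z) D[IDX(z, y, x)] = d[z];
    }
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = D[IDX(z, y, x)];
      dt1d(f, d, ny, v, zbnd);
      for (int y = 0; y < ny; ++y) D[IDX(z, y, x)] = d[y];
    }
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = D[IDX(z, y, x)];
      dt1d(f, d, nx, v, zbnd);
      for (int x = 0; x < nx; ++x) D[IDX(z, y, x)] = d[x];
    }
  #undef IDX
}

// squared Euclidean distance to the nearest !inside voxel; if pad_background,
// the volume is surrounded by one layer of background voxels before the
// transform (the image boundary acts as background).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector inside, IntegerVector dim,
                         bool pad_background) {
  Grid g(dim);
  const double INF = 1e30;
  if (!pad_background) {
    std::vector<double> D(g.n());
    for (int i = 0; i < g.n(); ++i) D[i] = inside[i] ? INF : 0.0;
    edt_sq_buffer(D, g.nz, g.ny, g.nx);
    NumericVector out(g.n());
    for (int i = 0; i < g.n(); ++i) out[i] = D[i];
    out.attr("dim") = dim;
    return out;
  }
  int pz = g.nz + 2, py = g.ny + 2, px = g.nx + 2;
  std::vector<double> D((size_t)pz * py * px, 0.0);
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z)
        if (inside[g.idx(z, y, x)])
          D[(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1))] = INF;
  edt_sq_buffer(D, pz, py, px);
  NumericVector out(g.n());
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z)
        out[g.idx(z, y, x)] =
          D[(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1))];
  out.attr("dim") = dim;
  return out;
}

// morphological reconstruction by dilation of marker under mask
// (Vincent 1993 hybrid raster/FIFO algorithm)
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker, NumericVector mask,
                                       IntegerVector dim, int connectivity) {
  Grid g(dim);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  int nn = (int)dz.size();
  std::vector<int> off(nn);
  for (int k = 0; k < nn; ++k) off[k] = dz[k] + g.nz * (dy[k] + g.ny * dx[k]);
  NumericVector J = clone(marker);
  for (int i = 0; i < g.n(); ++i) if (J[i] > mask[i]) J[i] = mask[i];

  // forward raster scan: neighbors with negative linear offset precede
  for (int i = 0; i < g.n(); ++i) {
    int z, y, x; g.coords(i, z, y, x);
    double m = J[i];
    for (int k = 0; k < nn; ++k) {
      if (off[k] >= 0) continue;
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      double v = J[g.idx(zz, yy, xx)];
      if (v > m) m = v;
    }
    if (m > mask[i]) m = mask[i];
    J[i] = m;
  }
  // backward raster scan + queue seeding
  std::queue<int> fifo;
  for (int i = g.n() - 1; i >= 0; --i) {
    int z, y, x; g.coords(i, z, y, x);
    double m = J[i];
    for (int k = 0; k < nn; ++k) {
      if (off[k] <= 0) continue;
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      double v = J[g.idx(zz, yy, xx)];
      if (v > m) m = v;
    }
    if (m > mask[i]) m = mask[i];
    J[i] = m;
    for (int k = 0; k < nn; ++k) {
      if (off[k] <= 0) continue;
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      int q = g.idx(zz, yy, xx);
      if (J[q] < J[i] && J[q] < mask[q]) { fifo.push(i); break; }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int z, y, x; g.coords(p, z, y, x);
    for (int k = 0; k < nn; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      int q = g.idx(zz, yy, xx);
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dim;
  return J;
}

// regional maxima of f restricted to mask (plateau-aware)
// [[Rcpp::export]]
LogicalVector cpp_regional_maxima(NumericVector f, LogicalVector mask,
                                  IntegerVector dim, int connectivity) {
  Grid g(dim);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  std::vector<uint8_t> notmax(g.n(), 0);
  std::queue<int> q;
  for (int i = 0; i < g.n(); ++i) {
    if (!mask[i]) continue;
    int z, y, x; g.coords(i, z, y, x);
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      int j = g.idx(zz, yy, xx);
      if (mask[j] && f[j] > f[i]) { notmax[i] = 1; q.push(i); break; }
    }
  }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int z, y, x; g.coords(p, z, y, x);
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      int j = g.idx(zz, yy, xx);
      if (mask[j] && !notmax[j] && f[j] == f[p]) { notmax[j] = 1; q.push(j); }
    }
  }
  LogicalVector out(g.n());
  for (int i = 0; i < g.n(); ++i) out[i] = mask[i] && !notmax[i];
  out.attr("dim") = dim;
  return out;
}

// marker-controlled flooding: highest priority first, FIFO among ties,
// markers seeded in ascending voxel order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim,
                            int connectivity) {
  Grid g(dim);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  IntegerVector lab(g.n(), 0);
  typedef std::pair<double, int64_t> Item; // (priority, -counter) packed
  std::priority_queue<std::pair<std::pair<double, int64_t>, int> > pq;
  int64_t counter = 0;
  for (int i = 0; i < g.n(); ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(std::make_pair(std::make_pair(priority[i], -counter), i));
      ++counter;
    }
  }
  while (!pq.empty()) {
    int p = pq.top().second; pq.pop();
    int z, y, x; g.coords(p, z, y, x);
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      int q = g.idx(zz, yy, xx);
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[p];
        pq.push(std::make_pair(std::make_pair(priority[q], -counter), q));
        ++counter;
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// grow labels into background by `iterations` synchronous 6-neighbor steps;
// a background voxel takes the smallest adjacent positive label.
// [[Rcpp::export]]
IntegerVector cpp_grow_labels(IntegerVector labels, IntegerVector dim,
                              int iterations) {
  Grid g(dim);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(6, dz, dy, dx);
  IntegerVector cur = clone(labels);
  for (int it = 0; it < iterations; ++it) {
    IntegerVector nxt = clone(cur);
    bool changed = false;
    for (int i = 0; i < g.n(); ++i) {
      if (cur[i] != 0) continue;
      int z, y, x; g.coords(i, z, y, x);
      int best = 0;
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
          continue;
        int v = cur[g.idx(zz, yy, xx)];
        if (v > 0 && (best == 0 || v < best)) best = v;
      }
      if (best > 0) { nxt[i] = best; changed = true; }
    }
    cur = nxt;
    if (!changed) break;
  }
  cur.attr("dim") = dim;
  return cur;
}

// separable Gaussian blur, mirror boundary
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, double sigma) {
  Grid g(dim);
  if (sigma <= 0) { NumericVector out = clone(vol); out.attr("dim") = dim; return out; }
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int k = -r; k <= r; ++k) {
    ker[k + r] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += ker[k + r];
  }
  for (int k = 0; k < 2 * r + 1; ++k) ker[k] /= s;
  NumericVector A = clone(vol), B(g.n());
  int dims[3] = {g.nz, g.ny, g.nx};
  for (int axis = 0; axis < 3; ++axis) {
    int n = dims[axis];
    for (int i = 0; i < g.n(); ++i) {
      int z, y, x; g.coords(i, z, y, x);
      int c[3] = {z, y, x};
      double acc = 0;
      for (int k = -r; k <= r; ++k) {
        int p = c[axis] + k;
        if (p < 0) p = -p - 1;
        if (p >= n) p = 2 * n - p - 1;
        if (p < 0) p = 0;           // degenerate tiny axis
        if (p >= n) p = n - 1;
        int cc[3] = {c[0], c[1], c[2]};
        cc[axis] = p;
        acc += ker[k + r] * A[g.idx(cc[0], cc[1], cc[2])];
      }
      B[i] = acc;
    }
    std::swap(A, B);
  }
  A.attr("dim") = dim;
  return A;
}

// local thickness by sphere painting: thickness(v) = 2 * max r over spheres
// of radius r = edt - 0.5 containing v; centers pruned to non-dominated ones.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector edt, IntegerVector dim) {
  Grid g(dim);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(26, dz, dy, dx);
  NumericVector out(g.n(), 0.0);
  std::vector<std::pair<double, int> > centers;
  for (int i = 0; i < g.n(); ++i) {
    if (edt[i] <= 0) continue;
    int z, y, x; g.coords(i, z, y, x);
    bool dominated = false;
    for (size_t k = 0; k < dz.size() && !dominated; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= g.nz || yy < 0 || yy >= g.ny || xx < 0 || xx >= g.nx)
        continue;
      double dd = std::sqrt((double)(dz[k]*dz[k] + dy[k]*dy[k] + dx[k]*dx[k]));
      if (edt[g.idx(zz, yy, xx)] >= edt[i] + dd) dominated = true;
    }
    if (!dominated) centers.push_back(std::make_pair(edt[i], i));
  }
  std::sort(centers.begin(), centers.end());
  for (int c = (int)centers.size() - 1; c >= 0; --c) {
    double r = centers[c].first - 0.5;
    if (r < 0) continue;
    int i = centers[c].second;
    int z, y, x; g.coords(i, z, y, x);
    int ir = (int)std::floor(r);
    double r2 = r * r, d = 2.0 * r;
    for (int a = std::max(0, z - ir); a <= std::min(g.nz - 1, z + ir); ++a)
      for (int b = std::max(0, y - ir); b <= std::min(g.ny - 1, y + ir); ++b)
        for (int e = std::max(0, x - ir); e <= std::min(g.nx - 1, x + ir); ++e) {
          double q2 = (double)(a-z)*(a-z) + (double)(b-y)*(b-y) + (double)(e-x)*(e-x);
          if (q2 <= r2) {
            int j = g.idx(a, b, e);
            if (edt[j] > 0 && out[j] < d) out[j] = d;
          }
        }
  }
  // every in-phase voxel is itself the center of a sphere of radius edt-0.5
  for (int i = 0; i < g.n(); ++i)
    if (edt[i] > 0 && out[i] < 2.0 * (edt[i] - 0.5))
      out[i] = 2.0 * (edt[i] - 0.5);
  out.attr("dim") = dim;
  return out;
}

// marching tetrahedra: accumulate  sum_t A_t n_t n_t^T  and total area of the
// `level` iso-surface. The integrand is even in n, so orientation is moot.
// Coordinates are voxel indices (z, y, x), zero-based.
// [[Rcpp::export]]
List cpp_mesh_tensor(NumericVector vol, IntegerVector dim, double level) {
  Grid g(dim);
  static const int OFF[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int TETS[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double T[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
  double area = 0;
  double P[8][3], val[8];
  for (int x = 0; x < g.nx - 1; ++x)
    for (int y = 0; y < g.ny - 1; ++y)
      for (int z = 0; z < g.nz - 1; ++z) {
        int nin = 0;
        for (int v = 0; v < 8; ++v) {
          int zz = z + OFF[v][0], yy = y + OFF[v][1], xx = x + OFF[v][2];
          val[v] = vol[g.idx(zz, yy, xx)];
          P[v][0] = zz; P[v][1] = yy; P[v][2] = xx;
          if (val[v] > level) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (val[vi[k]] > level) ins[ni++] = vi[k];
            else outs[no++] = vi[k];
          }
          if (ni == 0 || ni == 4) continue;
          double pts[4][3];
          int ntri = 0;
          double tris[2][3][3];
          // edge interpolation helper
          #define INTERP(a, b, dst) do { \
            double tt = (level - val[a]) / (val[b] - val[a]); \
            for (int d3 = 0; d3 < 3; ++d3) \
              dst[d3] = P[a][d3] + tt * (P[b][d3] - P[a][d3]); \
          } while (0)
          if (ni == 1) {
            INTERP(ins[0], outs[0], pts[0]);
            INTERP(ins[0], outs[1], pts[1]);
            INTERP(ins[0], outs[2], pts[2]);
            for (int d3 = 0; d3 < 3; ++d3) {
              tris[0][0][d3] = pts[0][d3];
              tris[0][1][d3] = pts[1][d3];
              tris[0][2][d3] = pts[2][d3];
            }
            ntri = 1;
          } else if (ni == 3) {
            INTERP(ins[0], outs[0], pts[0]);
            INTERP(ins[1], outs[0], pts[1]);
            INTERP(ins[2], outs[0], pts[2]);
            for (int d3 = 0; d3 < 3; ++d3) {
              tris[0][0][d3] = pts[0][d3];
              tris[0][1][d3] = pts[1][d3];
              tris[0][2][d3] = pts[2][d3];
            }
            ntri = 1;
          } else { // 2 in / 2 out: quad -> two triangles
            INTERP(ins[0], outs[0], pts[0]);
            INTERP(ins[0], outs[1], pts[1]);
            INTERP(ins[1], outs[1], pts[2]);
            INTERP(ins[1], outs[0], pts[3]);
            for (int d3 = 0; d3 < 3; ++d3) {
              tris[0][0][d3] = pts[0][d3];
              tris[0][1][d3] = pts[1][d3];
              tris[0][2][d3] = pts[2][d3];
              tris[1][0][d3] = pts[0][d3];
              tris[1][1][d3] = pts[2][d3];
              tris[1][2][d3] = pts[3][d3];
            }
            ntri = 2;
          }
          #undef INTERP
          for (int q = 0; q < ntri; ++q) {
            double e1[3], e2[3], cr[3];
            for (int d3 = 0; d3 < 3; ++d3) {
              e1[d3] = tris[q][1][d3] - tris[q][0][d3];
              e2[d3] = tris[q][2][d3] - tris[q][0][d3];
            }
            cr[0] = e1[1]*e2[2] - e1[2]*e2[1];
            cr[1] = e1[2]*e2[0] - e1[0]*e2[2];
            cr[2] = e1[0]*e2[1] - e1[1]*e2[0];
            double a2 = std::sqrt(cr[0]*cr[0] + cr[1]*cr[1] + cr[2]*cr[2]);
            if (a2 <= 0) continue;
            double A = 0.5 * a2;
            for (int d3 = 0; d3 < 3; ++d3) cr[d3] /= a2;
            for (int i2 = 0; i2 < 3; ++i2)
              for (int j2 = 0; j2 < 3; ++j2)
                T[i2][j2] += A * cr[i2] * cr[j2];
            area += A;
          }
        }
      }
  NumericMatrix Tm(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Tm(i, j) = T[i][j];
  return List::create(_["tensor"] = Tm, _["area"] = area);
}
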