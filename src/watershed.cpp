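// Tolerance-based marker-controlled watershed primitives for 3D stacks.
// Arrays are R numeric vectors with dim = c(nx, ny, nz), x fastest
// (column-major), 0-based linear index i = x + nx*(y + ny*z).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  R_xlen_t n;
  Grid(IntegerVector dim) {
    if (dim.size() != 3) stop("dim must have length 3");
    nx = dim[0]; ny = dim[1]; nz = dim[2];
    n = (R_xlen_t)nx * ny * nz;
  }
  inline void coords(R_xlen_t i, int &x, int &y, int &z) const {
    x = (int)(i % nx);
    y = (int)((i / nx) % ny);
    z = (int)(i / ((R_xlen_t)nx * ny));
  }
  inline R_xlen_t index(int x, int y, int z) const {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  }
  // Collect neighbor linear indices of voxel i under 6- or 26-connectivity.
  inline int neighbors(R_xlen_t i, int conn, R_xlen_t *out) const {
    int x, y, z, k = 0;
    coords(i, x, y, z);
    if (conn == 6) {
      if (x > 0)      out[k++] = index(x - 1, y, z);
      if (x < nx - 1) out[k++] = index(x + 1, y, z);
      if (y > 0)      out[k++] = index(x, y - 1, z);
      if (y < ny - 1) out[k++] = index(x, y + 1, z);
      if (z > 0)      out[k++] = index(x, y, z - 1);
      if (z < nz - 1) out[k++] = index(x, y, z + 1);
    } else {
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                zz < 0 || zz >= nz) continue;
            out[k++] = index(xx, yy, zz);
          }
    }
    return k;
  }
};

} // namespace

// Morphological reconstruction by erosion of `marker` constrained from
// below by `mask` (requires marker >= mask pointwise). Iterated forward /
// backward raster sweeps until stable; used for the h-minima transform
// reconstruct_erosion(image + h, image).
// [[Rcpp::export]]
NumericVector cpp_reconstruct_erosion(NumericVector marker, NumericVector mask,
                                      IntegerVector dim, int conn) {
  Grid g(dim);
  if (marker.size() != g.n || mask.size() != g.n)
    stop("marker/mask size does not match dim");
  NumericVector r = clone(marker);
  R_xlen_t nb[26];
  bool changed = true;
  while (changed) {
    changed = false;
    for (R_xlen_t i = 0; i < g.n; ++i) {
      int k = g.neighbors(i, conn, nb);
      double m = r[i];
      for (int j = 0; j < k; ++j)
        if (nb[j] < i && r[nb[j]] < m) m = r[nb[j]];
      double v = std::max(mask[i], m);
      if (v < r[i]) { r[i] = v; changed = true; }
    }
    for (R_xlen_t i = g.n - 1; i >= 0; --i) {
      int k = g.neighbors(i, conn, nb);
      double m = r[i];
      for (int j = 0; j < k; ++j)
        if (nb[j] > i && r[nb[j]] < m) m = r[nb[j]];
      double v = std::max(mask[i], m);
      if (v < r[i]) { r[i] = v; changed = true; }
    }
  }
  return r;
}

// Label regional minima: connected plateaus (equal-valued, conn-connected)
// with no strictly lower neighbor. Labels assigned in scan order of the
// first plateau voxel encountered, so output is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_regional_minima(NumericVector image, IntegerVector dim,
                                  int conn) {
  Grid g(dim);
  if (image.size() != g.n) stop("image size does not match dim");
  IntegerVector lab(g.n, 0);
  std::vector<char> visited(g.n, 0);
  R_xlen_t nb[26];
  int next = 0;
  std::vector<R_xlen_t> plateau;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (visited[i]) continue;
    // BFS over the plateau at image[i]
    double v = image[i];
    plateau.clear();
    bool is_min = true;
    visited[i] = 1;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t p = q.front(); q.pop();
      plateau.push_back(p);
      int k = g.neighbors(p, conn, nb);
      for (int j = 0; j < k; ++j) {
        R_xlen_t u = nb[j];
        if (image[u] < v) is_min = false;
        else if (image[u] == v && !visited[u]) { visited[u] = 1; q.push(u); }
      }
    }
    if (is_min) {
      ++next;
      for (size_t j = 0; j < plateau.size(); ++j) lab[plateau[j]] = next;
    }
  }
  return lab;
}

// Marker-controlled flooding. Deterministic rule, mirrored by the naive R
// oracle used in the tests: repeatedly take the unlabeled voxel adjacent to
// a labeled one that minimizes (image value, linear index); assign it the
// label of its labeled neighbor minimizing (image value, linear index).
// Every voxel ends up labeled, so basins partition the grid.
// [[Rcpp::export]]
IntegerVector cpp_marker_watershed(NumericVector image, IntegerVector markers,
                                   IntegerVector dim, int conn) {
  Grid g(dim);
  if (image.size() != g.n || markers.size() != g.n)
    stop("image/markers size does not match dim");
  IntegerVector lab = clone(markers);
  typedef std::pair<double, R_xlen_t> Item; // (value, index), min-heap
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > heap;
  std::vector<char> inq(g.n, 0);
  R_xlen_t nb[26];
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (lab[i] != 0) continue;
    int k = g.neighbors(i, conn, nb);
    for (int j = 0; j < k; ++j)
      if (lab[nb[j]] != 0) {
        heap.push(Item(image[i], i));
        inq[i] = 1;
        break;
      }
  }
  while (!heap.empty()) {
    Item it = heap.top(); heap.pop();
    R_xlen_t p = it.second;
    if (lab[p] != 0) continue;
    // labeled neighbor with smallest (value, index)
    int k = g.neighbors(p, conn, nb);
    double bestv = R_PosInf;
    R_xlen_t besti = -1;
    int bestl = 0;
    for (int j = 0; j < k; ++j) {
      R_xlen_t u = nb[j];
      if (lab[u] != 0) {
        if (image[u] < bestv || (image[u] == bestv && u < besti)) {
          bestv = image[u]; besti = u; bestl = lab[u];
        }
      }
    }
    lab[p] = bestl;
    for (int j = 0; j < k; ++j) {
      R_xlen_t u = nb[j];
      if (lab[u] == 0 && !inq[u]) { heap.push(Item(image[u], u)); inq[u] = 1; }
    }
  }
  return lab;
}

// Connected-component labeling of a positive-integer marker image
// (0 = background); used to turn extended minima into watershed markers.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int conn) {
  Grid g(dim);
  if (mask.size() != g.n) stop("mask size does not match dim");
  IntegerVector lab(g.n, 0);
  R_xlen_t nb[26];
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t p = q.front(); q.pop();
      int k = g.neighbors(p, conn, nb);
      for (int j = 0; j < k; ++j) {
        R_xlen_t u = nb[j];
        if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; q.push(u); }
      }
    }
  }
  return lab;
}
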