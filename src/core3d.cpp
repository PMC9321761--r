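// Voxel-level kernels for 3D gray / binary volumes.
// Arrays arrive as flat vectors in R's column-major layout with dim = (nx, ny, nz):
// linear index = x + nx * (y + ny * z), 0-based here.  Axis order (x, y, z),
// z = slice index, matching the package's documented coordinate convention.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// half-sample symmetric reflection: -1 -> 0, n -> n-1
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static inline R_xlen_t lin(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// ---------------------------------------------------------------- median ----

// [[Rcpp::export]]
IntegerVector cpp_median3d(IntegerVector vol, IntegerVector dim, int width) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = width / 2;
  const int m = width * width * width;
  IntegerVector out(vol.size());
  std::vector<int> buf(m);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int k = 0;
        for (int dz = -r; dz <= r; ++dz) {
          int zz = reflect_idx(z + dz, nz);
          for (int dy = -r; dy <= r; ++dy) {
            int yy = reflect_idx(y + dy, ny);
            for (int dx = -r; dx <= r; ++dx) {
              int xx = reflect_idx(x + dx, nx);
              buf[k++] = vol[lin(xx, yy, zz, nx, ny)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[lin(x, y, z, nx, ny)] = buf[m / 2];
      }
  return out;
}

// ------------------------------------------------------- erosion/dilation ----

// offsets: m x 3 integer matrix of structuring-element offsets (centred).
// erode: voxel true iff every SE sample (reflect-padded) is object.
// dilate: voxel true iff any SE sample is object.

// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets, bool erosion) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = offsets.nrow();
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool acc = erosion;  // AND identity for erosion, OR identity for dilation
        for (int i = 0; i < m; ++i) {
          int xx = reflect_idx(x + offsets(i, 0), nx);
          int yy = reflect_idx(y + offsets(i, 1), ny);
          int zz = reflect_idx(z + offsets(i, 2), nz);
          bool v = mask[lin(xx, yy, zz, nx, ny)];
          if (erosion) { if (!v) { acc = false; break; } }
          else         { if (v)  { acc = true;  break; } }
        }
        out[lin(x, y, z, nx, ny)] = acc;
      }
  return out;
}

// ------------------------------------------------------- chamfer distance ----

// Two-pass (3,4,5) chamfer propagation.  Background = 0; object voxels get the
// integer chamfer cost to the nearest in-volume background voxel.  Voxels
// outside the volume are not treated as background (no padding).

// [[Rcpp::export]]
IntegerVector cpp_chamfer(LogicalVector mask, IntegerVector dim,
                          int wf, int we, int wv) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int INF = INT_MAX / 4;
  R_xlen_t n = mask.size();
  std::vector<int> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0;

  // forward mask: offsets lexicographically before (0,0,0) in scan order
  const int fo[13][3] = {
    {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
    {-1,1,-1},{0,1,-1},{1,1,-1},{-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0}};
  int fw[13];
  for (int i = 0; i < 13; ++i) {
    int nz0 = (fo[i][0] != 0) + (fo[i][1] != 0) + (fo[i][2] != 0);
    fw[i] = nz0 == 1 ? wf : (nz0 == 2 ? we : wv);
  }

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t p = lin(x, y, z, nx, ny);
        if (d[p] == 0) continue;
        int best = d[p];
        for (int i = 0; i < 13; ++i) {
          int xx = x + fo[i][0], yy = y + fo[i][1], zz = z + fo[i][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          int cand = d[lin(xx, yy, zz, nx, ny)] + fw[i];
          if (cand < best) best = cand;
        }
        d[p] = best;
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        R_xlen_t p = lin(x, y, z, nx, ny);
        if (d[p] == 0) continue;
        int best = d[p];
        for (int i = 0; i < 13; ++i) {
          int xx = x - fo[i][0], yy = y - fo[i][1], zz = z - fo[i][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          int cand = d[lin(xx, yy, zz, nx, ny)] + fw[i];
          if (cand < best) best = cand;
        }
        d[p] = best;
      }
  return IntegerVector(d.begin(), d.end());
}

// -------------------------------------- grayscale reconstruction (erosion) ----

// Reconstruction by erosion of `ref` from `marker` (marker >= ref pointwise),
// 26-neighbourhood: iterated raster/anti-raster sweeps until stable.
// Used by the H-minima transform: h_minima(f, h) = R^eps_f(f + h).

// [[Rcpp::export]]
NumericVector cpp_reconstruct_erosion(NumericVector marker, NumericVector ref,
                                      IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = marker.size();
  std::vector<double> g(marker.begin(), marker.end());

  const int fo[13][3] = {
    {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
    {-1,1,-1},{0,1,-1},{1,1,-1},{-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0}};

  bool changed = true;
  int guard = 0;
  while (changed && ++guard < 10000) {
    changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t p = lin(x, y, z, nx, ny);
          double v = g[p];
          for (int i = 0; i < 13; ++i) {
            int xx = x + fo[i][0], yy = y + fo[i][1], zz = z + fo[i][2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            double c = g[lin(xx, yy, zz, nx, ny)];
            if (c < v) v = c;
          }
          if (v < ref[p]) v = ref[p];
          if (v != g[p]) { g[p] = v; changed = true; }
        }
    for (int z = nz - 1; z >= 0; --z)
      for (int y = ny - 1; y >= 0; --y)
        for (int x = nx - 1; x >= 0; --x) {
          R_xlen_t p = lin(x, y, z, nx, ny);
          double v = g[p];
          for (int i = 0; i < 13; ++i) {
            int xx = x - fo[i][0], yy = y - fo[i][1], zz = z - fo[i][2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            double c = g[lin(xx, yy, zz, nx, ny)];
            if (c < v) v = c;
          }
          if (v < ref[p]) v = ref[p];
          if (v != g[p]) { g[p] = v; changed = true; }
        }
  }
  return NumericVector(g.begin(), g.end());
}

// ----------------------------------------------------- neighbourhood sets ----

static void conn_offsets(int connectivity, std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6  && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
}

// --------------------------------------------------- connected components ----

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  std::vector<std::array<int,3>> off;
  conn_offsets(connectivity, off);
  IntegerVector lab(n);  // zero-initialised
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t q = lin(xx, yy, zz, nx, ny);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// --------------------------------------------------------- regional minima ----

// Labels the regional minima (equal-value plateaus with no lower neighbour,
// 26-connectivity) of `relief` restricted to `mask`.  Labels are assigned in
// increasing order of the smallest linear voxel index of each minimum.

// [[Rcpp::export]]
IntegerVector cpp_regional_minima(NumericVector relief, LogicalVector mask,
                                  IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = relief.size();
  std::vector<std::array<int,3>> off;
  conn_offsets(26, off);
  std::vector<int> state(n, 0);  // 0 unvisited, 1 non-minimum, 2 minimum
  IntegerVector lab(n);
  std::vector<R_xlen_t> plateau, stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || state[s] != 0) continue;
    double v = relief[s];
    bool is_min = true;
    plateau.clear(); stack.clear();
    stack.push_back(s); state[s] = 1; plateau.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t q = lin(xx, yy, zz, nx, ny);
        if (!mask[q]) continue;
        if (relief[q] < v) { is_min = false; continue; }
        if (relief[q] == v && state[q] == 0) {
          state[q] = 1; plateau.push_back(q); stack.push_back(q);
        }
      }
    }
    if (is_min) {
      ++next;
      for (R_xlen_t p : plateau) { lab[p] = next; state[p] = 2; }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// ---------------------------------------------------------------- watershed ----

// Meyer-style priority flooding of `relief` restricted to `mask`, seeded by
// `seeds` (positive labels, e.g. from cpp_regional_minima).  Every mask voxel
// is assigned the label of the basin that reaches it first; ties in relief
// value are broken by queue insertion order (deterministic).

struct QItem {
  double v; uint64_t ord; R_xlen_t idx; int lab;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.v != b.v) return a.v > b.v;       // min-heap on relief value
    return a.ord > b.ord;                    // FIFO within equal values
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector relief, LogicalVector mask,
                            IntegerVector seeds, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = relief.size();
  std::vector<std::array<int,3>> off;
  conn_offsets(26, off);
  IntegerVector lab(n);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  uint64_t ord = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0) {
      lab[i] = seeds[i];
      pq.push({relief[i], ord++, i, seeds[i]});
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    R_xlen_t p = it.idx;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    for (auto& o : off) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t q = lin(xx, yy, zz, nx, ny);
      if (!mask[q] || lab[q] != 0) continue;
      lab[q] = lab[p];
      pq.push({relief[q], ord++, q, lab[q]});
    }
  }
  return lab;
}

// ------------------------------------------------- simple-point machinery ----

// 3x3x3 neighbourhood topology tests (Malandain-Bertrand characterisation):
// a voxel is simple iff the object restricted to its 26-neighbourhood has
// exactly one 26-component, and the background restricted to its
// 18-neighbourhood has exactly one 6-component that is 6-adjacent to the
// centre.  Local indices 0..26: i = (dx+1) + 3*(dy+1) + 9*(dz+1), centre 13.

static int adj26[27][27]; static int n26_adj[27];
static int adj6n[27][27]; static int n6n_adj[27];
static bool in_n18[27]; static bool is_face[27];
static bool tables_ready = false;

static void build_tables() {
  for (int i = 0; i < 27; ++i) {
    int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    int m = std::abs(ix) + std::abs(iy) + std::abs(iz);
    in_n18[i] = (i != 13) && m <= 2;
    is_face[i] = m == 1;
    n26_adj[i] = 0; n6n_adj[i] = 0;
    for (int j = 0; j < 27; ++j) {
      if (i == j) continue;
      int jx = j % 3 - 1, jy = (j / 3) % 3 - 1, jz = j / 9 - 1;
      int cheb = std::max({std::abs(ix - jx), std::abs(iy - jy), std::abs(iz - jz)});
      int man  = std::abs(ix - jx) + std::abs(iy - jy) + std::abs(iz - jz);
      if (cheb == 1 && i != 13 && j != 13) adj26[i][n26_adj[i]++] = j;
      if (man == 1 && i != 13 && j != 13)  adj6n[i][n6n_adj[i]++] = j;
    }
  }
  tables_ready = true;
}

// nb[27]: object occupancy of the 3x3x3 block (centre included but ignored)
static bool is_simple(const bool nb[27]) {
  if (!tables_ready) build_tables();
  // C*: 26-components of object within N26
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || comp[i] != -1) continue;
    int top = 0; stack[top++] = i; comp[i] = ncomp;
    while (top) {
      int p = stack[--top];
      for (int k = 0; k < n26_adj[p]; ++k) {
        int q = adj26[p][k];
        if (q != 13 && nb[q] && comp[q] == -1) { comp[q] = ncomp; stack[top++] = q; }
      }
    }
    ++ncomp;
  }
  if (ncomp != 1) return false;
  // C^bar: 6-components of background within N18 that contain a face neighbour
  int bcomp[27]; for (int i = 0; i < 27; ++i) bcomp[i] = -1;
  int nb_touch = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in_n18[i] || nb[i] || bcomp[i] != -1) continue;
    int top = 0; stack[top++] = i; bcomp[i] = 1;
    bool touches = false;
    while (top) {
      int p = stack[--top];
      if (is_face[p]) touches = true;
      for (int k = 0; k < n6n_adj[p]; ++k) {
        int q = adj6n[p][k];
        if (in_n18[q] && !nb[q] && bcomp[q] == -1) { bcomp[q] = 1; stack[top++] = q; }
      }
    }
    if (touches) ++nb_touch;
  }
  return nb_touch == 1;
}

static void fetch_nb(const std::vector<uint8_t>& m, int x, int y, int z,
                     int nx, int ny, int nz, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int i = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[i] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          ? (m[lin(xx, yy, zz, nx, ny)] != 0) : false;
      }
}

static int count_obj_neighbours(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
  return c;
}

// ------------------------------------------------------ directional thinning ----

// Topology-preserving curve thinning: six directional sub-cycles per pass
// (U, D, N, S, E, W); in each sub-cycle the border voxels in that direction
// that are simple and not curve endpoints are collected, then deleted
// sequentially with the simple-point test re-checked at deletion time.
// Endpoint protection is sticky: once a voxel has <= 1 object neighbour it
// is anchored and never deleted later, which stops zig-zag curve ends from
// eroding corner by corner.  Deterministic: candidates scanned and deleted
// in linear-index order.

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim, int max_pass = -1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  std::vector<uint8_t> m(n);
  std::vector<uint8_t> anchored(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  if (!tables_ready) build_tables();

  // U, D, N, S, E, W: z+1, z-1, y-1, y+1, x+1, x-1 must be background
  const int dirs[6][3] = {{0,0,1},{0,0,-1},{0,-1,0},{0,1,0},{1,0,0},{-1,0,0}};
  bool nb[27];
  bool any_removed = true;
  std::vector<R_xlen_t> cand;
  int pass = 0;
  while (any_removed && (max_pass < 0 || pass++ < max_pass)) {
    any_removed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            R_xlen_t p = lin(x, y, z, nx, ny);
            if (!m[p]) continue;
            int bx = x + dirs[d][0], by = y + dirs[d][1], bz = z + dirs[d][2];
            bool border = !(bx >= 0 && bx < nx && by >= 0 && by < ny &&
                            bz >= 0 && bz < nz) ? true
                          : (m[lin(bx, by, bz, nx, ny)] == 0);
            if (!border && !anchored[p]) continue;
            fetch_nb(m, x, y, z, nx, ny, nz, nb);
            if (count_obj_neighbours(nb) <= 1) { anchored[p] = 1; continue; }
            if (!border || anchored[p]) continue;
            if (is_simple(nb)) cand.push_back(p);
          }
      for (R_xlen_t p : cand) {
        if (anchored[p]) continue;
        int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
        fetch_nb(m, x, y, z, nx, ny, nz, nb);
        if (count_obj_neighbours(nb) <= 1) { anchored[p] = 1; continue; }
        if (is_simple(nb)) { m[p] = 0; any_removed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  return out;
}

// ------------------------------------------------------------- MIL tracing ----

// For each direction (unit vector, rows of `dirs`) a grid of parallel test
// lines with transverse spacing `spacing` (voxels) is traced through the
// volume at sampling step `step` (voxels).  Returns per direction the total
// sampled in-volume line length (voxel units) and the number of
// object<->background crossings between consecutive in-volume samples.

// [[Rcpp::export]]
NumericMatrix cpp_mil_trace(LogicalVector mask, IntegerVector dim,
                            NumericMatrix dirs, double spacing, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = dirs.nrow();
  NumericMatrix out(nd, 2);
  const double cx = nx / 2.0, cy = ny / 2.0, cz = nz / 2.0;
  const double rad = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny + (double)nz * nz);
  for (int di = 0; di < nd; ++di) {
    double wx = dirs(di, 0), wy = dirs(di, 1), wz = dirs(di, 2);
    // transverse orthonormal basis (u, v)
    double ax = 1, ay = 0, az = 0;
    if (std::abs(wx) > 0.9) { ax = 0; ay = 1; }
    double ux = wy * az - wz * ay, uy = wz * ax - wx * az, uz = wx * ay - wy * ax;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    double vx = wy * uz - wz * uy, vy = wz * ux - wx * uz, vz = wx * uy - wy * ux;
    int nl = (int)std::ceil(rad / spacing);
    double tot_len = 0; double crossings = 0;
    int nsteps = (int)std::ceil(2 * rad / step);
    for (int a = -nl; a <= nl; ++a)
      for (int b = -nl; b <= nl; ++b) {
        double bx = cx + (a * ux + b * vx) * spacing;
        double by = cy + (a * uy + b * vy) * spacing;
        double bz = cz + (a * uz + b * vz) * spacing;
        int prev = -1;  // -1: previous sample out of volume
        int nin = 0;
        for (int s = 0; s <= nsteps; ++s) {
          double t = -rad + s * step;
          int x = (int)std::floor(bx + t * wx);
          int y = (int)std::floor(by + t * wy);
          int z = (int)std::floor(bz + t * wz);
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) {
            prev = -1;
            continue;
          }
          int cur = mask[lin(x, y, z, nx, ny)] ? 1 : 0;
          ++nin;
          if (prev >= 0 && cur != prev) crossings += 1;
          prev = cur;
        }
        if (nin > 1) tot_len += (nin - 1) * step;
      }
    out(di, 0) = tot_len;
    out(di, 1) = crossings;
  }
  return out;
}
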