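// Voxel-level kernels for 3D binary morphology, hole filling, connected
// component labeling and fixed-band region growing. Arrays are R logical /
// numeric 3D arrays in (z, y, x) order, i.e. column-major with
// dim = c(nz, ny, nx); linear index = z + nz * (y + ny * x).
//
// Convention: voxels outside the grid are background. Erosion therefore
// removes foreground at the grid border; callers that want border-safe
// morphology pad first (see pad_mask() on the R side).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

struct Off3 {
  int dz, dy, dx;
};

static std::vector<Off3> connectivity_offsets(int connectivity) {
  std::vector<Off3> out;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        out.push_back({dz, dy, dx});
      }
  return out;
}

static std::vector<Off3> se_offsets(const LogicalVector &se,
                                    const IntegerVector &se_dim) {
  int sz = se_dim[0], sy = se_dim[1], sx = se_dim[2];
  int cz = sz / 2, cy = sy / 2, cx = sx / 2;
  std::vector<Off3> out;
  for (int x = 0; x < sx; ++x)
    for (int y = 0; y < sy; ++y)
      for (int z = 0; z < sz; ++z)
        if (se[z + sz * (y + sy * x)])
          out.push_back({z - cz, y - cy, x - cx});
  return out;
}

static inline bool in_grid(int z, int y, int x, int nz, int ny, int nx) {
  return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
}

// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dim,
                         LogicalVector se, IntegerVector se_dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<Off3> offs = se_offsets(se, se_dim);
  LogicalVector out(mask.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool hit = false;
        for (size_t k = 0; k < offs.size() && !hit; ++k) {
          int zz = z - offs[k].dz, yy = y - offs[k].dy, xx = x - offs[k].dx;
          if (in_grid(zz, yy, xx, nz, ny, nx) && mask[zz + nz * (yy + ny * xx)])
            hit = true;
        }
        out[z + nz * (y + ny * x)] = hit;
      }
  return out;
}

// [[Rcpp::export(name = ".erode_cpp")]]
LogicalVector erode_cpp(LogicalVector mask, IntegerVector dim,
                        LogicalVector se, IntegerVector se_dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<Off3> offs = se_offsets(se, se_dim);
  LogicalVector out(mask.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool all_fg = true;
        for (size_t k = 0; k < offs.size() && all_fg; ++k) {
          int zz = z + offs[k].dz, yy = y + offs[k].dy, xx = x + offs[k].dx;
          if (!in_grid(zz, yy, xx, nz, ny, nx) ||
              !mask[zz + nz * (yy + ny * xx)])
            all_fg = false;
        }
        out[z + nz * (y + ny * x)] = all_fg;
      }
  return out;
}

// Background components reachable from any grid face stay background;
// every other background voxel becomes foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dim,
                             int background_connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<Off3> offs = connectivity_offsets(background_connectivity);
  std::vector<uint8_t> reached(mask.size(), 0);
  std::queue<int> q;
  auto push_if_bg = [&](int z, int y, int x) {
    int i = z + nz * (y + ny * x);
    if (!mask[i] && !reached[i]) {
      reached[i] = 1;
      q.push(i);
    }
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 ||
            x == nx - 1)
          push_if_bg(z, y, x);
  while (!q.empty()) {
    int i = q.front();
    q.pop();
    int x = i / (nz * ny), rem = i % (nz * ny), y = rem / nz, z = rem % nz;
    for (size_t k = 0; k < offs.size(); ++k) {
      int zz = z + offs[k].dz, yy = y + offs[k].dy, xx = x + offs[k].dx;
      if (in_grid(zz, yy, xx, nz, ny, nx)) push_if_bg(zz, yy, xx);
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] || !reached[i];
  return out;
}

// Raw labeling pass: components numbered in discovery order; the R wrapper
// reorders by size with the documented tie-break.
// [[Rcpp::export(name = ".label_components_cpp")]]
List label_components_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<Off3> offs = connectivity_offsets(connectivity);
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<int> sizes;
  std::vector<int> minz, miny, minx;
  std::queue<int> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = z + nz * (y + ny * x);
        if (!mask[i] || lab[i]) continue;
        ++next;
        sizes.push_back(0);
        minz.push_back(z);
        miny.push_back(y);
        minx.push_back(x);
        lab[i] = next;
        q.push(i);
        while (!q.empty()) {
          int j = q.front();
          q.pop();
          sizes[next - 1]++;
          int jx = j / (nz * ny), rem = j % (nz * ny), jy = rem / nz,
              jz = rem % nz;
          if (jz < minz[next - 1]) minz[next - 1] = jz;
          if (jy < miny[next - 1]) miny[next - 1] = jy;
          if (jx < minx[next - 1]) minx[next - 1] = jx;
          for (size_t k = 0; k < offs.size(); ++k) {
            int zz = jz + offs[k].dz, yy = jy + offs[k].dy,
                xx = jx + offs[k].dx;
            if (!in_grid(zz, yy, xx, nz, ny, nx)) continue;
            int jj = zz + nz * (yy + ny * xx);
            if (mask[jj] && !lab[jj]) {
              lab[jj] = next;
              q.push(jj);
            }
          }
        }
      }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes),
                      _["min_z"] = wrap(minz), _["min_y"] = wrap(miny),
                      _["min_x"] = wrap(minx));
}

// Fixed-band region growing: BFS from the seed over voxels whose intensity
// lies in [lo, hi]; the seed is always included.
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dim,
                              IntegerVector seed_zyx, double lo, double hi,
                              int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<Off3> offs = connectivity_offsets(connectivity);
  LogicalVector out(vol.size());
  int s = seed_zyx[0] + nz * (seed_zyx[1] + ny * seed_zyx[2]);
  std::queue<int> q;
  out[s] = true;
  q.push(s);
  while (!q.empty()) {
    int i = q.front();
    q.pop();
    int x = i / (nz * ny), rem = i % (nz * ny), y = rem / nz, z = rem % nz;
    for (size_t k = 0; k < offs.size(); ++k) {
      int zz = z + offs[k].dz, yy = y + offs[k].dy, xx = x + offs[k].dx;
      if (!in_grid(zz, yy, xx, nz, ny, nx)) continue;
      int j = zz + nz * (yy + ny * xx);
      if (!out[j] && vol[j] >= lo && vol[j] <= hi) {
        out[j] = true;
        q.push(j);
      }
    }
  }
  return out;
}
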