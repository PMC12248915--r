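#include <Rcpp.h>
using namespace Rcpp;

// Gray-level matrix builders over a 3-D discretized label grid.
// `levels` holds positive integer gray levels inside the mask and 0 outside.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Run-length matrix: maximal runs of equal gray level along the 13 unique
// 3-D directions, aggregated by summing the per-direction matrices.
// [[Rcpp::export]]
IntegerMatrix glrlm_cpp(IntegerVector levels, IntegerVector dims, int ngray) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = std::max(std::max(nx, ny), nz);
  IntegerMatrix out(ngray, maxlen);
  int dirs[13][3];
  int nd = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
          dirs[nd][0] = dx; dirs[nd][1] = dy; dirs[nd][2] = dz; ++nd;
        }
      }
  for (int d = 0; d < nd; ++d) {
    int dx = dirs[d][0], dy = dirs[d][1], dz = dirs[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int lv = levels[idx3(x, y, z, nx, ny)];
          if (lv <= 0) continue;
          int px = x - dx, py = y - dy, pz = z - dz;
          bool start = px < 0 || px >= nx || py < 0 || py >= ny ||
                       pz < 0 || pz >= nz ||
                       levels[idx3(px, py, pz, nx, ny)] != lv;
          if (!start) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz && levels[idx3(cx, cy, cz, nx, ny)] == lv) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          out(lv - 1, len - 1) += 1;
        }
  }
  return out;
}

// Size-zone matrix: 26-connected zones of equal gray level, counted by size.
// [[Rcpp::export]]
IntegerMatrix glszm_cpp(IntegerVector levels, IntegerVector dims, int ngray) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  std::vector<int> stack;
  int maxzone = 1;
  for (int v = 0; v < n; ++v) {
    int lv = levels[v];
    if (lv <= 0 || seen[v]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(v);
    seen[v] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int tx = cx + dx, ty = cy + dy, tz = cz + dz;
            if (tx < 0 || tx >= nx || ty < 0 || ty >= ny || tz < 0 ||
                tz >= nz) continue;
            int t = idx3(tx, ty, tz, nx, ny);
            if (!seen[t] && levels[t] == lv) {
              seen[t] = 1;
              stack.push_back(t);
            }
          }
    }
    zones.push_back(std::make_pair(lv, size));
    if (size > maxzone) maxzone = size;
  }
  IntegerMatrix out(ngray, maxzone);
  for (size_t i = 0; i < zones.size(); ++i)
    out(zones[i].first - 1, zones[i].second - 1) += 1;
  return out;
}

// Dependence matrix: per in-mask voxel, dependence = 1 + number of in-mask
// 26-neighbours sharing its gray level (centre voxel included).
// [[Rcpp::export]]
IntegerMatrix gldm_cpp(IntegerVector levels, IntegerVector dims, int ngray) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix out(ngray, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int lv = levels[idx3(x, y, z, nx, ny)];
        if (lv <= 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int tx = x + dx, ty = y + dy, tz = z + dz;
              if (tx < 0 || tx >= nx || ty < 0 || ty >= ny || tz < 0 ||
                  tz >= nz) continue;
              if (levels[idx3(tx, ty, tz, nx, ny)] == lv) ++dep;
            }
        out(lv - 1, dep - 1) += 1;
      }
  return out;
}
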