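// 3D topological thinning to a 1-voxel-wide curve skeleton.
//
// Sequential border peeling with the classical simple-point criterion:
// a foreground voxel may be deleted iff removing it changes neither the
// 26-connectivity of the foreground in its 3x3x3 neighborhood nor the
// 6-connectivity of the background in its 18-neighborhood. Endpoints
// (voxels with at most one foreground neighbor) are preserved so tube
// centerlines keep their full length. Deletion runs in 6 directional
// sub-iterations per cycle, with simplicity re-checked at deletion time,
// until a full cycle removes nothing.

#include <Rcpp.h>
#include <vector>
#include <array>

using namespace Rcpp;

namespace {

// offsets of the 3x3x3 neighborhood, index = (dx+1) + 3*(dy+1) + 9*(dz+1)
inline int nbIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected foreground components among the 26 neighbors
int fgComponents26(const std::array<bool, 27>& nb) {
  std::array<int, 27> label{};
  label.fill(0);
  int ncomp = 0;
  std::vector<int> stack;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || label[i]) continue;
    ++ncomp;
    stack.clear();
    stack.push_back(i);
    label[i] = ncomp;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2)
              continue;
            int j = nx + 3 * ny + 9 * nz;
            if (j == 13 || j == cur || !nb[j] || label[j]) continue;
            label[j] = ncomp;
            stack.push_back(j);
          }
    }
  }
  return ncomp;
}

// number of 6-connected background components in the 18-neighborhood that
// touch the center by a face
int bgComponents6(const std::array<bool, 27>& nb) {
  // 18-neighborhood: |dx|+|dy|+|dz| <= 2, excluding center
  auto in18 = [](int i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    return m >= 1 && m <= 2;
  };
  auto isFace = [](int i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    return std::abs(x) + std::abs(y) + std::abs(z) == 1;
  };
  std::array<int, 27> label{};
  label.fill(0);
  int ncomp = 0;
  std::vector<int> stack;
  for (int i = 0; i < 27; ++i) {
    if (!in18(i) || nb[i] || label[i] || !isFace(i)) continue;
    // seed only from face neighbors: components not 6-adjacent to the
    // center do not count
    ++ncomp;
    stack.clear();
    stack.push_back(i);
    label[i] = ncomp;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto& f : face) {
        int nx = cx + f[0], ny = cy + f[1], nz = cz + f[2];
        if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2)
          continue;
        int j = nx + 3 * ny + 9 * nz;
        if (j == 13 || !in18(j) || nb[j] || label[j]) continue;
        label[j] = ncomp;
        stack.push_back(j);
      }
    }
  }
  return ncomp;
}

struct Vol {
  const int nx, ny, nz;
  std::vector<unsigned char> v;
  Vol(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_),
                                   v((size_t)nx_ * ny_ * nz_, 0) {}
  inline bool at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
      return false;
    return v[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] != 0;
  }
  inline unsigned char& ref(int x, int y, int z) {
    return v[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
  }
};

void fillNeighborhood(const Vol& vol, int x, int y, int z,
                      std::array<bool, 27>& nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[nbIndex(dx, dy, dz)] = vol.at(x + dx, y + dy, z + dz);
}

inline int fgNeighborCount(const std::array<bool, 27>& nb) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++c;
  return c;
}

inline bool isSimple(const std::array<bool, 27>& nb) {
  return fgComponents26(nb) == 1 && bgComponents6(nb) == 1;
}

} // namespace

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != mask.size())
    stop("mask length does not match dims");
  Vol vol(nx, ny, nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    vol.v[i] = (mask[i] == TRUE) ? 1 : 0;

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  std::array<bool, 27> nb;
  bool changed = true;
  std::vector<std::array<int, 3>> border;
  while (changed) {
    changed = false;
    for (auto& d : dirs) {
      border.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            if (!vol.at(x, y, z)) continue;
            if (vol.at(x + d[0], y + d[1], z + d[2])) continue;
            border.push_back({x, y, z});
          }
      for (auto& p : border) {
        // re-check at deletion time: sequential deletion keeps topology
        fillNeighborhood(vol, p[0], p[1], p[2], nb);
        int nfg = fgNeighborCount(nb);
        if (nfg <= 1) continue; // endpoint (or isolated): keep
        if (!isSimple(nb)) continue;
        vol.ref(p[0], p[1], p[2]) = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = vol.v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
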