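#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D curve thinning to a 1-voxel-wide centerline.
// A foreground voxel may be deleted when it is a simple point for the
// (26, 6) digital-topology pair (Malandain & Bertrand characterization:
// exactly one 26-component of foreground among its 26 neighbors, and exactly
// one 6-component of background in its 18-neighborhood that touches a face
// neighbor) and is not a curve endpoint (<= 1 foreground neighbor).
// Deletion proceeds in six directional subiterations (U/D/N/S/E/W border
// voxels) with sequential re-checking, which keeps the result centered.

static const int N26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
  {-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},
  {-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
  {-1,1,1},{0,1,1},{1,1,1}
};

// nb[] is the 3x3x3 cube as 27 flags, index = (x+1) + 3*(y+1) + 9*(z+1),
// center at 13.
static inline int cubeIdx(int x, int y, int z) {
  return (x + 1) + 3 * (y + 1) + 9 * (z + 1);
}

// number of foreground voxels among the 26 neighbors
static int countNeighbors(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++c;
  return c;
}

// 26-components of foreground among the 26 neighbors must equal 1
static bool foregroundCondition(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (int t = 0; t < 26; ++t) {
        int x = cx + N26[t][0], y = cy + N26[t][1], z = cz + N26[t][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        int q = cubeIdx(x, y, z);
        if (q == 13 || seen[q] || !nb[q]) continue;
        seen[q] = true;
        stack[top++] = q;
      }
    }
  }
  return comps == 1;
}

// 6-components of background within the 18-neighborhood, counted only if
// they contain a face neighbor of the center; must equal 1.
static bool backgroundCondition(const bool nb[27]) {
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (m == 1 || m == 2);
  }
  static const int faces[6] = {4, 10, 12, 14, 16, 22};
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int fi = 0; fi < 6; ++fi) {
    int s = faces[fi];
    if (nb[s] || seen[s]) continue;
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int x = cx + F6[t][0], y = cy + F6[t][1], z = cz + F6[t][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        int q = cubeIdx(x, y, z);
        if (q == 13 || !in18[q] || seen[q] || nb[q]) continue;
        seen[q] = true;
        stack[top++] = q;
      }
    }
  }
  return comps == 1;
}

// [[Rcpp::export]]
LogicalVector skeletonize_cpp(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  auto at = [&](int i, int j, int k) -> char {
    if (i < 0 || j < 0 || k < 0 || i >= d1 || j >= d2 || k >= d3) return 0;
    return img[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)];
  };
  auto fillCube = [&](int i, int j, int k, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[cubeIdx(dx, dy, dz)] = at(i + dx, j + dy, k + dz) != 0;
  };
  // border direction offsets: voxel is a d-border point if its face neighbor
  // in direction d is background
  static const int DIRS[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int k = 0; k < d3; ++k)
        for (int j = 0; j < d2; ++j)
          for (int i = 0; i < d1; ++i) {
            R_xlen_t s = i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
            if (!img[s]) continue;
            if (at(i + DIRS[d][0], j + DIRS[d][1], k + DIRS[d][2])) continue;
            bool nb[27];
            fillCube(i, j, k, nb);
            int cnt = countNeighbors(nb);
            if (cnt <= 1) continue; // endpoint or isolated: preserve
            if (foregroundCondition(nb) && backgroundCondition(nb))
              cand.push_back(s);
          }
      // sequential deletion with re-check (candidate neighborhoods change as
      // earlier candidates are removed)
      for (size_t c = 0; c < cand.size(); ++c) {
        R_xlen_t s = cand[c];
        int i = (int)(s % d1);
        int j = (int)((s / d1) % d2);
        int k = (int)(s / ((R_xlen_t)d1 * d2));
        bool nb[27];
        fillCube(i, j, k, nb);
        int cnt = countNeighbors(nb);
        if (cnt <= 1) continue;
        if (foregroundCondition(nb) && backgroundCondition(nb)) {
          img[s] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dim;
  return out;
}
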