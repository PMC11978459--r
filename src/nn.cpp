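#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nearest-neighbour queries between 3-D point sets via a uniform hash grid
// over the reference set (build O(m), query ~O(1) per point for surface-like
// data). Ties go to the lowest reference index. Point counts here are a few
// hundred to a few thousand per surface, queried thousands of times per
// analysis, which is exactly where the grid pays off over a plain scan.

namespace {

struct Grid {
  const double *rx, *ry, *rz;
  int nr;
  double minx, miny, minz, h;
  int nx, ny, nz;
  std::vector<int> cell_start;   // CSR layout of point ids per cell
  std::vector<int> cell_items;

  int cell_of(double x, double y, double z, int &cx, int &cy, int &cz) const {
    cx = (int)std::floor((x - minx) / h); if (cx < 0) cx = 0; if (cx >= nx) cx = nx - 1;
    cy = (int)std::floor((y - miny) / h); if (cy < 0) cy = 0; if (cy >= ny) cy = ny - 1;
    cz = (int)std::floor((z - minz) / h); if (cz < 0) cz = 0; if (cz >= nz) cz = nz - 1;
    return (cz * ny + cy) * nx + cx;
  }
};

Grid build_grid(NumericMatrix ref) {
  Grid g;
  g.nr = ref.nrow();
  g.rx = &ref(0, 0); g.ry = &ref(0, 1); g.rz = &ref(0, 2);
  double maxx = g.rx[0], maxy = g.ry[0], maxz = g.rz[0];
  g.minx = g.rx[0]; g.miny = g.ry[0]; g.minz = g.rz[0];
  for (int j = 1; j < g.nr; ++j) {
    if (g.rx[j] < g.minx) g.minx = g.rx[j]; if (g.rx[j] > maxx) maxx = g.rx[j];
    if (g.ry[j] < g.miny) g.miny = g.ry[j]; if (g.ry[j] > maxy) maxy = g.ry[j];
    if (g.rz[j] < g.minz) g.minz = g.rz[j]; if (g.rz[j] > maxz) maxz = g.rz[j];
  }
  const double ex = maxx - g.minx, ey = maxy - g.miny, ez = maxz - g.minz;
  double vol = std::max(ex, 1e-12) * std::max(ey, 1e-12) * std::max(ez, 1e-12);
  g.h = std::max(1.5 * std::cbrt(vol / g.nr), 1e-12);
  g.nx = std::max(1, std::min(128, (int)(ex / g.h) + 1));
  g.ny = std::max(1, std::min(128, (int)(ey / g.h) + 1));
  g.nz = std::max(1, std::min(128, (int)(ez / g.h) + 1));
  // recompute h so the capped grid still covers the box
  g.h = std::max(g.h, std::max(ex / g.nx, std::max(ey / g.ny, ez / g.nz)) * (1 + 1e-12));
  const int ncell = g.nx * g.ny * g.nz;
  std::vector<int> count(ncell, 0);
  std::vector<int> cell_id(g.nr);
  int cx, cy, cz;
  for (int j = 0; j < g.nr; ++j) {
    cell_id[j] = g.cell_of(g.rx[j], g.ry[j], g.rz[j], cx, cy, cz);
    ++count[cell_id[j]];
  }
  g.cell_start.assign(ncell + 1, 0);
  for (int c = 0; c < ncell; ++c) g.cell_start[c + 1] = g.cell_start[c] + count[c];
  g.cell_items.assign(g.nr, 0);
  std::vector<int> fill(g.cell_start.begin(), g.cell_start.end() - 1);
  for (int j = 0; j < g.nr; ++j) g.cell_items[fill[cell_id[j]]++] = j;
  // keep ids sorted per cell so ties resolve to the lowest index naturally
  // (fill order is already ascending in j, so they are sorted)
  return g;
}

inline void nn_one(const Grid &g, double x, double y, double z,
                   int &best_j, double &best_d2) {
  int cx, cy, cz;
  g.cell_of(x, y, z, cx, cy, cz);
  best_j = -1;
  best_d2 = R_PosInf;
  const int max_ring = std::max(g.nx, std::max(g.ny, g.nz));
  for (int ring = 0; ring <= max_ring; ++ring) {
    if (best_j >= 0) {
      // any point in a cell at Chebyshev ring r is at least (r-1)*h away
      const double lo = (ring - 1) * g.h;
      if (lo > 0 && lo * lo > best_d2) break;
    }
    const int x0 = std::max(0, cx - ring), x1 = std::min(g.nx - 1, cx + ring);
    const int y0 = std::max(0, cy - ring), y1 = std::min(g.ny - 1, cy + ring);
    const int z0 = std::max(0, cz - ring), z1 = std::min(g.nz - 1, cz + ring);
    for (int iz = z0; iz <= z1; ++iz) {
      for (int iy = y0; iy <= y1; ++iy) {
        for (int ix = x0; ix <= x1; ++ix) {
          // only the shell of this ring
          if (std::max(std::abs(ix - cx), std::max(std::abs(iy - cy), std::abs(iz - cz))) != ring)
            continue;
          const int c = (iz * g.ny + iy) * g.nx + ix;
          for (int q = g.cell_start[c]; q < g.cell_start[c + 1]; ++q) {
            const int j = g.cell_items[q];
            const double dx = x - g.rx[j], dy = y - g.ry[j], dz = z - g.rz[j];
            const double d = dx * dx + dy * dy + dz * dz;
            if (d < best_d2 || (d == best_d2 && j < best_j)) { best_d2 = d; best_j = j; }
          }
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List nn_query_cpp(NumericMatrix query, NumericMatrix ref) {
  const Grid g = build_grid(ref);
  const int nq = query.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  for (int i = 0; i < nq; ++i) {
    int bj; double bd;
    nn_one(g, query(i, 0), query(i, 1), query(i, 2), bj, bd);
    idx[i] = bj + 1;
    d2[i] = bd;
  }
  return List::create(_["index"] = idx, _["dist2"] = d2);
}

// Mean squared closest-point distance from each row of A to the rows of B.
// [[Rcpp::export]]
double mean_min_dist2_cpp(NumericMatrix A, NumericMatrix B) {
  const Grid g = build_grid(B);
  const int na = A.nrow();
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    int bj; double bd;
    nn_one(g, A(i, 0), A(i, 1), A(i, 2), bj, bd);
    acc += bd;
  }
  return acc / na;
}
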