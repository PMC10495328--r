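#include <Rcpp.h>
#include <cmath>
#include <map>
#include <tuple>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Watertight-mesh point containment by parity ray casting (Moller-Trumbore).
// A fixed irrationally-oriented ray direction avoids grazing edges/vertices
// of axis-aligned fixture geometry.

static const double RD[3] = {0.57321098765432, 0.61234567891234, 0.54455667788991};

// [[Rcpp::export]]
LogicalVector points_in_mesh_cpp(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  const double eps = 1e-12;
  double rl = std::sqrt(RD[0] * RD[0] + RD[1] * RD[1] + RD[2] * RD[2]);
  const double d0 = RD[0] / rl, d1 = RD[1] / rl, d2 = RD[2] / rl;
  LogicalVector out(np);

  std::vector<double> ax(nf), ay(nf), az(nf), e1x(nf), e1y(nf), e1z(nf),
      e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    ax[f] = V(i0, 0); ay[f] = V(i0, 1); az[f] = V(i0, 2);
    e1x[f] = V(i1, 0) - ax[f]; e1y[f] = V(i1, 1) - ay[f]; e1z[f] = V(i1, 2) - az[f];
    e2x[f] = V(i2, 0) - ax[f]; e2y[f] = V(i2, 1) - ay[f]; e2z[f] = V(i2, 2) - az[f];
  }

  for (int p = 0; p < np; ++p) {
    const double ox = pts(p, 0), oy = pts(p, 1), oz = pts(p, 2);
    int crossings = 0;
    for (int f = 0; f < nf; ++f) {
      double hx = d1 * e2z[f] - d2 * e2y[f];
      double hy = d2 * e2x[f] - d0 * e2z[f];
      double hz = d0 * e2y[f] - d1 * e2x[f];
      double a = e1x[f] * hx + e1y[f] * hy + e1z[f] * hz;
      if (std::fabs(a) < eps) continue;
      double inv = 1.0 / a;
      double sx = ox - ax[f], sy = oy - ay[f], sz = oz - az[f];
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qx = sy * e1z[f] - sz * e1y[f];
      double qy = sz * e1x[f] - sx * e1z[f];
      double qz = sx * e1y[f] - sy * e1x[f];
      double v = (d0 * qx + d1 * qy + d2 * qz) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
      if (t > 1e-9) ++crossings;
    }
    out[p] = (crossings % 2) == 1;
  }
  return out;
}

// Single-linkage connected components at a fixed linking radius, via a
// uniform grid (cell size = radius, 27-neighborhood) and union-find.

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

// [[Rcpp::export]]
IntegerVector cluster_radius_cpp(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  IntegerVector lab(n);
  if (n == 0) return lab;
  const double r2 = radius * radius;
  typedef std::tuple<long, long, long> Cell;
  std::map<Cell, std::vector<int>> grid;
  auto ix = [radius](double v) { return (long)std::floor(v / radius); };
  for (int i = 0; i < n; ++i)
    grid[Cell(ix(pts(i, 0)), ix(pts(i, 1)), ix(pts(i, 2)))].push_back(i);

  UF uf(n);
  for (int i = 0; i < n; ++i) {
    long cx = ix(pts(i, 0)), cy = ix(pts(i, 1)), cz = ix(pts(i, 2));
    for (long dx = -1; dx <= 1; ++dx)
      for (long dy = -1; dy <= 1; ++dy)
        for (long dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(Cell(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double ddx = pts(i, 0) - pts(j, 0);
            double ddy = pts(i, 1) - pts(j, 1);
            double ddz = pts(i, 2) - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) uf.unite(i, j);
          }
        }
  }
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
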