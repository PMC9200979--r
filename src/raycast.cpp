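// Axis-aligned ray casting against a triangle soup.
//
// For a closed, consistently outward-oriented surface (or a union of such
// components) the signed crossing count along a ray equals the number of
// enclosing surfaces at a point, so occupancy is "signed count >= 1".
// This is exact for watertight input and, voted over the three axis
// directions, robust to moderate open defects (the photogrammetry blind
// area), which is what the volumetric remesher relies on.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Crossing {
  double t;
  int sgn;
};

// Fill `grid` (nx*ny*nz, x fastest) with inside counts (clamped to 0/1)
// obtained by casting rays along `axis` through every cell-centre column.
void cast_axis(const NumericMatrix& V, const IntegerMatrix& F,
               const double origin[3], double h,
               const int dims[3], int axis, std::vector<unsigned char>& grid,
               bool accumulate) {
  const int a = axis, u = (axis + 1) % 3, v = (axis + 2) % 3;
  const int nu = dims[u], nv = dims[v], na = dims[a];
  const long strides[3] = {1L, (long)dims[0], (long)dims[0] * dims[1]};
  const long sa = strides[a], su = strides[u], sv = strides[v];
  const int nf = F.nrow();

  // bin triangles over the (u, v) column grid
  std::vector<int> binCount((size_t)nu * nv, 0);
  std::vector<int> lo_u(nf), hi_u(nf), lo_v(nf), hi_v(nf);
  std::vector<bool> skip(nf, false);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0), i1 = F(f, 1), i2 = F(f, 2);
    double umin = std::min({V(i0, u), V(i1, u), V(i2, u)});
    double umax = std::max({V(i0, u), V(i1, u), V(i2, u)});
    double vmin = std::min({V(i0, v), V(i1, v), V(i2, v)});
    double vmax = std::max({V(i0, v), V(i1, v), V(i2, v)});
    int bu0 = (int)std::floor((umin - origin[u]) / h - 0.5);
    int bu1 = (int)std::floor((umax - origin[u]) / h - 0.5) + 1;
    int bv0 = (int)std::floor((vmin - origin[v]) / h - 0.5);
    int bv1 = (int)std::floor((vmax - origin[v]) / h - 0.5) + 1;
    bu0 = std::max(bu0, 0); bu1 = std::min(bu1, nu - 1);
    bv0 = std::max(bv0, 0); bv1 = std::min(bv1, nv - 1);
    if (bu0 > bu1 || bv0 > bv1) { skip[f] = true; continue; }
    lo_u[f] = bu0; hi_u[f] = bu1; lo_v[f] = bv0; hi_v[f] = bv1;
    for (int bv = bv0; bv <= bv1; ++bv)
      for (int bu = bu0; bu <= bu1; ++bu)
        binCount[(size_t)bv * nu + bu]++;
  }
  std::vector<long> binStart((size_t)nu * nv + 1, 0);
  for (size_t b = 0; b < (size_t)nu * nv; ++b)
    binStart[b + 1] = binStart[b] + binCount[b];
  std::vector<int> binTri(binStart[(size_t)nu * nv]);
  std::vector<long> cursor(binStart.begin(), binStart.end() - 1);
  for (int f = 0; f < nf; ++f) {
    if (skip[f]) continue;
    for (int bv = lo_v[f]; bv <= hi_v[f]; ++bv)
      for (int bu = lo_u[f]; bu <= hi_u[f]; ++bu)
        binTri[cursor[(size_t)bv * nu + bu]++] = f;
  }

  std::vector<Crossing> cr;
  for (int iv = 0; iv < nv; ++iv) {
    double pv = origin[v] + (iv + 0.5) * h;
    for (int iu = 0; iu < nu; ++iu) {
      double pu = origin[u] + (iu + 0.5) * h;
      cr.clear();
      size_t b = (size_t)iv * nu + iu;
      for (long q = binStart[b]; q < binStart[b + 1]; ++q) {
        int f = binTri[q];
        int i0 = F(f, 0), i1 = F(f, 1), i2 = F(f, 2);
        double au = V(i0, u), av = V(i0, v), aa = V(i0, a);
        double bu_ = V(i1, u), bv_ = V(i1, v), ba = V(i1, a);
        double cu = V(i2, u), cv = V(i2, v), ca = V(i2, a);
        double den = (bu_ - au) * (cv - av) - (bv_ - av) * (cu - au);
        if (std::fabs(den) < 1e-300) continue;  // edge-on triangle
        double w0 = ((bu_ - pu) * (cv - pv) - (bv_ - pv) * (cu - pu)) / den;
        double w1 = ((cu - pu) * (av - pv) - (cv - pv) * (au - pu)) / den;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
        Crossing c;
        c.t = w0 * aa + w1 * ba + w2 * ca;
        c.sgn = den > 0 ? 1 : -1;  // sign of the face normal's `axis` component
        cr.push_back(c);
      }
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end(),
                [](const Crossing& x, const Crossing& y) { return x.t < y.t; });
      // winding at t = (sum of signs of crossings above t)
      int total = 0;
      for (const Crossing& c : cr) total += c.sgn;
      size_t p = 0;
      int below = 0;
      long base = (long)iu * su + (long)iv * sv;
      for (int k = 0; k < na; ++k) {
        double tc = origin[a] + (k + 0.5) * h;
        while (p < cr.size() && cr[p].t < tc) below += cr[p++].sgn;
        if (total - below >= 1) {
          long idx = base + (long)k * sa;
          if (accumulate) { if (grid[idx] < 250) grid[idx]++; }
          else grid[idx] = 1;
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector occupancy_votes_cpp(NumericMatrix V, IntegerMatrix F,
                                  NumericVector origin, double h,
                                  IntegerVector dims, IntegerVector axes) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  std::vector<unsigned char> grid((size_t)d[0] * d[1] * d[2], 0);
  for (int k = 0; k < axes.size(); ++k)
    cast_axis(V, F, o, h, d, axes[k], grid, true);
  IntegerVector out(grid.size());
  for (size_t i = 0; i < grid.size(); ++i) out[i] = grid[i];
  return out;
}

// Count of voxel centres with winding >= 1 on a grid covering the mesh
// bounding box (plus one-cell margin), cast along one axis. Used as the
// volume oracle: count * h^3 stands in for water displacement.
// [[Rcpp::export]]
double voxel_inside_count_cpp(NumericMatrix V, IntegerMatrix F,
                              NumericVector origin, double h,
                              IntegerVector dims, int axis) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  std::vector<unsigned char> grid((size_t)d[0] * d[1] * d[2], 0);
  cast_axis(V, F, o, h, d, axis, grid, false);
  double n = 0;
  for (size_t i = 0; i < grid.size(); ++i) n += grid[i];
  return n;
}
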