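#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Label connected components of a 3D binary mask (column-major, dims h x w x d).
// connectivity: 6 (face) or 26 (face+edge+vertex). Labels are assigned in raster
// scan order, so component 1 contains the foreground voxel with the smallest
// linear index, component 2 the next unvisited one, and so on. That ordering is
// what gives the package its deterministic size-tie break (smallest minimum
// linear index wins when components are sorted by size then label).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int h = dims[0], w = dims[1], d = dims[2];
  const R_xlen_t n = (R_xlen_t)h * w * d;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int vx = (int)(v % h);
      int vy = (int)((v / h) % w);
      int vz = (int)(v / ((R_xlen_t)h * w));
      for (int k = 0; k < nn; ++k) {
        int ux = vx + dx[k], uy = vy + dy[k], uz = vz + dz[k];
        if (ux < 0 || ux >= h || uy < 0 || uy >= w || uz < 0 || uz >= d) continue;
        R_xlen_t u = (R_xlen_t)uz * h * w + (R_xlen_t)uy * h + ux;
        if (mask[u] && lab[u] == 0) { lab[u] = cur; stack.push_back(u); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// One-dimensional squared distance transform (lower envelope of parabolas),
// with physical sample spacing `step`. f holds squared distances on input and
// output. Felzenszwalb & Huttenlocher's algorithm on coordinates x_i = step*i.
static void dt1d(std::vector<double>& f, double step) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), out(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = step * q;
    double s;
    while (true) {
      double xv = step * v[k];
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = step * q;
    while (z[k + 1] < xq) ++k;
    double dx = xq - step * v[k];
    out[q] = dx * dx + f[v[k]];
  }
  f.swap(out);
}

// Exact squared Euclidean distance transform of a 3D mask: for every voxel the
// squared physical distance (spacing-scaled) to the nearest foreground voxel
// centre. A large finite sentinel stands in for infinity so the parabola
// envelope never sees inf - inf; any true distance is far below it.
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int h = dims[0], w = dims[1], d = dims[2];
  const R_xlen_t n = (R_xlen_t)h * w * d;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = 1e30;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> line;
  // axis 1 (fastest varying, length h, spacing[0])
  line.resize(h);
  for (int zz = 0; zz < d; ++zz)
    for (int yy = 0; yy < w; ++yy) {
      R_xlen_t base = (R_xlen_t)zz * h * w + (R_xlen_t)yy * h;
      bool any = false;
      for (int xx = 0; xx < h; ++xx) { line[xx] = g[base + xx]; if (line[xx] < INF) any = true; }
      if (!any) continue;
      dt1d(line, spacing[0]);
      for (int xx = 0; xx < h; ++xx) g[base + xx] = line[xx];
    }
  // axis 2 (length w, spacing[1])
  line.resize(w);
  for (int zz = 0; zz < d; ++zz)
    for (int xx = 0; xx < h; ++xx) {
      R_xlen_t base = (R_xlen_t)zz * h * w + xx;
      bool any = false;
      for (int yy = 0; yy < w; ++yy) { line[yy] = g[base + (R_xlen_t)yy * h]; if (line[yy] < INF) any = true; }
      if (!any) continue;
      dt1d(line, spacing[1]);
      for (int yy = 0; yy < w; ++yy) g[base + (R_xlen_t)yy * h] = line[yy];
    }
  // axis 3 (length d, spacing[2])
  line.resize(d);
  for (int yy = 0; yy < w; ++yy)
    for (int xx = 0; xx < h; ++xx) {
      R_xlen_t base = (R_xlen_t)yy * h + xx;
      bool any = false;
      for (int zz = 0; zz < d; ++zz) { line[zz] = g[base + (R_xlen_t)zz * h * w]; if (line[zz] < INF) any = true; }
      if (!any) continue;
      dt1d(line, spacing[2]);
      for (int zz = 0; zz < d; ++zz) g[base + (R_xlen_t)zz * h * w] = line[zz];
    }
  return g;
}
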