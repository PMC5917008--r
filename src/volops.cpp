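// Low-level voxel operations shared by the segmentation and skeletonization
// stages. All 3-D arrays are R column-major with dim = (n1, n2, n3) read as
// (z, y, x) and physical spacing (dz, dy, dx) in micrometres. Linear index
// convention: idx = i1 + n1 * (i2 + n2 * i3), zero-based.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
#include <map>

using namespace Rcpp;

static inline int lin(int i1, int i2, int i3, int n1, int n2) {
  return i1 + n1 * (i2 + n2 * i3);
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope scan), applied separably along each axis.

static void dt1d(std::vector<double>& f, std::vector<double>& d, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s, sv;
    double inter;
    while (true) {
      sv = (double)v[k] * s;
      inter = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * sq - 2.0 * sv);
      if (inter <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double dv = sq - (double)v[k] * s;
    d[q] = dv * dv + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_aniso")]]
NumericVector edt_aniso(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  // large finite init keeps the parabola intersections finite (an infinite
  // init would produce NaN and corrupt the lower envelope)
  const double BIG = 1e20;
  std::vector<double> d2(N);
  for (R_xlen_t i = 0; i < N; ++i) d2[i] = mask[i] ? BIG : 0.0;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), dl(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      f.assign(d2.begin() + base, d2.begin() + base + n1);
      dt1d(f, dl, spacing[0], v, z);
      for (int i = 0; i < n1; ++i) d2[base + i] = dl[i];
    }
  // axis 2 (stride n1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      f.resize(n2);
      for (int i = 0; i < n2; ++i) f[i] = d2[lin(i1, i, i3, n1, n2)];
      dt1d(f, dl, spacing[1], v, z);
      for (int i = 0; i < n2; ++i) d2[lin(i1, i, i3, n1, n2)] = dl[i];
      f.resize(nmax);
    }
  // axis 3 (stride n1*n2)
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      f.resize(n3);
      for (int i = 0; i < n3; ++i) f[i] = d2[lin(i1, i2, i, n1, n2)];
      dt1d(f, dl, spacing[2], v, z);
      for (int i = 0; i < n3; ++i) d2[lin(i1, i2, i, n1, n2)] = dl[i];
      f.resize(nmax);
    }

  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mask[i] ? std::sqrt(d2[i]) : 0.0;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-neighbourhood), scan-order labels.

static void neighbour_offsets(int conn, std::vector<std::array<int, 3>>& off) {
  off.clear();
  if (conn == 6) {
    off = {{{-1,0,0}},{{1,0,0}},{{0,-1,0}},{{0,1,0}},{{0,0,-1}},{{0,0,1}}};
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          if (a || b || c) off.push_back({{a, b, c}});
  }
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i3 = (int)(p / ((R_xlen_t)n1 * n2));
      int r = (int)(p % ((R_xlen_t)n1 * n2));
      int i2 = r / n1, i1 = r % n1;
      for (auto& o : off) {
        int j1 = i1 + o[0], j2 = i2 + o[1], j3 = i3 + o[2];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        R_xlen_t q = lin(j1, j2, j3, n1, n2);
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Fill background cavities fully enclosed in 3D (6-connected background).
// [[Rcpp::export(name = ".fill_holes3d")]]
LogicalVector fill_holes3d(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  LogicalVector bg(N);
  for (R_xlen_t i = 0; i < N; ++i) bg[i] = !mask[i];
  IntegerVector lab = cc_label(bg, dim, 6);
  int nlab = 0;
  for (R_xlen_t i = 0; i < N; ++i) if (lab[i] > nlab) nlab = lab[i];
  std::vector<char> touches(nlab + 1, 0);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        if (i1 && i1 != n1 - 1 && i2 && i2 != n2 - 1 && i3 && i3 != n3 - 1)
          continue;
        int l = lab[lin(i1, i2, i3, n1, n2)];
        if (l) touches[l] = 1;
      }
  LogicalVector out(N);
  for (R_xlen_t i = 0; i < N; ++i)
    out[i] = mask[i] || (lab[i] > 0 && !touches[lab[i]]);
  return out;
}

// 1-voxel-radius (3x3x3 box) dilation / erosion.
static LogicalVector morph_box(LogicalVector mask, IntegerVector dim, bool dilate) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(N);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        bool acc = !dilate;
        for (int a = std::max(0, i1 - 1); a <= std::min(n1 - 1, i1 + 1) && (acc != dilate); ++a)
          for (int b = std::max(0, i2 - 1); b <= std::min(n2 - 1, i2 + 1) && (acc != dilate); ++b)
            for (int c = std::max(0, i3 - 1); c <= std::min(n3 - 1, i3 + 1); ++c) {
              bool v = mask[lin(a, b, c, n1, n2)];
              if (dilate) { if (v) { acc = true; break; } }
              else { if (!v) { acc = false; break; } }
            }
        out[lin(i1, i2, i3, n1, n2)] = acc;
      }
  return out;
}

// [[Rcpp::export(name = ".dilate_box")]]
LogicalVector dilate_box(LogicalVector mask, IntegerVector dim) {
  return morph_box(mask, dim, true);
}

// [[Rcpp::export(name = ".erode_box")]]
LogicalVector erode_box(LogicalVector mask, IntegerVector dim) {
  return morph_box(mask, dim, false);
}

// ---------------------------------------------------------------------------
// 26-neighbourhood local maxima of a non-negative field (plateaus included).

// [[Rcpp::export(name = ".local_max26")]]
LogicalVector local_max26(NumericVector d, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(N, FALSE);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        double v = d[lin(i1, i2, i3, n1, n2)];
        if (v <= 0) continue;
        bool ismax = true;
        for (int a = std::max(0, i1 - 1); a <= std::min(n1 - 1, i1 + 1) && ismax; ++a)
          for (int b = std::max(0, i2 - 1); b <= std::min(n2 - 1, i2 + 1) && ismax; ++b)
            for (int c = std::max(0, i3 - 1); c <= std::min(n3 - 1, i3 + 1); ++c)
              if (d[lin(a, b, c, n1, n2)] > v) { ismax = false; break; }
        out[lin(i1, i2, i3, n1, n2)] = ismax;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Marker-based watershed by priority flooding of the distance map (regions
// grow from markers in order of decreasing elevation; 6-connected growth so
// segments cannot leak through diagonal background). Deterministic: ties are
// broken by insertion order.

struct QItem {
  double elev;
  uint64_t order;
  R_xlen_t idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.elev != b.elev) return a.elev < b.elev;  // max-heap on elevation
    return a.order > b.order;                      // FIFO among equals
  }
};

// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(NumericVector d, IntegerVector markers,
                              LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  uint64_t tick = 0;
  for (R_xlen_t i = 0; i < N; ++i)
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push({d[i], tick++, i, markers[i]});
    }
  const int o1[6] = {-1, 1, 0, 0, 0, 0};
  const int o2[6] = {0, 0, -1, 1, 0, 0};
  const int o3[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    R_xlen_t p = it.idx;
    int i3 = (int)(p / ((R_xlen_t)n1 * n2));
    int r = (int)(p % ((R_xlen_t)n1 * n2));
    int i2 = r / n1, i1 = r % n1;
    for (int k = 0; k < 6; ++k) {
      int j1 = i1 + o1[k], j2 = i2 + o2[k], j3 = i3 + o3[k];
      if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
        continue;
      R_xlen_t q = lin(j1, j2, j3, n1, n2);
      if (mask[q] && lab[q] == 0) {
        lab[q] = it.label;
        pq.push({d[q], tick++, q, it.label});
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian filter with reflective boundaries; sigma per axis in
// voxel units (0 skips the axis). Kernel radius = ceil(4 sigma).

static void conv_axis(std::vector<double>& v, int n1, int n2, int n3, int axis,
                      double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& x : k) x /= s;
  int nA = axis == 0 ? n1 : (axis == 1 ? n2 : n3);
  std::vector<double> line(nA), outl(nA);
  auto reflect = [&](int i) {
    while (i < 0 || i >= nA) {
      if (i < 0) i = -i - 1;
      if (i >= nA) i = 2 * nA - i - 1;
    }
    return i;
  };
  int nB = axis == 0 ? n2 : n1;
  int nC = axis == 2 ? n2 : n3;
  for (int c = 0; c < nC; ++c)
    for (int b = 0; b < nB; ++b) {
      for (int i = 0; i < nA; ++i) {
        int i1 = axis == 0 ? i : b;
        int i2 = axis == 1 ? i : (axis == 0 ? b : c);
        int i3 = axis == 2 ? i : c;
        line[i] = v[lin(i1, i2, i3, n1, n2)];
      }
      for (int i = 0; i < nA; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) acc += k[j + r] * line[reflect(i + j)];
        outl[i] = acc;
      }
      for (int i = 0; i < nA; ++i) {
        int i1 = axis == 0 ? i : b;
        int i2 = axis == 1 ? i : (axis == 0 ? b : c);
        int i3 = axis == 2 ? i : c;
        v[lin(i1, i2, i3, n1, n2)] = outl[i];
      }
    }
}

// [[Rcpp::export(name = ".gauss_sep")]]
NumericVector gauss_sep(NumericVector vol, IntegerVector dim,
                        NumericVector sigma_vox) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> v(vol.begin(), vol.end());
  conv_axis(v, n1, n2, n3, 0, sigma_vox[0]);
  conv_axis(v, n1, n2, n3, 1, sigma_vox[1]);
  conv_axis(v, n1, n2, n3, 2, sigma_vox[2]);
  NumericVector out(N);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra (6-tet cube decomposition, linear
// edge interpolation, anisotropic vertex placement). Input is a scalar field;
// binary territories should be lightly smoothed first (see R wrapper).

static const int TETS[6][4] = {
  {0, 5, 1, 3}, {0, 5, 3, 7}, {0, 5, 7, 4}, {0, 3, 2, 7}, {0, 7, 2, 6}, {0, 7, 6, 4}};
// vertex bit order: v = z*4 + y*2 + x
static const int VOFF[8][3] = {
  {0, 0, 0}, {0, 0, 1}, {0, 1, 0}, {0, 1, 1},
  {1, 0, 0}, {1, 0, 1}, {1, 1, 0}, {1, 1, 1}};

static inline double tri_area(const double* p0, const double* p1,
                              const double* p2) {
  double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
  double c0 = u[1] * w[2] - u[2] * w[1];
  double c1 = u[2] * w[0] - u[0] * w[2];
  double c2 = u[0] * w[1] - u[1] * w[0];
  return 0.5 * std::sqrt(c0 * c0 + c1 * c1 + c2 * c2);
}

// [[Rcpp::export(name = ".mt_surface_area")]]
double mt_surface_area(NumericVector vol, IntegerVector dim,
                       NumericVector spacing, double level) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  double area = 0.0;
  double vals[8], pos[8][3];
  for (int i3 = 0; i3 < n3 - 1; ++i3)
    for (int i2 = 0; i2 < n2 - 1; ++i2)
      for (int i1 = 0; i1 < n1 - 1; ++i1) {
        double vmin = 1e300, vmax = -1e300;
        for (int v = 0; v < 8; ++v) {
          // VOFF is (z, y, x); axes 1/2/3 = z/y/x
          int a1 = i1 + VOFF[v][0], a2 = i2 + VOFF[v][1], a3 = i3 + VOFF[v][2];
          vals[v] = vol[lin(a1, a2, a3, n1, n2)];
          pos[v][0] = a1 * spacing[0];
          pos[v][1] = a2 * spacing[1];
          pos[v][2] = a3 * spacing[2];
          vmin = std::min(vmin, vals[v]);
          vmax = std::max(vmax, vals[v]);
        }
        if (vmax < level || vmin >= level) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tet = TETS[t];
          bool in[4];
          int nin = 0;
          for (int v = 0; v < 4; ++v) {
            in[v] = vals[tet[v]] >= level;
            nin += in[v];
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) (in[v] ? ins[ni++] : outs[no++]) = v;
          auto interp = [&](int a, int b, double* q) {
            double va = vals[tet[a]], vb = vals[tet[b]];
            double tt = (level - va) / (vb - va);
            for (int k = 0; k < 3; ++k)
              q[k] = pos[tet[a]][k] + tt * (pos[tet[b]][k] - pos[tet[a]][k]);
          };
          double p[4][3];
          if (nin == 1) {
            for (int j = 0; j < 3; ++j) interp(ins[0], outs[j], p[j]);
            area += tri_area(p[0], p[1], p[2]);
          } else if (nin == 3) {
            for (int j = 0; j < 3; ++j) interp(ins[j], outs[0], p[j]);
            area += tri_area(p[0], p[1], p[2]);
          } else {
            interp(ins[0], outs[0], p[0]);
            interp(ins[0], outs[1], p[1]);
            interp(ins[1], outs[0], p[2]);
            interp(ins[1], outs[1], p[3]);
            area += tri_area(p[0], p[1], p[3]);
            area += tri_area(p[0], p[3], p[2]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Boundary-contour length of a 2-D scalar field by marching squares (linear
// interpolation, physical spacing). Saddles pair crossings along the scan
// edges deterministically.

// [[Rcpp::export(name = ".ms_perimeter")]]
double ms_perimeter(NumericMatrix img, NumericVector spacing, double level) {
  const int ny = img.nrow(), nx = img.ncol();
  const double sy = spacing[0], sx = spacing[1];
  double per = 0.0;
  // corners (y, x): 0=(0,0) 1=(0,1) 2=(1,1) 3=(1,0); edges 01,12,23,30
  const int cy[4] = {0, 0, 1, 1}, cx[4] = {0, 1, 1, 0};
  const int e0[4] = {0, 1, 2, 3}, e1[4] = {1, 2, 3, 0};
  for (int y = 0; y < ny - 1; ++y)
    for (int x = 0; x < nx - 1; ++x) {
      double v[4];
      bool in[4];
      int nin = 0;
      for (int c = 0; c < 4; ++c) {
        v[c] = img(y + cy[c], x + cx[c]);
        in[c] = v[c] >= level;
        nin += in[c];
      }
      if (nin == 0 || nin == 4) continue;
      double q[4][2];
      int nq = 0;
      for (int e = 0; e < 4; ++e) {
        int a = e0[e], b = e1[e];
        if (in[a] != in[b]) {
          double t = (level - v[a]) / (v[b] - v[a]);
          q[nq][0] = ((y + cy[a]) + t * (cy[b] - cy[a])) * sy;
          q[nq][1] = ((x + cx[a]) + t * (cx[b] - cx[a])) * sx;
          ++nq;
        }
      }
      if (nq == 2) {
        per += std::hypot(q[0][0] - q[1][0], q[0][1] - q[1][1]);
      } else if (nq == 4) {
        per += std::hypot(q[0][0] - q[1][0], q[0][1] - q[1][1]);
        per += std::hypot(q[2][0] - q[3][0], q[2][1] - q[3][1]);
      }
    }
  return per;
}

// ---------------------------------------------------------------------------
// One-pass per-label statistics for a label volume: voxel count, index sums
// (for centroids), compartment overlap counts, distance-map max + argmax, and
// which of the six stack borders the label touches.

// [[Rcpp::export(name = ".label_stats")]]
List label_stats(IntegerVector labels, IntegerVector dim, LogicalVector soma,
                 LogicalVector nucleus, NumericVector d) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  int K = 0;
  for (R_xlen_t i = 0; i < N; ++i) if (labels[i] > K) K = labels[i];
  NumericVector n(K), s1(K), s2(K), s3(K), nsoma(K), nnuc(K), dmax(K);
  IntegerVector argmax(K, -1);
  LogicalMatrix touch(K, 6);
  std::fill(dmax.begin(), dmax.end(), -1.0);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        R_xlen_t p = lin(i1, i2, i3, n1, n2);
        int l = labels[p];
        if (!l) continue;
        int k = l - 1;
        n[k] += 1;
        s1[k] += i1;
        s2[k] += i2;
        s3[k] += i3;
        if (soma.size() == N && soma[p]) nsoma[k] += 1;
        if (nucleus.size() == N && nucleus[p]) nnuc[k] += 1;
        if (d.size() == N && d[p] > dmax[k]) { dmax[k] = d[p]; argmax[k] = (int)p; }
        if (i1 == 0) touch(k, 0) = TRUE;
        if (i1 == n1 - 1) touch(k, 1) = TRUE;
        if (i2 == 0) touch(k, 2) = TRUE;
        if (i2 == n2 - 1) touch(k, 3) = TRUE;
        if (i3 == 0) touch(k, 4) = TRUE;
        if (i3 == n3 - 1) touch(k, 5) = TRUE;
      }
  return List::create(_["n"] = n, _["s1"] = s1, _["s2"] = s2, _["s3"] = s3,
                      _["n_soma"] = nsoma, _["n_nucleus"] = nnuc,
                      _["d_max"] = dmax, _["d_argmax"] = argmax,
                      _["touches"] = touch);
}

// Unique face-adjacent label pairs (a < b) in a label volume.
// [[Rcpp::export(name = ".face_adjacency")]]
IntegerMatrix face_adjacency(IntegerVector labels, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::map<std::pair<int, int>, int> seen;
  auto note = [&](int a, int b) {
    if (a > 0 && b > 0 && a != b) {
      if (a > b) std::swap(a, b);
      seen[{a, b}] = 1;
    }
  };
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        int l = labels[lin(i1, i2, i3, n1, n2)];
        if (!l) continue;
        if (i1 + 1 < n1) note(l, labels[lin(i1 + 1, i2, i3, n1, n2)]);
        if (i2 + 1 < n2) note(l, labels[lin(i1, i2 + 1, i3, n1, n2)]);
        if (i3 + 1 < n3) note(l, labels[lin(i1, i2, i3 + 1, n1, n2)]);
      }
  IntegerMatrix out((int)seen.size(), 2);
  int r = 0;
  for (auto& kv : seen) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    ++r;
  }
  return out;
}
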