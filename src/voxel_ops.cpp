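// 3D voxel kernels used by the segmentation and feature-extraction stages.
// All volumes are R arrays in column-major order with dim = (d1, d2, d3);
// linear index = i1 + d1*(i2 + d2*i3), 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect boundary without repeating the edge sample twice in a row
  // (scipy-style "reflect" == half-sample symmetric is NOT what we want;
  //  we use whole-sample symmetric: -1 -> 1, n -> n-2)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector vol, IntegerVector dim,
                                  IntegerVector window) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int r1 = (window[0] - 1) / 2, r2 = (window[1] - 1) / 2,
            r3 = (window[2] - 1) / 2;
  const int wn = window[0] * window[1] * window[2];
  NumericVector out(vol.size());
  const double* v = REAL(vol);
  double* o = REAL(out);
  std::vector<double> buf(wn);
  const bool interior_ok = (d1 > 2 * r1 && d2 > 2 * r2 && d3 > 2 * r3);
  for (int i3 = 0; i3 < d3; ++i3) {
    for (int i2 = 0; i2 < d2; ++i2) {
      const bool inner23 = interior_ok && i2 >= r2 && i2 < d2 - r2 &&
                           i3 >= r3 && i3 < d3 - r3;
      for (int i1 = 0; i1 < d1; ++i1) {
        int k = 0;
        if (inner23 && i1 >= r1 && i1 < d1 - r1) {
          // interior: no boundary reflection needed
          for (int o3 = -r3; o3 <= r3; ++o3)
            for (int o2 = -r2; o2 <= r2; ++o2) {
              const double* p =
                  v + (i1 - r1) + d1 * ((i2 + o2) + d2 * (i3 + o3));
              for (int o1 = 0; o1 <= 2 * r1; ++o1) buf[k++] = p[o1];
            }
        } else {
          for (int o3 = -r3; o3 <= r3; ++o3) {
            const int j3 = reflect_idx(i3 + o3, d3);
            for (int o2 = -r2; o2 <= r2; ++o2) {
              const int j2 = reflect_idx(i2 + o2, d2);
              const int base = d1 * (j2 + d2 * j3);
              for (int o1 = -r1; o1 <= r1; ++o1)
                buf[k++] = v[reflect_idx(i1 + o1, d1) + base];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + wn / 2, buf.end());
        double med = buf[wn / 2];
        if (wn % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + wn / 2 - 1,
                           buf.begin() + wn / 2);
          med = 0.5 * (med + buf[wn / 2 - 1]);
        }
        o[i1 + d1 * (i2 + d2 * i3)] = med;
      }
    }
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), sample
// spacing `w`: f holds squared distances on input, overwritten on output.
static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z, int n,
                  double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  f = d;
}

// Euclidean distance (voxel units by default; `spacing` allows anisotropy)
// from every true voxel to the nearest false voxel. False voxels get 0.
// Space outside the volume is not treated as background.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;

  const int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2) {
      const int base = d1 * (i2 + d2 * i3);
      for (int i1 = 0; i1 < d1; ++i1) f[i1] = g[i1 + base];
      f.resize(d1);
      edt1d(f, d, v, z, d1, spacing[0]);
      for (int i1 = 0; i1 < d1; ++i1) g[i1 + base] = f[i1];
      f.resize(nmax);
    }
  // axis 2
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i1 = 0; i1 < d1; ++i1) {
      for (int i2 = 0; i2 < d2; ++i2) f[i2] = g[i1 + d1 * (i2 + d2 * i3)];
      f.resize(d2);
      edt1d(f, d, v, z, d2, spacing[1]);
      for (int i2 = 0; i2 < d2; ++i2) g[i1 + d1 * (i2 + d2 * i3)] = f[i2];
      f.resize(nmax);
    }
  // axis 3
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      for (int i3 = 0; i3 < d3; ++i3) f[i3] = g[i1 + d1 * (i2 + d2 * i3)];
      f.resize(d3);
      edt1d(f, d, v, z, d3, spacing[2]);
      for (int i3 = 0; i3 < d3; ++i3) g[i1 + d1 * (i2 + d2 * i3)] = f[i3];
      f.resize(nmax);
    }

  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

static void neighbour_offsets(int connectivity, const IntegerVector& dim,
                              std::vector<int>& off1, std::vector<int>& off2,
                              std::vector<int>& off3) {
  off1.clear(); off2.clear(); off3.clear();
  for (int o3 = -1; o3 <= 1; ++o3)
    for (int o2 = -1; o2 <= 1; ++o2)
      for (int o1 = -1; o1 <= 1; ++o1) {
        const int nz = std::abs(o1) + std::abs(o2) + std::abs(o3);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        off1.push_back(o1); off2.push_back(o2); off3.push_back(o3);
      }
}

// Connected-component labelling of a binary volume, 6- or 26-connectivity.
// Labels are 1..K in scan order of component discovery.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<int> off1, off2, off3;
  neighbour_offsets(connectivity, dim, off1, off2, off3);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int i1 = cur % d1, rem = cur / d1, i2 = rem % d2, i3 = rem / d2;
      for (size_t k = 0; k < off1.size(); ++k) {
        const int j1 = i1 + off1[k], j2 = i2 + off2[k], j3 = i3 + off3[k];
        if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
          continue;
        const int j = j1 + d1 * (j2 + d2 * j3);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Binary erosion by the 6-connected cross or the full 3x3x3 cube.
// Voxels outside the volume count as background, so volume-boundary
// voxels of the mask are always removed (they are surface).
// [[Rcpp::export]]
LogicalVector cpp_erode3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<int> off1, off2, off3;
  neighbour_offsets(connectivity, dim, off1, off2, off3);
  LogicalVector out(mask.size());
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        const int i = i1 + d1 * (i2 + d2 * i3);
        bool keep = mask[i];
        if (keep) {
          for (size_t k = 0; k < off1.size() && keep; ++k) {
            const int j1 = i1 + off1[k], j2 = i2 + off2[k], j3 = i3 + off3[k];
            if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 ||
                j3 >= d3) {
              keep = false;
            } else if (!mask[j1 + d1 * (j2 + d2 * j3)]) {
              keep = false;
            }
          }
        }
        out[i] = keep;
      }
  out.attr("dim") = dim;
  return out;
}

// Perinuclear ring ownership: every background voxel whose Euclidean
// distance to some labelled voxel is <= ring_width is assigned the label
// of the nearest labelled voxel; ties go to the lower label. Labelled
// voxels themselves keep 0 in the output (the ring excludes all nuclei).
// [[Rcpp::export]]
IntegerVector cpp_nearest_label_ring(IntegerVector labels, IntegerVector dim,
                                     double ring_width) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int R = (int)std::floor(ring_width);
  const double rw2 = ring_width * ring_width + 1e-9;
  // precompute in-ball offsets sorted by squared distance
  struct Off { int o1, o2, o3; double d2v; };
  std::vector<Off> offs;
  for (int o3 = -R; o3 <= R; ++o3)
    for (int o2 = -R; o2 <= R; ++o2)
      for (int o1 = -R; o1 <= R; ++o1) {
        const double dd = (double)(o1 * o1 + o2 * o2 + o3 * o3);
        if (dd == 0.0 || dd > rw2) continue;
        offs.push_back({o1, o2, o3, dd});
      }
  std::stable_sort(offs.begin(), offs.end(),
                   [](const Off& a, const Off& b) { return a.d2v < b.d2v; });
  IntegerVector ring(labels.size(), 0);
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        const int i = i1 + d1 * (i2 + d2 * i3);
        if (labels[i] != 0) continue;
        double best_d = -1.0;
        int best_lab = 0;
        for (size_t k = 0; k < offs.size(); ++k) {
          if (best_lab != 0 && offs[k].d2v > best_d) break;
          const int j1 = i1 + offs[k].o1, j2 = i2 + offs[k].o2,
                    j3 = i3 + offs[k].o3;
          if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
            continue;
          const int lab = labels[j1 + d1 * (j2 + d2 * j3)];
          if (lab == 0) continue;
          if (best_lab == 0) {
            best_lab = lab;
            best_d = offs[k].d2v;
          } else if (offs[k].d2v == best_d && lab < best_lab) {
            best_lab = lab;
          }
        }
        ring[i] = best_lab;
      }
  ring.attr("dim") = dim;
  return ring;
}

// Local maxima of `vol` within a cubic window of half-width `radius`,
// restricted to vol > 0. Plateau maxima are all flagged (merged later).
// [[Rcpp::export]]
LogicalVector cpp_local_maxima3d(NumericVector vol, IntegerVector dim,
                                 int radius) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector out(vol.size());
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2)
      for (int i1 = 0; i1 < d1; ++i1) {
        const int i = i1 + d1 * (i2 + d2 * i3);
        const double v = vol[i];
        if (v <= 0) { out[i] = false; continue; }
        bool is_max = true;
        for (int o3 = -radius; o3 <= radius && is_max; ++o3) {
          const int j3 = i3 + o3;
          if (j3 < 0 || j3 >= d3) continue;
          for (int o2 = -radius; o2 <= radius && is_max; ++o2) {
            const int j2 = i2 + o2;
            if (j2 < 0 || j2 >= d2) continue;
            const int base = d1 * (j2 + d2 * j3);
            for (int o1 = -radius; o1 <= radius; ++o1) {
              const int j1 = i1 + o1;
              if (j1 < 0 || j1 >= d1) continue;
              if (vol[j1 + base] > v) { is_max = false; break; }
            }
          }
        }
        out[i] = is_max;
      }
  out.attr("dim") = dim;
  return out;
}

// Seeded watershed by priority flooding: regions grow from seed labels
// outward through `mask`, always expanding the highest-priority frontier
// voxel first (priority = distance transform, so ridges are reached last).
// Deterministic: FIFO order breaks priority ties.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector priority, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::vector<int> off1, off2, off3;
  neighbour_offsets(6, dim, off1, off2, off3);
  IntegerVector lab(clone(seeds));
  struct Node {
    double p;
    long order;
    int idx;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.p != b.p) return a.p < b.p;  // max-heap on priority
      return a.order > b.order;          // FIFO among ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < seeds.size(); ++i)
    if (seeds[i] != 0) pq.push({priority[i], order++, (int)i});
  while (!pq.empty()) {
    const Node nd = pq.top();
    pq.pop();
    const int cur = nd.idx;
    const int i1 = cur % d1, rem = cur / d1, i2 = rem % d2, i3 = rem / d2;
    const int mylab = lab[cur];
    for (size_t k = 0; k < off1.size(); ++k) {
      const int j1 = i1 + off1[k], j2 = i2 + off2[k], j3 = i3 + off3[k];
      if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
        continue;
      const int j = j1 + d1 * (j2 + d2 * j3);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = mylab;
      pq.push({priority[j], order++, j});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
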