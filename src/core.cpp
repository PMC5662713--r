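#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double R_CLIP = 1.0 - 1e-7;

// Searchlight weighted sum of Fisher-z pattern correlations.
//
// A, B: voxel-by-trial matrices restricted to the analysis mask (column = one
// trial's pattern). mask_lin0: 0-based linear indices (into the full volume)
// of the mask voxels, in the same order as the rows of A/B. col_of_lin0 maps
// every linear voxel index to its row in A/B, or -1 outside the mask.
// offsets: K x 3 integer voxel offsets enumerating the sphere.
// wi0/wj0/wv: triplets of the nonzero contrast weights (0-based trial
// indices into columns of A and B).
//
// Returns per-center S(v) = sum_ij w_ij * atanh(clip(corr)) over the in-mask
// neighborhood of v; NaN where the neighborhood has fewer than min_voxels
// voxels. Zero-variance patterns contribute z = 0 and are counted.
// [[Rcpp::export]]
List cpp_searchlight(NumericMatrix A, NumericMatrix B,
                     IntegerVector dims, IntegerVector mask_lin0,
                     IntegerVector col_of_lin0, IntegerMatrix offsets,
                     IntegerVector wi0, IntegerVector wj0, NumericVector wv,
                     int min_voxels) {
  const int V = mask_lin0.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = offsets.nrow();
  const int P = wi0.size();
  const int Ta = A.ncol(), Tb = B.ncol();

  // which trials actually appear in the contrast
  std::vector<int> used_a, used_b;
  std::vector<int> pos_a(Ta, -1), pos_b(Tb, -1);
  for (int p = 0; p < P; ++p) {
    int i = wi0[p], j = wj0[p];
    if (pos_a[i] < 0) { pos_a[i] = used_a.size(); used_a.push_back(i); }
    if (pos_b[j] < 0) { pos_b[j] = used_b.size(); used_b.push_back(j); }
  }
  const int Ua = used_a.size(), Ub = used_b.size();

  NumericVector out(V, NA_REAL);
  long zero_var = 0;

  std::vector<int> nb; nb.reserve(K);
  std::vector<double> sa(Ua), ssa(Ua), sb(Ub), ssb(Ub);
  std::vector<double> bufA((size_t)K * Ua), bufB((size_t)K * Ub);

  for (int c = 0; c < V; ++c) {
    int lin = mask_lin0[c];
    int x = lin % nx, rem = lin / nx;
    int y = rem % ny, z = rem / ny;

    nb.clear();
    for (int k = 0; k < K; ++k) {
      int xx = x + offsets(k, 0);
      int yy = y + offsets(k, 1);
      int zz = z + offsets(k, 2);
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int col = col_of_lin0[xx + nx * (yy + (R_xlen_t)ny * zz)];
      if (col >= 0) nb.push_back(col);
    }
    const int n = nb.size();
    if (n < min_voxels) continue;

    // gather contiguous neighborhood buffers so pair dot-products vectorize
    for (int u = 0; u < Ua; ++u) {
      const double *col = &A(0, used_a[u]);
      double *dst = &bufA[(size_t)u * n];
      double s = 0, ss = 0;
      for (int k = 0; k < n; ++k) {
        double v = col[nb[k]]; dst[k] = v; s += v; ss += v * v;
      }
      sa[u] = s; ssa[u] = ss;
    }
    for (int u = 0; u < Ub; ++u) {
      const double *col = &B(0, used_b[u]);
      double *dst = &bufB[(size_t)u * n];
      double s = 0, ss = 0;
      for (int k = 0; k < n; ++k) {
        double v = col[nb[k]]; dst[k] = v; s += v; ss += v * v;
      }
      sb[u] = s; ssb[u] = ss;
    }

    double S = 0;
    for (int p = 0; p < P; ++p) {
      const int ia = pos_a[wi0[p]], ib = pos_b[wj0[p]];
      const double *ca = &bufA[(size_t)ia * n];
      const double *cb = &bufB[(size_t)ib * n];
      double sab = 0;
      for (int k = 0; k < n; ++k) sab += ca[k] * cb[k];
      double va = n * ssa[ia] - sa[ia] * sa[ia];
      double vb = n * ssb[ib] - sb[ib] * sb[ib];
      if (va <= 1e-12 || vb <= 1e-12) { ++zero_var; continue; }
      double r = (n * sab - sa[ia] * sb[ib]) / std::sqrt(va * vb);
      if (r > R_CLIP) r = R_CLIP; else if (r < -R_CLIP) r = -R_CLIP;
      S += wv[p] * std::atanh(r);
    }
    out[c] = S;
  }

  return List::create(_["values"] = out,
                      _["zero_variance_pairs"] = (double)zero_var);
}

// Separable Gaussian convolution of a 3D volume with truncated kernels
// (no edge renormalization; callers renormalize within a mask).
// sigma_vox: per-axis standard deviation in voxel units.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> cur(vol.begin(), vol.end()), nxt(cur.size());
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int half = (int)std::ceil(4.0 * s);
    std::vector<double> ker(2 * half + 1);
    double tot = 0;
    for (int k = -half; k <= half; ++k) {
      double w = std::exp(-0.5 * k * k / (s * s));
      ker[k + half] = w; tot += w;
    }
    for (double &w : ker) w /= tot;

    const int len = sizes[ax], stride = strides[ax];
    const int nline = (nx * ny * nz) / len;
    // iterate all lines along this axis
    for (int line = 0; line < nline; ++line) {
      // compute base index of the line
      int base;
      if (ax == 0) base = line * nx;
      else if (ax == 1) { int x = line % nx, z = line / nx; base = x + nx * ny * z; }
      else base = line;
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        int lo = std::max(0, i - half), hi = std::min(len - 1, i + half);
        for (int j = lo; j <= hi; ++j)
          acc += ker[j - i + half] * cur[base + j * stride];
        nxt[base + i * stride] = acc;
      }
    }
    std::swap(cur, nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

static void neighbor_offsets(int connectivity, const IntegerVector &dims,
                             std::vector<std::array<int,3>> &offs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

// Label connected components among supra-threshold voxels.
// supra0: 0-based linear indices; returns 1-based component label per voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(IntegerVector supra0, IntegerVector dims,
                                 int connectivity) {
  const int n = supra0.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<int, int> idx;
  idx.reserve(n * 2);
  for (int i = 0; i < n; ++i) idx[supra0[i]] = i;
  std::vector<std::array<int,3>> offs;
  neighbor_offsets(connectivity, dims, offs);

  int next_label = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (labels[i]) continue;
    labels[i] = ++next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int lin = supra0[cur];
      int x = lin % nx, rem = lin / nx;
      int y = rem % ny, z = rem / ny;
      for (auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        auto it = idx.find(xx + nx * (yy + ny * zz));
        if (it != idx.end() && !labels[it->second]) {
          labels[it->second] = next_label;
          stack.push_back(it->second);
        }
      }
    }
  }
  return labels;
}

// Maximum connected-component size among supra-threshold voxels.
// [[Rcpp::export]]
int cpp_max_cluster(IntegerVector supra0, IntegerVector dims, int connectivity) {
  IntegerVector lab = cpp_label_clusters(supra0, dims, connectivity);
  int mx = 0;
  if (lab.size() == 0) return 0;
  int nlab = 0;
  for (int i = 0; i < lab.size(); ++i) nlab = std::max(nlab, lab[i]);
  std::vector<int> cnt(nlab + 1, 0);
  for (int i = 0; i < lab.size(); ++i) ++cnt[lab[i]];
  for (int l = 1; l <= nlab; ++l) mx = std::max(mx, cnt[l]);
  return mx;
}
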