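#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Similarity transform convention (shared with R/transforms.R):
// model = s * R(theta) * native + t, coordinates (x = col, y = row)
// taken relative to the image centre ((dim - 1) / 2, 0-based).
// Resampling inverts the map: for each output pixel the source pixel is
// looked up nearest-neighbour; out-of-bounds sources get `oob`.

// [[Rcpp::export]]
IntegerMatrix cpm_resample_nn(const IntegerMatrix& grid,
                              double tx, double ty, double theta, double s,
                              int nrow_out, int ncol_out, int oob) {
  const int nr = grid.nrow(), nc = grid.ncol();
  const double cyi = (nr - 1) / 2.0, cxi = (nc - 1) / 2.0;
  const double cyo = (nrow_out - 1) / 2.0, cxo = (ncol_out - 1) / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  IntegerMatrix out(nrow_out, ncol_out);
  for (int j = 0; j < ncol_out; ++j) {
    const double x = j - cxo - tx;
    for (int i = 0; i < nrow_out; ++i) {
      const double y = i - cyo - ty;
      const double xs = ( ct * x + st * y) / s + cxi;
      const double ys = (-st * x + ct * y) / s + cyi;
      const int js = (int) std::lround(xs);
      const int is = (int) std::lround(ys);
      out(i, j) = (is >= 0 && is < nr && js >= 0 && js < nc) ? grid(is, js) : oob;
    }
  }
  return out;
}

// Categorical template-matching score: mean, over model pixels with
// support > 0, of the model frequency of the class observed in the
// transformed pattern at that pixel.  freq has dim (nr, nc, K) with class
// codes 0..K-1 (code 0 = background); out-of-bounds sources count as
// background.  Candidates: one row per (tx, ty, theta, s).

// [[Rcpp::export]]
NumericVector cpm_score_batch(const IntegerMatrix& grid,
                              const NumericVector& freq,
                              const IntegerMatrix& support,
                              const NumericMatrix& cand) {
  IntegerVector dims = freq.attr("dim");
  const int nr = dims[0], nc = dims[1], K = dims[2];
  const int gnr = grid.nrow(), gnc = grid.ncol();
  const double cyi = (gnr - 1) / 2.0, cxi = (gnc - 1) / 2.0;
  const double cyo = (nr - 1) / 2.0, cxo = (nc - 1) / 2.0;

  // precompute supported pixel list
  std::vector<int> si, sj;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (support(i, j) > 0) { si.push_back(i); sj.push_back(j); }
  const int np = (int) si.size();

  NumericVector out(cand.nrow());
  for (int c = 0; c < cand.nrow(); ++c) {
    const double tx = cand(c, 0), ty = cand(c, 1);
    const double ct = std::cos(cand(c, 2)), st = std::sin(cand(c, 2));
    const double s = cand(c, 3);
    double acc = 0.0;
    for (int p = 0; p < np; ++p) {
      const int i = si[p], j = sj[p];
      const double x = j - cxo - tx, y = i - cyo - ty;
      const double xs = ( ct * x + st * y) / s + cxi;
      const double ys = (-st * x + ct * y) / s + cyi;
      const int js = (int) std::lround(xs);
      const int is = (int) std::lround(ys);
      int k = 0;
      if (is >= 0 && is < gnr && js >= 0 && js < gnc) k = grid(is, js);
      if (k < 0 || k >= K) k = 0;
      acc += freq[i + (size_t) nr * j + (size_t) nr * nc * k];
    }
    out[c] = np > 0 ? acc / np : 0.0;
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}
static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a); b = uf_find(parent, b);
  if (a != b) parent[b] = a;
}

// Connected components of a logical mask (4-connectivity); 0 = not in mask,
// components labelled 1..n in scan order.

// [[Rcpp::export]]
IntegerMatrix cpm_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> parent(nr * nc);
  for (int k = 0; k < nr * nc; ++k) parent[k] = k;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      if (i + 1 < nr && mask(i + 1, j)) uf_union(parent, i + j * nr, i + 1 + j * nr);
      if (j + 1 < nc && mask(i, j + 1)) uf_union(parent, i + j * nr, i + (j + 1) * nr);
    }
  IntegerMatrix lab(nr, nc);
  std::vector<int> relab(nr * nc, 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) { lab(i, j) = 0; continue; }
      int r = uf_find(parent, i + j * nr);
      if (relab[r] == 0) relab[r] = ++next;
      lab(i, j) = relab[r];
    }
  return lab;
}

// Single-linkage region growing: 4-neighbour pixels whose RGB distance is
// below `thr` are merged into one region.  img has dim (nr, nc, 3).

// [[Rcpp::export]]
IntegerMatrix cpm_merge_labels(const NumericVector& img, double thr) {
  IntegerVector dims = img.attr("dim");
  const int nr = dims[0], nc = dims[1];
  const size_t plane = (size_t) nr * nc;
  std::vector<int> parent(nr * nc);
  for (int k = 0; k < nr * nc; ++k) parent[k] = k;
  const double thr2 = thr * thr;
  auto dist2 = [&](int a, int b) {
    double d = 0;
    for (int ch = 0; ch < 3; ++ch) {
      double x = img[a + ch * plane] - img[b + ch * plane];
      d += x * x;
    }
    return d;
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int k = i + j * nr;
      if (i + 1 < nr && dist2(k, k + 1) < thr2) uf_union(parent, k, k + 1);
      if (j + 1 < nc && dist2(k, k + nr) < thr2) uf_union(parent, k, k + nr);
    }
  IntegerMatrix lab(nr, nc);
  std::vector<int> relab(nr * nc, 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int r = uf_find(parent, i + j * nr);
      if (relab[r] == 0) relab[r] = ++next;
      lab(i, j) = relab[r];
    }
  return lab;
}

// Even-odd rule point-in-polygon test, vectorized over query points.

// [[Rcpp::export]]
LogicalVector cpm_in_polygon(const NumericVector& px, const NumericVector& py,
                             const NumericVector& vx, const NumericVector& vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector out(n);
  for (int k = 0; k < n; ++k) {
    bool inside = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      if (((vy[i] > py[k]) != (vy[j] > py[k])) &&
          (px[k] < (vx[j] - vx[i]) * (py[k] - vy[i]) / (vy[j] - vy[i]) + vx[i]))
        inside = !inside;
    }
    out[k] = inside;
  }
  return out;
}

// Area-majority resampling of a categorical raster: each output pixel is
// assigned the modal class over a vote x vote grid of subpixel samples
// (nearest-neighbour lookups), approximating the majority class of the
// pixel's footprint.  Ties break to the lower class code (declaration
// order); out-of-bounds samples vote for `oob`.

// [[Rcpp::export]]
IntegerMatrix cpm_resample_vote(const IntegerMatrix& grid,
                                double tx, double ty, double theta, double s,
                                int nrow_out, int ncol_out, int oob,
                                int K, int vote) {
  if (vote <= 1)
    return cpm_resample_nn(grid, tx, ty, theta, s, nrow_out, ncol_out, oob);
  const int nr = grid.nrow(), nc = grid.ncol();
  const double cyi = (nr - 1) / 2.0, cxi = (nc - 1) / 2.0;
  const double cyo = (nrow_out - 1) / 2.0, cxo = (ncol_out - 1) / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  IntegerMatrix out(nrow_out, ncol_out);
  std::vector<int> cnt(K + 1);           // last slot counts oob votes
  std::vector<double> off(vote);
  for (int v = 0; v < vote; ++v) off[v] = (v + 0.5) / vote - 0.5;
  for (int j = 0; j < ncol_out; ++j) {
    for (int i = 0; i < nrow_out; ++i) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int a = 0; a < vote; ++a) {
        const double x = j + off[a] - cxo - tx;
        for (int b = 0; b < vote; ++b) {
          const double y = i + off[b] - cyo - ty;
          const double xs = ( ct * x + st * y) / s + cxi;
          const double ys = (-st * x + ct * y) / s + cyi;
          const int js = (int) std::lround(xs);
          const int is = (int) std::lround(ys);
          if (is >= 0 && is < nr && js >= 0 && js < nc) {
            int k = grid(is, js);
            if (k >= 0 && k < K) cnt[k]++; else cnt[K]++;
          } else cnt[K]++;
        }
      }
      int best = 0, bestn = -1;
      for (int k = 0; k < K; ++k)
        if (cnt[k] > bestn) { bestn = cnt[k]; best = k; }
      // oob majority -> treat as out of frame
      out(i, j) = (cnt[K] > bestn) ? oob : best;
    }
  }
  return out;
}
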