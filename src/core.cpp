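#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Grid-bucketed fixed-radius neighbour search over the first two feature
// dimensions (pixel x, y); the Euclidean test itself uses all columns.
// Valid because |dx| > eps or |dy| > eps already implies distance > eps.
namespace {

struct GridIndex {
  std::unordered_map<long long, std::vector<int> > cells;
  double cell;
  const NumericMatrix& pts;

  GridIndex(const NumericMatrix& p, double eps) : cell(eps), pts(p) {
    for (int i = 0; i < p.nrow(); ++i)
      cells[key(p(i, 0), p(i, 1))].push_back(i);
  }

  long long key(double x, double y) const {
    long long cx = (long long)std::floor(x / cell);
    long long cy = (long long)std::floor(y / cell);
    return cx * 2097152LL * 2097152LL + cy * 2097152LL; // collision-free for image coords
  }

  // neighbours of point i (self included), sorted by point index
  void query(int i, double eps2, std::vector<int>& out) const {
    out.clear();
    int d = pts.ncol();
    long long cx = (long long)std::floor(pts(i, 0) / cell);
    long long cy = (long long)std::floor(pts(i, 1) / cell);
    for (long long gx = cx - 1; gx <= cx + 1; ++gx) {
      for (long long gy = cy - 1; gy <= cy + 1; ++gy) {
        long long k = gx * 2097152LL * 2097152LL + gy * 2097152LL;
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          cells.find(k);
        if (it == cells.end()) continue;
        const std::vector<int>& bucket = it->second;
        for (size_t b = 0; b < bucket.size(); ++b) {
          int j = bucket[b];
          double s = 0.0;
          for (int c = 0; c < d; ++c) {
            double diff = pts(i, c) - pts(j, c);
            s += diff * diff;
            if (s > eps2) break;
          }
          if (s <= eps2) out.push_back(j);
        }
      }
    }
    std::sort(out.begin(), out.end());
  }
};

} // namespace

// Canonical DBSCAN. Points are visited in row order; a point is core when
// >= minPts points (itself included) lie within eps. Border points keep the
// label of the first cluster that reaches them, clusters are numbered 1..k
// in order of creation, noise is 0. With rows supplied in row-major pixel
// order this realises the deterministic first-reached-core tie-break.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int minPts) {
  int n = pts.nrow();
  IntegerVector label(n, 0);
  std::vector<bool> visited(n, false);
  if (n == 0) return label;
  GridIndex grid(pts, eps);
  double eps2 = eps * eps;
  std::vector<int> nb, nb2;
  int cid = 0;

  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    grid.query(i, eps2, nb);
    if ((int)nb.size() < minPts) continue; // noise unless later claimed as border
    ++cid;
    label[i] = cid;
    std::vector<int> seeds(nb);
    for (size_t s = 0; s < seeds.size(); ++s) {
      int q = seeds[s];
      if (!visited[q]) {
        visited[q] = true;
        grid.query(q, eps2, nb2);
        if ((int)nb2.size() >= minPts)
          seeds.insert(seeds.end(), nb2.begin(), nb2.end());
      }
      if (label[q] == 0) label[q] = cid;
    }
  }
  return label;
}

// 8-connected component labelling of a binary mask; labels are consecutive
// from 1 in row-major order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int cid = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++cid;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = cid;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int pr = idx % nr, pc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = cid;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ImageJ-style "Remove Outliers": replace a pixel by the median of its
// circular neighbourhood (radius in px, centre included, clipped at the
// borders) iff it deviates from that median by more than `threshold`.
// mode: 1 = bright outliers, 2 = dark, 3 = both.
// [[Rcpp::export]]
NumericMatrix cpp_remove_outliers(NumericMatrix img, int radius,
                                  double threshold, int mode) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<int, int> > off;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius)
        off.push_back(std::make_pair(dr, dc));
  std::vector<double> v;
  v.reserve(off.size());
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      v.clear();
      for (size_t k = 0; k < off.size(); ++k) {
        int qr = r + off[k].first, qc = c + off[k].second;
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        v.push_back(img(qr, qc));
      }
      size_t m = v.size() / 2;
      std::nth_element(v.begin(), v.begin() + m, v.end());
      double med = v[m];
      if (v.size() % 2 == 0) {
        double lo = *std::max_element(v.begin(), v.begin() + m);
        med = (med + lo) / 2.0;
      }
      double x = img(r, c);
      bool hit = (mode != 2 && x - med > threshold) ||
                 (mode != 1 && med - x > threshold);
      out(r, c) = hit ? med : x;
    }
  }
  return out;
}
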