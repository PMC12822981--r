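#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Pairwise window kernels are O(n_windows^2); they live here so that 2D
// entropy stays tractable on full-size ROIs.

// Sample entropy pair counts. Windows of side m are taken only at top-left
// positions where an (m+1)x(m+1) window also fits, so the m and m+1 counts
// share a common support. Returns c(A, B): unordered pair counts with
// Chebyshev distance <= r at sizes m+1 and m. A match at m+1 implies a match
// at m (the m-window is nested), so the m+1 check runs only after an m match.
// [[Rcpp::export]]
NumericVector cpp_sampen2d_counts(NumericMatrix x, int m, double r) {
  const int H = x.nrow(), W = x.ncol();
  const int nh = H - m, nw = W - m;  // positions where (m+1)-window fits
  if (nh < 1 || nw < 1) stop("image too small for template size m+1");
  const int n = nh * nw;
  const int km = m * m;
  const int ke = 2 * m + 1;  // extra pixels completing the (m+1)-window
  std::vector<double> wm((size_t)n * km), we((size_t)n * ke);
  for (int p = 0; p < n; ++p) {
    const int pi = p % nh, pj = p / nh;
    int k = 0;
    double *b = &wm[(size_t)p * km];
    for (int dj = 0; dj < m; ++dj)
      for (int di = 0; di < m; ++di) b[k++] = x(pi + di, pj + dj);
    k = 0;
    double *e = &we[(size_t)p * ke];
    for (int di = 0; di <= m; ++di) e[k++] = x(pi + di, pj + m);
    for (int dj = 0; dj < m; ++dj) e[k++] = x(pi + m, pj + dj);
  }
  double A = 0.0, B = 0.0;
  for (int p = 0; p < n; ++p) {
    const double *bp = &wm[(size_t)p * km], *ep = &we[(size_t)p * ke];
    for (int q = p + 1; q < n; ++q) {
      const double *bq = &wm[(size_t)q * km];
      bool match_m = true;
      for (int k = 0; k < km; ++k) {
        if (std::fabs(bp[k] - bq[k]) > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      const double *eq = &we[(size_t)q * ke];
      bool match_m1 = true;
      for (int k = 0; k < ke; ++k) {
        if (std::fabs(ep[k] - eq[k]) > r) { match_m1 = false; break; }
      }
      if (match_m1) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Fuzzy entropy: mean-centered windows, similarity exp(-(d^nexp)/r) with d
// the Chebyshev distance of the centered windows. Returns c(phi_m, phi_m1),
// the average similarity over unordered distinct pairs at the common
// positions (where the (m+1)-window fits). Windows are pre-extracted into
// contiguous buffers: the pair loop is O(n^2) and dominates the runtime.
// [[Rcpp::export]]
NumericVector cpp_fuzzen2d_phis(NumericMatrix x, int m, double r, double nexp) {
  const int H = x.nrow(), W = x.ncol();
  const int nh = H - m, nw = W - m;
  if (nh < 1 || nw < 1) stop("image too small for template size m+1");
  const int n = nh * nw;
  const int m1 = m + 1;
  const int km = m * m, km1 = m1 * m1;
  std::vector<double> wm((size_t)n * km), wm1((size_t)n * km1);
  for (int p = 0; p < n; ++p) {
    const int pi = p % nh, pj = p / nh;
    double s = 0.0, s1 = 0.0;
    int k = 0, k1 = 0;
    double *bm = &wm[(size_t)p * km], *bm1 = &wm1[(size_t)p * km1];
    for (int dj = 0; dj < m1; ++dj)
      for (int di = 0; di < m1; ++di) {
        double v = x(pi + di, pj + dj);
        bm1[k1++] = v; s1 += v;
        if (di < m && dj < m) { bm[k++] = v; s += v; }
      }
    const double mu = s / km, mu1 = s1 / km1;
    for (k = 0; k < km; ++k) bm[k] -= mu;
    for (k1 = 0; k1 < km1; ++k1) bm1[k1] -= mu1;
  }
  const bool sq = (nexp == 2.0);
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int p = 0; p < n; ++p) {
    const double *bpm = &wm[(size_t)p * km], *bpm1 = &wm1[(size_t)p * km1];
    for (int q = p + 1; q < n; ++q) {
      const double *bqm = &wm[(size_t)q * km], *bqm1 = &wm1[(size_t)q * km1];
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < km; ++k) {
        double d = std::fabs(bpm[k] - bqm[k]);
        if (d > dm) dm = d;
      }
      for (int k = 0; k < km1; ++k) {
        double d = std::fabs(bpm1[k] - bqm1[k]);
        if (d > dm1) dm1 = d;
      }
      if (sq) {
        phi_m += std::exp(-(dm * dm) / r);
        phi_m1 += std::exp(-(dm1 * dm1) / r);
      } else {
        phi_m += std::exp(-std::pow(dm, nexp) / r);
        phi_m1 += std::exp(-std::pow(dm1, nexp) / r);
      }
    }
  }
  const double npairs = (double)n * (n - 1) / 2.0;
  return NumericVector::create(phi_m / npairs, phi_m1 / npairs);
}

// Distribution entropy histogram: Chebyshev distances of all unordered
// distinct m x m window pairs, binned into `bins` equal-width bins spanning
// [0, max distance]. Two passes (max, then counts) to avoid storing the
// O(n^2) distance matrix. Returns the bin counts.
// [[Rcpp::export]]
NumericVector cpp_disten2d_hist(NumericMatrix x, int m, int bins) {
  const int H = x.nrow(), W = x.ncol();
  const int nh = H - m + 1, nw = W - m + 1;
  if (nh < 1 || nw < 1) stop("image too small for template size m");
  const int n = nh * nw;
  if (n < 2) stop("fewer than 2 windows");
  const int km = m * m;
  std::vector<double> w((size_t)n * km);
  for (int p = 0; p < n; ++p) {
    const int pi = p % nh, pj = p / nh;
    int k = 0;
    double *b = &w[(size_t)p * km];
    for (int dj = 0; dj < m; ++dj)
      for (int di = 0; di < m; ++di) b[k++] = x(pi + di, pj + dj);
  }
  double maxd = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    NumericVector counts(bins);
    for (int p = 0; p < n; ++p) {
      const double *bp = &w[(size_t)p * km];
      for (int q = p + 1; q < n; ++q) {
        const double *bq = &w[(size_t)q * km];
        double dmax = 0.0;
        for (int k = 0; k < km; ++k) {
          double d = std::fabs(bp[k] - bq[k]);
          if (d > dmax) dmax = d;
        }
        if (pass == 0) {
          if (dmax > maxd) maxd = dmax;
        } else {
          int b = (maxd > 0.0) ? (int)std::floor(dmax / maxd * bins) : 0;
          if (b >= bins) b = bins - 1;
          counts[b] += 1.0;
        }
      }
    }
    if (pass == 1) return counts;
  }
  return NumericVector(bins);  // unreachable
}

// Median filter with replicate (clamp-to-edge) padding.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int radius) {
  const int H = x.nrow(), W = x.ncol();
  const int k = 2 * radius + 1, nsz = k * k;
  NumericMatrix out(H, W);
  std::vector<double> buf(nsz);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int idx = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int cj = std::min(std::max(j + dj, 0), W - 1);
        for (int di = -radius; di <= radius; ++di) {
          int ci = std::min(std::max(i + di, 0), H - 1);
          buf[idx++] = x(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + nsz / 2, buf.end());
      out(i, j) = buf[nsz / 2];
    }
  return out;
}

// 8-connected components of equal gray level (size-zone matrix support).
// Returns a label matrix with zones numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_zones(IntegerMatrix lv) {
  const int H = lv.nrow(), W = lv.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (lab(i, j) != 0) continue;
      const int g = lv(i, j);
      lab(i, j) = ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        std::pair<int,int> c = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = c.first + di, nj = c.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (lab(ni, nj) == 0 && lv(ni, nj) == g) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}
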