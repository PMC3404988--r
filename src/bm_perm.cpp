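#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// midranks (average ranks under ties) of v
static std::vector<double> midranks(const std::vector<double>& v) {
  int n = v.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    double avg = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
  return r;
}

// Brunner-Munzel studentized statistic from group values and their pooled
// midranks. Zero rank variance: 0 when the mean midranks agree (all tied),
// +/-Inf for perfect separation. Groups of size 1 contribute zero variance.
static double bm_stat(const std::vector<double>& x, const std::vector<double>& y,
                      const std::vector<double>& Rx, const std::vector<double>& Ry) {
  int nx = x.size(), ny = y.size();
  std::vector<double> rx = midranks(x), ry = midranks(y);
  double m1 = 0.0, m2 = 0.0;
  for (double v : Rx) m1 += v;
  m1 /= nx;
  for (double v : Ry) m2 += v;
  m2 /= ny;
  double v1 = 0.0, v2 = 0.0;
  if (nx > 1) {
    for (int i = 0; i < nx; ++i) {
      double t = Rx[i] - rx[i] - m1 + (nx + 1) / 2.0;
      v1 += t * t;
    }
    v1 /= (nx - 1);
  }
  if (ny > 1) {
    for (int i = 0; i < ny; ++i) {
      double t = Ry[i] - ry[i] - m2 + (ny + 1) / 2.0;
      v2 += t * t;
    }
    v2 /= (ny - 1);
  }
  double denom = std::sqrt((double)nx * v1 + (double)ny * v2);
  double num = (double)nx * ny * (m2 - m1) / (nx + ny);
  if (denom == 0.0) {
    if (num == 0.0) return 0.0;
    return num > 0.0 ? R_PosInf : R_NegInf;
  }
  return num / denom;
}

// Monte-Carlo null: reassign pooled values to groups of size nx / N-nx at
// random (Fisher-Yates driven by R's RNG so set.seed() controls the draw)
// and return the statistic of every permutation.
// [[Rcpp::export]]
NumericVector cpp_bm_perm(NumericVector pooled, int nx, int nperm) {
  int N = pooled.size(), ny = N - nx;
  std::vector<double> vals(pooled.begin(), pooled.end());
  std::vector<double> R = midranks(vals);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericVector out(nperm);
  std::vector<double> x(nx), y(ny), Rx(nx), Ry(ny);
  for (int p = 0; p < nperm; ++p) {
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < nx; ++i) { x[i] = vals[idx[i]]; Rx[i] = R[idx[i]]; }
    for (int i = 0; i < ny; ++i) { y[i] = vals[idx[nx + i]]; Ry[i] = R[idx[nx + i]]; }
    out[p] = bm_stat(x, y, Rx, Ry);
  }
  return out;
}

// Statistic for explicit group assignments: each column of xidx holds the
// 1-based indices of the pooled values assigned to the first group.
// [[Rcpp::export]]
NumericVector cpp_bm_assignments(NumericVector pooled, IntegerMatrix xidx) {
  int N = pooled.size();
  int nx = xidx.nrow(), ny = N - nx, B = xidx.ncol();
  std::vector<double> vals(pooled.begin(), pooled.end());
  std::vector<double> R = midranks(vals);
  NumericVector out(B);
  std::vector<bool> inx(N);
  std::vector<double> x(nx), y(ny), Rx(nx), Ry(ny);
  for (int b = 0; b < B; ++b) {
    std::fill(inx.begin(), inx.end(), false);
    for (int i = 0; i < nx; ++i) {
      int k = xidx(i, b) - 1;
      x[i] = vals[k]; Rx[i] = R[k]; inx[k] = true;
    }
    int j = 0;
    for (int k = 0; k < N; ++k) {
      if (!inx[k]) { y[j] = vals[k]; Ry[j] = R[k]; ++j; }
    }
    out[b] = bm_stat(x, y, Rx, Ry);
  }
  return out;
}
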