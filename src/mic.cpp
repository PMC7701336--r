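// Maximal information coefficient (MIC) by the characteristic-matrix
// dynamic-programming approximation: one axis is equipartitioned into rows,
// the other axis is optimally partitioned (over clump boundaries) by DP;
// both orientations are searched and the maximum normalized mutual
// information over all grids with (columns x rows) <= B = n^alpha is
// returned.  Mutual information is additive over columns, which gives an
// exact DP on the clump-respecting partitions.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Greedy equipartition of "groups" (tie groups of consecutive sorted
// values, never split) into at most q bins of near-equal point counts.
// Returns bin index per group.
static std::vector<int> equipartition(const std::vector<int>& group_sizes,
                                      int q) {
  const int g = (int)group_sizes.size();
  int n = 0;
  for (int s : group_sizes) n += s;
  std::vector<int> bin(g);
  int cur = 0, cur_size = 0, assigned = 0;
  double desired = (double)n / q;
  for (int i = 0; i < g; ++i) {
    int s = group_sizes[i];
    if (cur_size > 0 && cur < q - 1 &&
        std::fabs(cur_size + s - desired) >= std::fabs(cur_size - desired)) {
      ++cur;
      cur_size = 0;
      desired = (double)(n - assigned) / (q - cur);
    }
    bin[i] = cur;
    cur_size += s;
    assigned += s;
  }
  return bin;
}

// Best mutual information over partitions of the clump sequence into
// exactly l columns, for l = 1..p_max.  cnt: clumps x q row-count matrix.
// Mutual information is additive over columns, so the column gain
// g(s, t) for a column covering clumps (s, t] is precomputed (with an
// x*log(x) lookup table -- no log calls in the DP) and the DP itself is
// pure table lookups.
static std::vector<double> optimize_axis(const std::vector<std::vector<int>>& cnt,
                                         int q, int p_max, int n) {
  const int K = (int)cnt.size();
  // cumulative per-row counts over clump prefixes, flat layout
  std::vector<int> cum((size_t)(K + 1) * q, 0);
  std::vector<int> tot(K + 1, 0);
  for (int t = 1; t <= K; ++t) {
    tot[t] = tot[t - 1];
    const std::vector<int>& row = cnt[t - 1];
    for (int r = 0; r < q; ++r) {
      cum[(size_t)t * q + r] = cum[(size_t)(t - 1) * q + r] + row[r];
      tot[t] += row[r];
    }
  }
  // x*log(x) table over all possible counts
  std::vector<double> xlogx(n + 1);
  xlogx[0] = 0.0;
  for (int v = 1; v <= n; ++v) xlogx[v] = v * std::log((double)v);
  std::vector<double> logRow(q, 0.0);
  for (int r = 0; r < q; ++r) {
    int nr = cum[(size_t)K * q + r];
    logRow[r] = nr > 0 ? std::log((double)nr) : 0.0;
  }
  const double logn = std::log((double)n);

  // g[s*(K+1)+t]: MI contribution of a column covering clumps (s, t]
  std::vector<double> g((size_t)(K + 1) * (K + 1), 0.0);
  for (int s = 0; s < K; ++s) {
    const int* cs = &cum[(size_t)s * q];
    for (int t = s + 1; t <= K; ++t) {
      const int* ct = &cum[(size_t)t * q];
      int nc = tot[t] - tot[s];
      double acc = 0.0;
      for (int r = 0; r < q; ++r) {
        int ncr = ct[r] - cs[r];
        acc += xlogx[ncr] - ncr * logRow[r];
      }
      acc += nc * logn - xlogx[nc];
      g[(size_t)s * (K + 1) + t] = acc / n;
    }
  }

  const double NEG = -1e300;
  int L = std::min(p_max, K);
  std::vector<double> prev(K + 1, NEG), curr(K + 1, NEG);
  std::vector<double> out(p_max + 1, 0.0);
  for (int t = 1; t <= K; ++t) prev[t] = g[t];  // s = 0
  out[1] = prev[K];
  for (int l = 2; l <= L; ++l) {
    std::fill(curr.begin(), curr.end(), NEG);
    for (int t = l; t <= K; ++t) {
      double b = NEG;
      for (int s = l - 1; s < t; ++s) {
        double v = prev[s] + g[(size_t)s * (K + 1) + t];
        if (v > b) b = v;
      }
      curr[t] = b;
    }
    out[l] = curr[K] > NEG / 2 ? curr[K] : 0.0;
    std::swap(prev, curr);
  }
  return out;
}

// Build clump row-count matrix for DP: points sorted by the partitioned
// axis, rows from the equipartitioned axis.  Tie groups on the partitioned
// axis are never split; adjacent pure same-row groups merge into clumps;
// if more than c*p clumps remain they are merged into superclumps.
static std::vector<std::vector<int>> build_clumps(
    const std::vector<double>& xv, const std::vector<int>& row, int q,
    int p_max, double c) {
  const int n = (int)xv.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xv[a] < xv[b]; });

  // tie groups of identical x, each with per-row counts
  std::vector<std::vector<int>> groups;
  int i = 0;
  while (i < n) {
    int j = i;
    std::vector<int> cnt(q, 0);
    while (j < n && xv[ord[j]] == xv[ord[i]]) {
      ++cnt[row[ord[j]]];
      ++j;
    }
    groups.push_back(cnt);
    i = j;
  }

  // merge adjacent groups that are pure in the same row
  std::vector<std::vector<int>> clumps;
  auto pure_row = [&](const std::vector<int>& cnt) {
    int r = -1;
    for (int k = 0; k < q; ++k)
      if (cnt[k] > 0) {
        if (r >= 0) return -2;
        r = k;
      }
    return r;
  };
  for (auto& gvec : groups) {
    if (!clumps.empty()) {
      int r1 = pure_row(clumps.back()), r2 = pure_row(gvec);
      if (r1 >= 0 && r1 == r2) {
        clumps.back()[r1] += gvec[r1];
        continue;
      }
    }
    clumps.push_back(gvec);
  }

  int limit = std::max(2, (int)(c * p_max));
  if ((int)clumps.size() > limit) {
    std::vector<int> sizes(clumps.size());
    for (size_t t = 0; t < clumps.size(); ++t) {
      int s = 0;
      for (int r = 0; r < q; ++r) s += clumps[t][r];
      sizes[t] = s;
    }
    std::vector<int> bin = equipartition(sizes, limit);
    std::vector<std::vector<int>> sup(bin.back() + 1, std::vector<int>(q, 0));
    for (size_t t = 0; t < clumps.size(); ++t)
      for (int r = 0; r < q; ++r) sup[bin[t]][r] += clumps[t][r];
    return sup;
  }
  return clumps;
}

// one orientation: equipartition yv into q rows, optimize xv into <= p cols
static void scan_orientation(const std::vector<double>& xv,
                             const std::vector<double>& yv, int B, double c,
                             double& best) {
  const int n = (int)xv.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return yv[a] < yv[b]; });

  for (int q = 2; q <= B / 2; ++q) {
    int p_max = B / q;
    if (p_max < 2) break;

    // tie groups along y
    std::vector<int> gsize;
    std::vector<int> gidx(n);
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && yv[ord[j]] == yv[ord[i]]) ++j;
      for (int t = i; t < j; ++t) gidx[ord[t]] = (int)gsize.size();
      gsize.push_back(j - i);
      i = j;
    }
    if ((int)gsize.size() < 2) return;  // constant y: MI is 0
    std::vector<int> gbin = equipartition(gsize, q);
    int q_eff = gbin.back() + 1;
    if (q_eff < 2) continue;
    std::vector<int> row(n);
    for (int t = 0; t < n; ++t) row[t] = gbin[gidx[t]];

    std::vector<std::vector<int>> clumps = build_clumps(xv, row, q_eff, p_max, c);
    std::vector<double> I = optimize_axis(clumps, q_eff, p_max, n);
    for (int l = 2; l <= p_max; ++l) {
      double denom = std::log((double)std::min(l, q));
      double v = I[l] / denom;
      if (v > best) best = v;
    }
  }
}

// [[Rcpp::export(name = ".mic_cpp")]]
double mic_cpp(NumericVector x, NumericVector y, double alpha, double c) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  int B = (int)std::floor(std::pow((double)n, alpha));
  if (B < 4) stop("sample too small for the requested grid budget");
  double best = 0.0;
  scan_orientation(xv, yv, B, c, best);
  scan_orientation(yv, xv, B, c, best);
  if (best > 1.0) best = 1.0;  // guard tiny numerical overshoot
  return best;
}
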