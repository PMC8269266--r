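// Maximal information coefficient (classic MINE approximation) and a
// nearest-taxon distance kernel for the betaMNTD null model.
//
// The MIC search follows the original scheme: for each grid shape
// (nx, ny) with nx * ny <= n^alpha, the finer axis is equipartitioned
// into ny rows (ties kept together) and the column partition is
// optimized by dynamic programming over clump boundaries, with clumps
// capped at c * nx superclumps. The DP maximizes the per-column additive
// decomposition of H(P) - H(P,Q), which equals I(P;Q) - H(Q) up to the
// constant H(Q), so it is equivalent to maximizing mutual information.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double xlogx(double p) {
  return p > 0.0 ? p * std::log(p) : 0.0;
}

// assign sorted values to ng groups of near-equal size, ties together
static void equipartition(const std::vector<double>& v, int ng,
                          std::vector<int>& grp) {
  int n = (int)v.size();
  grp.assign(n, 0);
  int i = 0, curr = 0;
  double h = 0.0, target = (double)n / ng;
  while (i < n) {
    int s = 1;
    while (i + s < n && v[i + s] == v[i]) s++;
    if (h != 0.0 && curr < ng - 1) {
      if (std::fabs(h + s - target) >= std::fabs(h - target)) {
        curr++;
        h = 0.0;
        target = (double)(n - i) / (ng - curr);
      }
    }
    for (int k = 0; k < s; k++) grp[i + k] = curr;
    i += s;
    h += s;
  }
}

// best normalized score for one orientation: rows from `ry`
// (equipartitioned), columns optimized along `cx`
static void mic_orientation(const std::vector<double>& cx,
                            const std::vector<double>& ry,
                            int B, double ccoef, double& best) {
  int n = (int)cx.size();
  std::vector<int> ordc(n), ordr(n);
  for (int i = 0; i < n; i++) ordc[i] = ordr[i] = i;
  std::sort(ordc.begin(), ordc.end(),
            [&](int a, int b) { return cx[a] < cx[b]; });
  std::sort(ordr.begin(), ordr.end(),
            [&](int a, int b) { return ry[a] < ry[b]; });
  std::vector<double> rsorted(n);
  for (int i = 0; i < n; i++) rsorted[i] = ry[ordr[i]];

  for (int ny = 2; ny <= B / 2; ny++) {
    int nx_max = B / ny;
    if (nx_max < 2) break;
    std::vector<int> grp;
    equipartition(rsorted, ny, grp);
    std::vector<int> rowOf(n);
    for (int i = 0; i < n; i++) rowOf[ordr[i]] = grp[i];

    // atomic groups: runs of equal column-axis value; row id or -1 if
    // mixed
    std::vector<int> gsize, grow;
    {
      int i = 0;
      while (i < n) {
        int s = 1;
        int r = rowOf[ordc[i]];
        bool pure = true;
        while (i + s < n && cx[ordc[i + s]] == cx[ordc[i]]) {
          if (rowOf[ordc[i + s]] != r) pure = false;
          s++;
        }
        gsize.push_back(s);
        grow.push_back(pure ? r : -1);
        i += s;
      }
    }
    // clumps: merge consecutive pure groups sharing a row
    std::vector<std::vector<int>> clump; // per-clump row histogram
    {
      int i = 0, ng = (int)gsize.size(), pos = 0;
      while (i < ng) {
        std::vector<int> hist(ny, 0);
        int r = grow[i];
        // fill histogram for group i
        for (int k = 0; k < gsize[i]; k++)
          hist[rowOf[ordc[pos + k]]]++;
        pos += gsize[i];
        int j = i + 1;
        while (r >= 0 && j < ng && grow[j] == r) {
          for (int k = 0; k < gsize[j]; k++)
            hist[rowOf[ordc[pos + k]]]++;
          pos += gsize[j];
          j++;
        }
        clump.push_back(hist);
        i = j;
      }
    }
    int k = (int)clump.size();
    if (k < 2) continue;

    // cap at c * nx superclumps (boundaries only at clump edges)
    int khat = std::max(2, (int)(ccoef * nx_max));
    if (k > khat) {
      std::vector<std::vector<int>> sc;
      int i = 0, curr = 0;
      double h = 0.0;
      int placed = 0;
      double target = (double)n / khat;
      std::vector<int> acc(ny, 0);
      bool accEmpty = true;
      while (i < k) {
        int s = 0;
        for (int r = 0; r < ny; r++) s += clump[i][r];
        if (!accEmpty && curr < khat - 1 &&
            std::fabs(h + s - target) >= std::fabs(h - target)) {
          sc.push_back(acc);
          acc.assign(ny, 0);
          accEmpty = true;
          curr++;
          h = 0.0;
          target = (double)(n - placed) / (khat - curr);
        }
        for (int r = 0; r < ny; r++) acc[r] += clump[i][r];
        accEmpty = false;
        h += s;
        placed += s;
        i++;
      }
      if (!accEmpty) sc.push_back(acc);
      clump = sc;
      k = (int)clump.size();
      if (k < 2) continue;
    }

    // cumulative row counts over clump prefixes
    std::vector<std::vector<double>> cum(k + 1,
                                         std::vector<double>(ny, 0.0));
    std::vector<double> tot(k + 1, 0.0);
    for (int t = 1; t <= k; t++) {
      for (int r = 0; r < ny; r++) {
        cum[t][r] = cum[t - 1][r] + clump[t - 1][r];
        tot[t] += cum[t][r];
      }
    }
    double HQ = 0.0;
    for (int r = 0; r < ny; r++) HQ -= xlogx(cum[k][r] / n);

    // per-column contribution g(s, t] = -p log p + sum_r p_r log p_r
    std::vector<std::vector<double>> g(k + 1,
                                       std::vector<double>(k + 1, 0.0));
    for (int s = 0; s < k; s++) {
      for (int t = s + 1; t <= k; t++) {
        double nm = tot[t] - tot[s];
        double val = -xlogx(nm / n);
        for (int r = 0; r < ny; r++)
          val += xlogx((cum[t][r] - cum[s][r]) / n);
        g[s][t] = val;
      }
    }

    int lmax = std::min(nx_max, k);
    std::vector<double> Fprev(k + 1), Fcurr(k + 1);
    for (int t = 1; t <= k; t++) Fprev[t] = g[0][t];
    for (int l = 2; l <= lmax; l++) {
      for (int t = l; t <= k; t++) {
        double mx = R_NegInf;
        for (int s = l - 1; s < t; s++) {
          double v = Fprev[s] + g[s][t];
          if (v > mx) mx = v;
        }
        Fcurr[t] = mx;
      }
      double inats = HQ + Fcurr[k];
      if (inats > 0.0) {
        double score = inats / std::log((double)std::min(l, ny));
        if (score > best) best = score;
      }
      std::swap(Fprev, Fcurr);
    }
  }
}

// [[Rcpp::export]]
double mic_cpp(NumericVector xr, NumericVector yr, double alpha,
               double ccoef) {
  int n = xr.size();
  if (n != yr.size()) stop("x and y must have equal length");
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
  int B = (int)std::floor(std::pow((double)n, alpha));
  if (B < 4) B = 4;
  double best = 0.0;
  mic_orientation(x, y, B, ccoef, best);
  mic_orientation(y, x, B, ccoef, best);
  if (best > 1.0) best = 1.0;
  return best;
}

// nearest-taxon distances: out[i, s] = min over j in presence[[s]] of
// d[perm[i], perm[j]] (perm relabels taxa for the phylogeny-shuffling
// null; indices 1-based from R)
// [[Rcpp::export]]
NumericMatrix min_dist_cols(NumericMatrix d, List presence,
                            IntegerVector perm) {
  int n = d.nrow(), ns = presence.size();
  NumericMatrix out(n, ns);
  for (int s = 0; s < ns; s++) {
    IntegerVector idx = presence[s];
    int k = idx.size();
    std::vector<int> cols(k);
    for (int j = 0; j < k; j++) cols[j] = perm[idx[j] - 1] - 1;
    for (int i = 0; i < n; i++) {
      int ri = perm[i] - 1;
      double m = R_PosInf;
      for (int j = 0; j < k; j++) {
        double v = d(ri, cols[j]);
        if (v < m) m = v;
      }
      out(i, s) = m;
    }
  }
  return out;
}
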