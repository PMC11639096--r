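// Compiled kernels for the per-sample feature extractors: rank-based
// boundary (insulation) scoring, arrowhead corner scoring for contact
// domains, and local-neighborhood expected models for loop calling.
// Matrices arrive dense and symmetric with NA on masked bins.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline bool ok(double x) { return !ISNAN(x); }

// Mann-Whitney U of set1 (expected larger) vs set2, ties counted 1/2,
// normal approximation without continuity correction.
static double mw_z(const std::vector<double>& s1,
                   const std::vector<double>& s2) {
  const double n1 = (double)s1.size(), n2 = (double)s2.size();
  double U = 0.0;
  for (double a : s1)
    for (double b : s2) {
      if (a > b) U += 1.0;
      else if (a == b) U += 0.5;
    }
  return (U - n1 * n2 / 2.0) / std::sqrt(n1 * n2 * (n1 + n2 + 1.0) / 12.0);
}

// Boundary scores at every inter-bin edge.  Edge t (0-based, between bins t
// and t+1) is scored for each window w in [wmin, wmax] fully inside the
// chromosome; per distance d the within-left/right pair sets are rank-
// compared against the distance-matched cross set, per-d Z scores are
// Stouffer-combined over d with 1/sqrt(w), and the edge keeps the maximum
// over windows.  Returns (n-1) x 4: leftZ, rightZ, combinedZ, best window.
// [[Rcpp::export]]
NumericMatrix boundary_scores_cpp(NumericMatrix M, int wmin, int wmax) {
  const int n = M.nrow();
  NumericMatrix out(n - 1, 4);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> s1, s2, sl, sr;

  for (int t = 0; t < n - 1; ++t) {
    double bestC = NA_REAL, bestL = NA_REAL, bestR = NA_REAL;
    double bestW = NA_REAL;
    for (int w = wmin; w <= wmax; ++w) {
      if (t - w + 1 < 0 || t + w > n - 1) continue;
      double zC = 0.0, zL = 0.0, zR = 0.0;
      int nC = 0, nL = 0, nR = 0;
      for (int d = 1; d <= w; ++d) {
        s1.clear(); s2.clear(); sl.clear(); sr.clear();
        for (int p = t - w + 1; p + d <= t; ++p) {          // within-left
          double v = M(p, p + d);
          if (ok(v)) { s1.push_back(v); sl.push_back(v); }
        }
        for (int p = t + 1; p + d <= t + w; ++p) {          // within-right
          double v = M(p, p + d);
          if (ok(v)) { s1.push_back(v); sr.push_back(v); }
        }
        int plo = std::max(t - d + 1, t - w + 1);
        int phi = std::min(t, t + w - d);
        for (int p = plo; p <= phi; ++p) {                  // cross
          double v = M(p, p + d);
          if (ok(v)) s2.push_back(v);
        }
        if (s2.size() >= 2) {
          if (s1.size() >= 2) { zC += mw_z(s1, s2); ++nC; }
          if (sl.size() >= 2) { zL += mw_z(sl, s2); ++nL; }
          if (sr.size() >= 2) { zR += mw_z(sr, s2); ++nR; }
        }
      }
      double sw = std::sqrt((double)w);
      if (nC > 0) {
        double sc = zC / sw;
        if (ISNAN(bestC) || sc > bestC) { bestC = sc; bestW = w; }
      }
      if (nL > 0) { double sc = zL / sw; if (ISNAN(bestL) || sc > bestL) bestL = sc; }
      if (nR > 0) { double sc = zR / sw; if (ISNAN(bestR) || sc > bestR) bestR = sc; }
    }
    out(t, 0) = bestL; out(t, 1) = bestR; out(t, 2) = bestC; out(t, 3) = bestW;
  }
  return out;
}

// Arrowhead transform A(i, i+d) = (M(i,i-d) - M(i,i+d)) /
// (M(i,i-d) + M(i,i+d)); NA when out of range or masked, 0 when both 0.
static double arrowhead_at(const NumericMatrix& M, int i, int d) {
  const int n = M.nrow();
  if (i - d < 0 || i + d >= n) return NA_REAL;
  double up = M(i - d, i), dn = M(i, i + d);
  if (ISNAN(up) || ISNAN(dn)) return NA_REAL;
  double s = up + dn;
  if (s == 0.0) return 0.0;
  return (up - dn) / s;
}

// [[Rcpp::export]]
NumericMatrix arrowhead_matrix_cpp(NumericMatrix M, int dmax) {
  const int n = M.nrow();
  NumericMatrix A(n, dmax + 1);
  std::fill(A.begin(), A.end(), NA_REAL);
  for (int i = 0; i < n; ++i)
    for (int d = 1; d <= dmax; ++d)
      A(i, d) = arrowhead_at(M, i, d);
  return A;
}

// Corner score for candidate domain [a, b] (0-based inclusive bins):
// mean of A(i, i+d) over pixels whose mirror lies inside the domain but
// whose forward pixel crosses b, minus the mean over pixels inside the
// domain whose mirror crosses a.  NA when either pixel set is empty.
static double corner_from_A(const NumericMatrix& A, int a, int b) {
  double s1 = 0.0, s2 = 0.0;
  int c1 = 0, c2 = 0;
  const int dmax = A.ncol() - 1;
  for (int i = a; i <= b; ++i) {
    // set 1: i+d > b, i-d >= a  ->  d in [b-i+1, i-a]
    int lo = b - i + 1, hi = std::min(i - a, dmax);
    for (int d = std::max(lo, 1); d <= hi; ++d) {
      double v = A(i, d);
      if (ok(v)) { s1 += v; ++c1; }
    }
    // set 2: i+d <= b, i-d < a  ->  d in [i-a+1, b-i]
    lo = i - a + 1; hi = std::min(b - i, dmax);
    for (int d = std::max(lo, 1); d <= hi; ++d) {
      double v = A(i, d);
      if (ok(v)) { s2 += v; ++c2; }
    }
  }
  if (c1 == 0 || c2 == 0) return NA_REAL;
  return s1 / c1 - s2 / c2;
}

// [[Rcpp::export]]
double corner_score_cpp(NumericMatrix M, int a, int b) {
  int L = b - a;
  NumericMatrix A = arrowhead_matrix_cpp(M, L);
  return corner_from_A(A, a, b);
}

// Score every candidate (a, b) with Lmin <= b - a <= Lmax.
// Returns ncand x 3 (a, b, S) including NA scores.
// [[Rcpp::export]]
NumericMatrix corner_scan_cpp(NumericMatrix M, int Lmin, int Lmax) {
  const int n = M.nrow();
  NumericMatrix A = arrowhead_matrix_cpp(M, std::min(Lmax, n - 1));
  std::vector<double> va, vb, vs;
  for (int a = 0; a < n; ++a) {
    for (int L = Lmin; L <= Lmax; ++L) {
      int b = a + L;
      if (b >= n) break;
      double s = corner_from_A(A, a, b);
      va.push_back((double)a); vb.push_back((double)b); vs.push_back(s);
    }
  }
  NumericMatrix out(va.size(), 3);
  for (size_t r = 0; r < va.size(); ++r) {
    out(r, 0) = va[r]; out(r, 1) = vb[r]; out(r, 2) = vs[r];
  }
  return out;
}

// Local expected models for loop candidate pixels.  For each candidate
// (i, j) the four neighborhoods (donut ring, lower-left quadrant,
// horizontal stripe, vertical stripe; all excluding the p-box) are summed
// over balanced values and distance-expected values, and
// lambda_N = e(|i-j|) * sum(M) / sum(e).  Returns ncand x 5:
// observed, donut, lower-left, horizontal, vertical (NA where undefined).
// [[Rcpp::export]]
NumericMatrix loop_stats_cpp(NumericMatrix M, NumericVector evec,
                             IntegerVector iidx, IntegerVector jidx,
                             int p, int w) {
  const int n = M.nrow();
  const int m = iidx.size();
  NumericMatrix out(m, 5);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int c = 0; c < m; ++c) {
    int i = iidx[c], j = jidx[c];
    double obs = M(i, j);
    out(c, 0) = obs;
    double ed = evec[std::abs(j - i)];
    if (!ok(ed) || ed <= 0.0) continue;
    double sm[4] = {0, 0, 0, 0}, se[4] = {0, 0, 0, 0};
    int cnt[4] = {0, 0, 0, 0};
    for (int di = -w; di <= w; ++di) {
      for (int dj = -w; dj <= w; ++dj) {
        int x = i + di, y = j + dj;
        if (x < 0 || y < 0 || x >= n || y >= n || x == y) continue;
        int box = std::max(std::abs(di), std::abs(dj));
        if (box <= p) continue;                        // p-box excluded
        double v = M(x, y);
        double e = evec[std::abs(y - x)];
        if (!ok(v) || !ok(e)) continue;
        bool memb[4];
        memb[0] = true;                                // donut ring
        memb[1] = (di >= 1 && dj <= -1);               // lower-left quadrant
        memb[2] = (std::abs(di) <= 1 && std::abs(dj) > p);   // horizontal
        memb[3] = (std::abs(dj) <= 1 && std::abs(di) > p);   // vertical
        for (int k = 0; k < 4; ++k)
          if (memb[k]) { sm[k] += v; se[k] += e; ++cnt[k]; }
      }
    }
    for (int k = 0; k < 4; ++k)
      if (cnt[k] > 0 && se[k] > 0.0)
        out(c, k + 1) = ed * sm[k] / se[k];
  }
  return out;
}
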