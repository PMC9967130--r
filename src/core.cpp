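#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Banded dynamic time warping between two equally-binned signals.
// Local cost |x_i - y_j|; steps diagonal/up/left; Sakoe-Chiba band in bins.
// Returns the optimal path as a 2-column (i, j) 1-based integer matrix.
// [[Rcpp::export(name = ".dtw_band_path")]]
IntegerMatrix dtw_band_path(NumericVector x, NumericVector y, int band) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty signal in DTW");
  const double INF = R_PosInf;
  // cumulative cost, row-major (n+1) x (m+1), 1-based cells
  std::vector<double> D((size_t)(n + 1) * (m + 1), INF);
  auto at = [m](int i, int j) -> size_t { return (size_t)i * (m + 1) + j; };
  D[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::fabs(x[i - 1] - y[j - 1]);
      double best = D[at(i - 1, j - 1)];
      if (D[at(i - 1, j)] < best) best = D[at(i - 1, j)];
      if (D[at(i, j - 1)] < best) best = D[at(i, j - 1)];
      D[at(i, j)] = c + best;
    }
  }
  if (!R_FINITE(D[at(n, m)])) stop("no DTW path inside band; widen band_s");
  // backtrack
  std::vector<int> pi, pj;
  int i = n, j = m;
  pi.push_back(i); pj.push_back(j);
  while (i > 1 || j > 1) {
    double d_diag = (i > 1 && j > 1) ? D[at(i - 1, j - 1)] : R_PosInf;
    double d_up   = (i > 1) ? D[at(i - 1, j)] : R_PosInf;
    double d_left = (j > 1) ? D[at(i, j - 1)] : R_PosInf;
    if (d_diag <= d_up && d_diag <= d_left) { --i; --j; }
    else if (d_up <= d_left) { --i; }
    else { --j; }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return path;
}

// Ion-current extraction for a set of frame targets against one aligned run.
// scan_rt: aligned MS1 scan RTs, ascending. peak_* sorted by m/z; peak_scan is
// a 0-based index into scan_rt. For every MS1 scan inside the RT window the
// trace takes the most intense peak inside the m/z window (0 if none); the
// area is the trapezoidal integral of that trace. A window holding a single
// scan uses area = intensity * cycle_s.
// Returns T x 2 matrix: area, apex RT (NA if trace all zero).
// [[Rcpp::export(name = ".extract_frames_run")]]
NumericMatrix extract_frames_run(NumericVector scan_rt,
                                 IntegerVector peak_scan,
                                 NumericVector peak_mz,
                                 NumericVector peak_int,
                                 NumericVector mz_lo, NumericVector mz_hi,
                                 NumericVector rt_lo, NumericVector rt_hi,
                                 double cycle_s) {
  const int S = scan_rt.size(), T = mz_lo.size(), P = peak_mz.size();
  NumericMatrix out(T, 2);
  std::fill(out.begin(), out.end(), 0.0);
  const double *mzp = REAL(peak_mz);
  for (int t = 0; t < T; ++t) {
    // scan range inside RT window (closed)
    int s0 = std::lower_bound(scan_rt.begin(), scan_rt.end(), rt_lo[t]) - scan_rt.begin();
    int s1 = std::upper_bound(scan_rt.begin(), scan_rt.end(), rt_hi[t]) - scan_rt.begin() - 1;
    if (s0 >= S || s1 < s0) { out(t, 1) = NA_REAL; continue; }
    const int W = s1 - s0 + 1;
    std::vector<double> trace(W, 0.0);
    // peak range inside m/z window (closed)
    int p0 = std::lower_bound(mzp, mzp + P, mz_lo[t]) - mzp;
    int p1 = std::upper_bound(mzp, mzp + P, mz_hi[t]) - mzp;
    for (int p = p0; p < p1; ++p) {
      int s = peak_scan[p];
      if (s < s0 || s > s1) continue;
      if (peak_int[p] > trace[s - s0]) trace[s - s0] = peak_int[p];
    }
    double area = 0.0, apex = -1.0, apex_rt = NA_REAL;
    if (W == 1) {
      area = trace[0] * cycle_s;
    } else {
      for (int k = 0; k + 1 < W; ++k)
        area += 0.5 * (trace[k] + trace[k + 1]) * (scan_rt[s0 + k + 1] - scan_rt[s0 + k]);
    }
    for (int k = 0; k < W; ++k)
      if (trace[k] > apex) { apex = trace[k]; apex_rt = scan_rt[s0 + k]; }
    out(t, 0) = area;
    out(t, 1) = (apex > 0.0) ? apex_rt : NA_REAL;
  }
  return out;
}
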