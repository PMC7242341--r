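#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Distance between trajectory rows i and j.
// norm: 0 = euclidean, 1 = chebyshev, 2 = manhattan
static inline double row_dist(const double* T, int n, int m,
                              int i, int j, int norm) {
  double acc = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = std::fabs(T[i + (std::size_t)k * n] -
                         T[j + (std::size_t)k * n]);
    if (norm == 0) acc += d * d;
    else if (norm == 1) { if (d > acc) acc = d; }
    else acc += d;
  }
  return norm == 0 ? std::sqrt(acc) : acc;
}

// Off-diagonal recurrence rate of the trajectory at radius eps.
// [[Rcpp::export(name = ".cppRecurrenceRate")]]
double cpp_recurrence_rate(NumericMatrix traj, double eps, int norm) {
  int n = traj.nrow(), m = traj.ncol();
  const double* T = REAL(traj);
  long long cnt = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (row_dist(T, n, m, i, j, norm) <= eps) ++cnt;
  return (2.0 * cnt) / ((double)n * (n - 1));
}

// Largest pairwise distance (used to bracket radius calibration) and a
// flag for a zero-diameter (degenerate) trajectory.
// [[Rcpp::export(name = ".cppMaxPairDist")]]
double cpp_max_pair_dist(NumericMatrix traj, int norm) {
  int n = traj.nrow(), m = traj.ncol();
  const double* T = REAL(traj);
  double mx = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = row_dist(T, n, m, i, j, norm);
      if (d > mx) mx = d;
    }
  return mx;
}

// Matrix-free RQA line statistics computed directly from the trajectory.
// Diagonal statistics exclude offsets |i-j| < theiler_w (the line of
// identity is always excluded); vertical statistics use the full matrix
// including the LOI. Returns NA for measures with no qualifying line.
// [[Rcpp::export(name = ".cppRqaStats")]]
List cpp_rqa_stats(NumericMatrix traj, double eps, int norm,
                   int theiler_w, int lmin, int vmin) {
  int n = traj.nrow(), m = traj.ncol();
  const double* T = REAL(traj);

  int kmin = theiler_w < 1 ? 1 : theiler_w;
  double lmax = 0.0, lsum = 0.0;
  long long lcount = 0, diagPts = 0, diagPtsLong = 0;
  for (int k = kmin; k < n; ++k) {          // one triangle; ratios unchanged
    int run = 0;
    for (int t = 0; t <= n - 1 - k; ++t) {
      bool rec = row_dist(T, n, m, t, t + k, norm) <= eps;
      if (rec) { ++run; ++diagPts; }
      if ((!rec || t == n - 1 - k) && run > 0) {
        if (run >= lmin) {
          if (run > lmax) lmax = run;
          lsum += run; ++lcount; diagPtsLong += run;
        }
        run = 0;
      }
    }
  }

  double vsum = 0.0;
  long long vcount = 0, recPts = 0, vertPtsLong = 0;
  for (int j = 0; j < n; ++j) {
    int run = 0;
    for (int i = 0; i < n; ++i) {
      bool rec = (i == j) || row_dist(T, n, m, i, j, norm) <= eps;
      if (rec) { ++run; ++recPts; }
      if ((!rec || i == n - 1) && run > 0) {
        if (run >= vmin) { vsum += run; ++vcount; vertPtsLong += run; }
        run = 0;
      }
    }
  }

  double rr = (double)(recPts - n) / ((double)n * (n - 1));
  return List::create(
    _["lmax"]  = lcount ? lmax : 0.0,
    _["lmean"] = lcount ? lsum / lcount : NA_REAL,
    _["tt"]    = vcount ? vsum / vcount : NA_REAL,
    _["det"]   = diagPts ? (double)diagPtsLong / diagPts : NA_REAL,
    _["lam"]   = recPts ? (double)vertPtsLong / recPts : NA_REAL,
    _["rr"]    = rr);
}

// Sample entropy template counts: B = pairs (i < j) of length-m templates
// within Chebyshev distance r, A = same for length m+1; templates indexed
// over 0..n-m-1 so A and B range over the same pairs (no self-matches).
// [[Rcpp::export(name = ".cppSampEnCounts")]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;              // number of (m+1)-length templates
  const double* v = REAL(x);
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool okm = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(v[i + k] - v[j + k]) > r) { okm = false; break; }
      }
      if (!okm) continue;
      ++B;
      if (std::fabs(v[i + m] - v[j + m]) <= r) ++A;
    }
  }
  return NumericVector::create((double)A, (double)B);
}
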