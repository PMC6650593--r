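#include <Rcpp.h>
using namespace Rcpp;

// Local similarity dynamic program over the band |i - j| <= D.
//
// Two running chains per diagonal: a positive partial sum
//   P(i,j) = max(0, P(i-1,j-1) + x_i * y_j)
// and a negative one
//   N(i,j) = max(0, N(i-1,j-1) - x_i * y_j).
// The local similarity score is the grand maximum over both, divided by n.
// Delay d = j - i (positive: y lags x). Ties are resolved by scanning
// delays in the order 0, +1, -1, +2, -2, ... and, within a cell, the
// positive chain before the negative one; replacement requires a strictly
// larger raw score, so the first-found optimum wins (smaller |delay|,
// then positive sign, then earliest alignment start).

struct LsBest {
  double raw;     // unnormalised best partial sum
  int sign;       // +1 or -1
  int delay;      // j - i
  int start_x;    // 1-based start index in x
  int start_y;    // 1-based start index in y
  int len;        // chain length
};

static LsBest ls_core(const double* x, const double* y, int n, int D) {
  LsBest best = {0.0, 1, 0, 1, 1, 0};
  for (int a = 0; a <= 2 * D; ++a) {
    int d = (a % 2 == 1) ? (a + 1) / 2 : -(a / 2);  // 0, +1, -1, +2, -2, ...
    // x index i runs so that j = i + d stays in [0, n-1] (0-based here)
    int i0 = (d >= 0) ? 0 : -d;
    int i1 = (d >= 0) ? (n - 1 - d) : (n - 1);
    double P = 0.0, N = 0.0;
    int lenP = 0, lenN = 0;
    for (int i = i0; i <= i1; ++i) {
      double prod = x[i] * y[i + d];
      P += prod;
      if (P <= 0.0) { P = 0.0; lenP = 0; } else { ++lenP; }
      N -= prod;
      if (N <= 0.0) { N = 0.0; lenN = 0; } else { ++lenN; }
      if (P > best.raw) {
        best.raw = P; best.sign = 1; best.delay = d;
        best.len = lenP; best.start_x = i - lenP + 2; best.start_y = i + d - lenP + 2;
      }
      if (N > best.raw) {
        best.raw = N; best.sign = -1; best.delay = d;
        best.len = lenN; best.start_x = i - lenN + 2; best.start_y = i + d - lenN + 2;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List ls_dp_cpp(NumericVector x, NumericVector y, int D) {
  int n = x.size();
  if (y.size() != n) stop("series must have equal length");
  if (D >= n) stop("delay limit D must be smaller than the series length");
  if (D < 0) stop("delay limit D must be non-negative");
  LsBest b = ls_core(x.begin(), y.begin(), n, D);
  return List::create(
    _["ls"] = b.raw / n,
    _["sign"] = b.sign,
    _["delay"] = b.delay,
    _["start_a"] = b.start_x,
    _["start_b"] = b.start_y,
    _["length"] = b.len);
}

// Count permutations whose raw score reaches the observed raw score.
// perms: n x n_perm matrix of 0-based index permutations applied to y.
// [[Rcpp::export]]
int ls_perm_count_cpp(NumericVector x, NumericVector y, int D,
                      IntegerMatrix perms, double obs_raw) {
  int n = x.size();
  if (y.size() != n || perms.nrow() != n) stop("dimension mismatch");
  int nperm = perms.ncol();
  std::vector<double> yp(n);
  int count = 0;
  const double tol = 1e-9 * (1.0 + std::fabs(obs_raw));
  for (int k = 0; k < nperm; ++k) {
    for (int i = 0; i < n; ++i) yp[i] = y[perms(i, k)];
    LsBest b = ls_core(x.begin(), &yp[0], n, D);
    if (b.raw >= obs_raw - tol) ++count;
  }
  return count;
}
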