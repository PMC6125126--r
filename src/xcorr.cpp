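#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson correlation between a and b at integer-sample lag k, using the
// overlapping samples only: k >= 0 pairs a[i] with b[i+k]. Prefix sums give
// per-lag means/variances in O(1); the cross dot product is O(n - |k|).
static double pearson_at_lag(const double* a, const double* b, int n,
                             const std::vector<double>& ca,
                             const std::vector<double>& caa,
                             const std::vector<double>& cb,
                             const std::vector<double>& cbb,
                             int k) {
  int len = n - std::abs(k);
  if (len < 3) return NA_REAL;
  int ia = (k >= 0) ? 0 : -k;  // start index into a
  int ib = (k >= 0) ? k : 0;   // start index into b
  const double* pa = a + ia;
  const double* pb = b + ib;
  double d0 = 0.0, d1 = 0.0, d2 = 0.0, d3 = 0.0;
  int i = 0;
  for (; i + 4 <= len; i += 4) {
    d0 += pa[i] * pb[i];
    d1 += pa[i + 1] * pb[i + 1];
    d2 += pa[i + 2] * pb[i + 2];
    d3 += pa[i + 3] * pb[i + 3];
  }
  double dot = d0 + d1 + d2 + d3;
  for (; i < len; ++i) dot += pa[i] * pb[i];
  double sa = ca[ia + len] - ca[ia];
  double saa = caa[ia + len] - caa[ia];
  double sb = cb[ib + len] - cb[ib];
  double sbb = cbb[ib + len] - cbb[ib];
  double num = dot - sa * sb / len;
  double va = saa - sa * sa / len;
  double vb = sbb - sb * sb / len;
  if (va <= 0.0 || vb <= 0.0) return NA_REAL;
  return num / std::sqrt(va * vb);
}

static void prefix_sums(const NumericVector& x, std::vector<double>& c,
                        std::vector<double>& cc) {
  int n = x.size();
  c.assign(n + 1, 0.0);
  cc.assign(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    c[i + 1] = c[i] + x[i];
    cc[i + 1] = cc[i] + x[i] * x[i];
  }
}

// [[Rcpp::export]]
List xcorr_pearson_cpp(NumericVector a, NumericVector b, int max_lag) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  if (max_lag >= n / 2) stop("max_lag must be below half the signal length");
  std::vector<double> ca, caa, cb, cbb;
  prefix_sums(a, ca, caa);
  prefix_sums(b, cb, cbb);
  int L = 2 * max_lag + 1;
  NumericVector r(L);
  IntegerVector lag(L);
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  for (int k = -max_lag; k <= max_lag; ++k) {
    lag[k + max_lag] = k;
    r[k + max_lag] = pearson_at_lag(pa, pb, n, ca, caa, cb, cbb, k);
  }
  return List::create(_["lag"] = lag, _["r"] = r);
}

// Peak of the trimmed Pearson cross-correlation over the lag window
// [shift - max_lag, shift + max_lag] for each (signed, in samples) shift:
// the linear-shift surrogate, with no wrap seam. Overlap shrinks with the
// shift magnitude, as it does for a physically shifted pair.
// [[Rcpp::export]]
NumericVector surrogate_peaks_linear_cpp(NumericVector a, NumericVector b,
                                         int max_lag, IntegerVector shifts) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  std::vector<double> ca, caa, cb, cbb;
  prefix_sums(a, ca, caa);
  prefix_sums(b, cb, cbb);
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  NumericVector out(shifts.size());
  for (int si = 0; si < shifts.size(); ++si) {
    int s = shifts[si];
    double best = R_NegInf;
    for (int k = s - max_lag; k <= s + max_lag; ++k) {
      if (std::abs(k) >= n - 2) continue;
      double r = pearson_at_lag(pa, pb, n, ca, caa, cb, cbb, k);
      if (!ISNAN(r) && r > best) best = r;
    }
    out[si] = best;
  }
  return out;
}

// Peak correlation values for circularly shifted copies of b. `shifts` are
// signed shifts in samples; shift s moves b[i] to position i + s (mod n).
// [[Rcpp::export]]
NumericVector surrogate_peaks_cpp(NumericVector a, NumericVector b,
                                  int max_lag, IntegerVector shifts) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  std::vector<double> ca, caa;
  prefix_sums(a, ca, caa);
  NumericVector out(shifts.size());
  NumericVector bs(n);
  std::vector<double> cb, cbb;
  const double* pa = REAL(a);
  for (int si = 0; si < shifts.size(); ++si) {
    int s = ((shifts[si] % n) + n) % n;
    for (int i = 0; i < n; ++i) bs[(i + s) % n] = b[i];
    prefix_sums(bs, cb, cbb);
    const double* pbs = REAL(bs);
    double best = R_NegInf;
    for (int k = -max_lag; k <= max_lag; ++k) {
      double r = pearson_at_lag(pa, pbs, n, ca, caa, cb, cbb, k);
      if (!ISNAN(r) && r > best) best = r;
    }
    out[si] = best;
  }
  return out;
}
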