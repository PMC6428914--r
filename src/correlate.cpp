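#include <Rcpp.h>
using namespace Rcpp;

// Symmetrically normalized fluctuation autocorrelation at a single integer lag:
//   G(k) = <x_i * x_{i+k}>_i / (<x_i>_i * <x_{i+k}>_i) - 1
// with all three means taken over the overlapping window i = 0 .. N-k-1.
// The per-lag (monitor) means reduce the finite-length bias that otherwise
// distorts correlation curves computed from short segments.
static double acf_at_lag(const double* x, int n, int k) {
  const int m = n - k;
  double sxy = 0.0, sx = 0.0, sy = 0.0;
  for (int i = 0; i < m; i++) {
    sx  += x[i];
    sy  += x[i + k];
    sxy += x[i] * x[i + k];
  }
  const double ml = sx / m, mr = sy / m;
  if (ml == 0.0 || mr == 0.0) return R_NaN; // dark window: undefined
  return (sxy / m) / (ml * mr) - 1.0;
}

// [[Rcpp::export]]
NumericVector acf_direct_cpp(NumericVector x, IntegerVector lags) {
  const int n = x.size();
  NumericVector out(lags.size());
  for (int j = 0; j < lags.size(); j++) {
    const int k = lags[j];
    if (k < 1 || k >= n) stop("lag out of range");
    out[j] = acf_at_lag(x.begin(), n, k);
  }
  return out;
}

// Multi-tau correlator: m lags per octave. Level 0 evaluates lags 1..2m at the
// native bin width; each further level halves the time resolution by pairwise
// rebinning (odd trailing bin dropped) and evaluates lags m+1..2m in rebinned
// units. The symmetric normalization is scale invariant under rebinning, so
// values line up with the direct estimator at shared lags.
// [[Rcpp::export]]
List acf_multitau_cpp(NumericVector x, int m, double max_lag_bins) {
  const int n = x.size();
  if (n < 2) stop("trace too short");
  if (m < 1) stop("m must be >= 1");

  std::vector<double> cur(x.begin(), x.end());
  std::vector<double> lags, vals;

  // level 0
  for (int k = 1; k <= 2 * m; k++) {
    if (k > max_lag_bins || k >= n) break;
    lags.push_back((double)k);
    vals.push_back(acf_at_lag(cur.data(), n, k));
  }

  double scale = 1.0;
  int ncur = n;
  while (true) {
    // pairwise rebin
    int nh = ncur / 2;
    if (nh < m + 2) break;
    for (int i = 0; i < nh; i++) cur[i] = cur[2 * i] + cur[2 * i + 1];
    ncur = nh;
    scale *= 2.0;
    bool any = false;
    for (int k = m + 1; k <= 2 * m; k++) {
      double lag = k * scale;
      if (lag > max_lag_bins) break;
      if (k >= ncur) break;
      lags.push_back(lag);
      vals.push_back(acf_at_lag(cur.data(), ncur, k));
      any = true;
    }
    if (!any && 2.0 * (m + 1) * scale > max_lag_bins) break;
  }

  return List::create(_["lags_bins"] = wrap(lags), _["values"] = wrap(vals));
}

// Mean of x over contiguous blocks of length `len` (used for per-segment
// channel means without copying in R).
// [[Rcpp::export]]
NumericVector block_means_cpp(NumericVector x, int len, int nblocks) {
  NumericVector out(nblocks);
  for (int b = 0; b < nblocks; b++) {
    double s = 0.0;
    const int off = b * len;
    for (int i = 0; i < len; i++) s += x[off + i];
    out[b] = s / len;
  }
  return out;
}
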