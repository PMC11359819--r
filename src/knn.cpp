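#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Mean of the k smallest squared Euclidean distances from sample t (0-based)
// to the other samples inside the clipped window [t - L, t + L].  `XT` holds
// the data sample-major (J contiguous values per sample) for cache locality.
// Ties between equidistant candidates are broken by lower sample index; the
// returned mean is identical to a full stable sort because tied distances
// contribute equally.
static double knn_dist_at(const std::vector<double>& XT, int n, int J,
                          int t, int L, int k, std::vector<double>& d2buf) {
  const int lo = std::max(0, t - L), hi = std::min(n - 1, t + L);
  const int ncand = hi - lo;  // window minus x_t itself
  if (ncand < k)
    stop("window at t=%d has only %d candidate neighbours but k=%d",
         t + 1, ncand, k);
  d2buf.clear();
  const double* xt = &XT[(size_t)t * J];
  for (int s = lo; s <= hi; ++s) {
    if (s == t) continue;
    const double* xs = &XT[(size_t)s * J];
    double acc = 0.0;
    for (int j = 0; j < J; ++j) {
      const double diff = xs[j] - xt[j];
      acc += diff * diff;
    }
    d2buf.push_back(acc);
  }
  std::nth_element(d2buf.begin(), d2buf.begin() + (k - 1), d2buf.end());
  double sum = 0.0;
  for (int i = 0; i < k; ++i) sum += d2buf[i];
  return sum / k;
}

static std::vector<double> transpose_to_sample_major(const NumericMatrix& X) {
  const int n = X.nrow(), J = X.ncol();
  std::vector<double> XT((size_t)n * J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i)
      XT[(size_t)i * J + j] = X(i, j);
  return XT;
}

// [[Rcpp::export(name = ".knn_profile_cpp")]]
NumericVector knn_profile_cpp(NumericMatrix X, int L, int k) {
  const int n = X.nrow(), J = X.ncol();
  const std::vector<double> XT = transpose_to_sample_major(X);
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * (size_t)L + 1);
  for (int t = 0; t < n; ++t)
    out[t] = knn_dist_at(XT, n, J, t, L, k, buf);
  return out;
}

// [[Rcpp::export(name = ".knn_point_cpp")]]
double knn_point_cpp(NumericMatrix X, int t, int L, int k) {
  const std::vector<double> XT = transpose_to_sample_major(X);
  std::vector<double> buf;
  buf.reserve(2 * (size_t)L + 1);
  return knn_dist_at(XT, X.nrow(), X.ncol(), t - 1, L, k, buf); // t 1-based
}
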