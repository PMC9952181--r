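#include <Rcpp.h>
using namespace Rcpp;

// Classic boundary-anchored DTW (symmetric1 step set: match, insert, delete),
// raw cumulative cost, no warping window. Inputs are time-major matrices
// (rows = samples, cols = channels).

static double dp_min3(double a, double b, double c) {
  return std::min(a, std::min(b, c));
}

// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericMatrix a, NumericMatrix b, bool multivariate) {
  const int n = a.nrow(), m = b.nrow(), C = a.ncol();
  if (n < 1 || m < 1) stop("empty slice");
  if (b.ncol() != C) stop("channel count mismatch");

  std::vector<double> prev(m), curr(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double cost;
      if (multivariate) {
        double s = 0.0;
        for (int c = 0; c < C; ++c) {
          double d = a(i, c) - b(j, c);
          s += d * d;
        }
        cost = std::sqrt(s);
      } else {
        cost = std::abs(a(i, 0) - b(j, 0));
      }
      if (i == 0 && j == 0) {
        curr[j] = cost;
      } else if (i == 0) {
        curr[j] = cost + curr[j - 1];
      } else if (j == 0) {
        curr[j] = cost + prev[j];
      } else {
        curr[j] = cost + dp_min3(prev[j - 1], prev[j], curr[j - 1]);
      }
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}
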