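#include <Rcpp.h>
using namespace Rcpp;

//' Accumulated cost of the best monotone warping path
//'
//' Dynamic program from (1,1) to (n,m) with steps right/up/diagonal and
//' local cost ||v1[i]-v2[j]|| + lambda |i-j|.
//'
//' @param v1,v2 velocity matrices (rows = samples).
//' @param lambda warping penalty per index offset.
//' @return Minimal summed path cost.
//' @export
// [[Rcpp::export]]
double dtw_path_cost(NumericMatrix v1, NumericMatrix v2, double lambda) {
  const int n = v1.nrow(), m = v2.nrow(), d = v1.ncol();
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double sq = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = v1(i, k) - v2(j, k);
        sq += diff * diff;
      }
      double c = std::sqrt(sq) + lambda * std::abs(i - j);
      if (i == 0 && j == 0) {
        cur[j] = c;
      } else if (i == 0) {
        cur[j] = cur[j - 1] + c;
      } else if (j == 0) {
        cur[j] = prev[j] + c;
      } else {
        double best = prev[j];               // (1,0)
        if (cur[j - 1] < best) best = cur[j - 1];   // (0,1)
        if (prev[j - 1] < best) best = prev[j - 1]; // (1,1)
        cur[j] = best + c;
      }
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

//' Distance from each point of A to its nearest point in B
//'
//' @param A,B point sets as (n x 2) matrices.
//' @return Numeric vector of length nrow(A).
//' @export
// [[Rcpp::export]]
NumericVector min_dist_to_set(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = A(i, 0) - B(j, 0);
      const double dy = A(i, 1) - B(j, 1);
      const double sq = dx * dx + dy * dy;
      if (sq < best) best = sq;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
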