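#include <Rcpp.h>
using namespace Rcpp;

// Exact weighted decision-stump search for AdaBoost.M1.
// xs:  n x p matrix, each column sorted ascending
// ord: n x p matrix of 1-based row indices sorting each column of the raw
//      feature matrix (so w[ord(i,j)] walks weights in sorted order)
// w:   case weights, y: labels in {-1, +1}
// Returns the stump minimising the weighted 0-1 error over all features,
// thresholds (midpoints between distinct consecutive values) and both
// polarities. polarity +1 predicts -1 left of the threshold, +1 right.
// [[Rcpp::export]]
List stump_search(const NumericMatrix& xs, const IntegerMatrix& ord,
                  const NumericVector& w, const NumericVector& y) {
  const int n = xs.nrow(), p = xs.ncol();
  double totW = 0.0, totWY = 0.0;
  for (int i = 0; i < n; ++i) { totW += w[i]; totWY += w[i] * y[i]; }
  // precompute w*y once; walk columns through raw pointers
  std::vector<double> wy(n);
  for (int i = 0; i < n; ++i) wy[i] = w[i] * y[i];
  const double* wptr = REAL(w);
  double bestErr = R_PosInf, bestThr = 0.0;
  int bestJ = -1, bestPol = 1;
  for (int j = 0; j < p; ++j) {
    const double* xcol = &xs(0, j);
    const int* ocol = &ord(0, j);
    double cw = 0.0, cwy = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      const int idx = ocol[i] - 1;
      cw += wptr[idx]; cwy += wy[idx];
      if (xcol[i] == xcol[i + 1]) continue;  // threshold undefined
      const double errA = (cw + cwy) / 2.0 +
                          ((totW - cw) - (totWY - cwy)) / 2.0;
      const double errB = totW - errA;
      if (errA < bestErr) {
        bestErr = errA; bestJ = j; bestPol = 1;
        bestThr = (xcol[i] + xcol[i + 1]) / 2.0;
      }
      if (errB < bestErr) {
        bestErr = errB; bestJ = j; bestPol = -1;
        bestThr = (xcol[i] + xcol[i + 1]) / 2.0;
      }
    }
  }
  return List::create(_["feature"] = bestJ + 1, _["threshold"] = bestThr,
                      _["polarity"] = bestPol, _["err"] = bestErr);
}
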