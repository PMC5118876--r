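#include <Rcpp.h>
using namespace Rcpp;

// Online training of a 1 x k line-topology self-organizing map.
// x: items in rows (already standardized), init: k x d initial node weights,
// order: epochs x n matrix of 0-based presentation orders (RNG handled in R).
// Learning rate and neighborhood width decay exponentially from *0 to *1
// over the full presentation schedule.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix x, NumericMatrix init,
                            IntegerMatrix order, double alpha0, double alpha1,
                            double sigma0, double sigma1) {
  const int n = x.nrow(), d = x.ncol();
  const int k = init.nrow();
  const int epochs = order.nrow();
  NumericMatrix w = clone(init);
  const double total = std::max(1.0, (double)epochs * n - 1.0);
  double t = 0.0;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s, t += 1.0) {
      const int i = order(e, s);
      const double frac = t / total;
      const double alpha = alpha0 * std::pow(alpha1 / alpha0, frac);
      const double sigma = sigma0 * std::pow(sigma1 / sigma0, frac);
      // best-matching node (ties to the lowest index)
      int bmu = 0;
      double best = R_PosInf;
      for (int j = 0; j < k; ++j) {
        double dist = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = x(i, c) - w(j, c);
          dist += diff * diff;
        }
        if (dist < best) { best = dist; bmu = j; }
      }
      for (int j = 0; j < k; ++j) {
        const double dj = j - bmu;
        const double h = std::exp(-(dj * dj) / (2.0 * sigma * sigma));
        const double step = alpha * h;
        if (step < 1e-12) continue;
        for (int c = 0; c < d; ++c) {
          w(j, c) += step * (x(i, c) - w(j, c));
        }
      }
    }
  }
  return w;
}
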