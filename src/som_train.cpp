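#include <Rcpp.h>
using namespace Rcpp;

// Online training loop for toroidal Kohonen maps, shared by the CPANN and
// SKN classifiers. Neuron k (0-based here) sits at (k / side, k % side);
// topological distance is Chebyshev with wrap-around and the neighbourhood
// kernel is triangular: a = max(0, 1 - d / (radius + 1)).
//
// weights : side^2 x F neuron weight matrix (modified copy returned)
// xbmu    : n x fb matrix searched for the best matching unit
//           (the first fb columns of `weights` are the BMU space)
// targets : n x F matrix the full weight vector is pulled towards
// order   : n x epochs, 0-based presentation order per epoch
// eta, radius : per-epoch schedule values (length epochs)
// bmu_w   : length-fb multipliers on the difference inside the BMU distance
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix weights, NumericMatrix xbmu,
                            NumericMatrix targets, IntegerMatrix order,
                            NumericVector eta, NumericVector radius,
                            int side, NumericVector bmu_w) {
  NumericMatrix W = clone(weights);
  const int m = W.nrow();          // side^2 neurons
  const int F = W.ncol();
  const int fb = xbmu.ncol();
  const int n = xbmu.nrow();
  const int epochs = eta.size();
  if (targets.ncol() != F) stop("targets/weights feature mismatch");
  if (order.nrow() != n || order.ncol() != epochs) stop("bad order matrix");

  for (int e = 0; e < epochs; ++e) {
    const double et = eta[e];
    const double rad = radius[e];
    const double inv = 1.0 / (rad + 1.0);
    for (int s = 0; s < n; ++s) {
      const int i = order(s, e);
      // best matching unit: weighted squared Euclidean over the BMU block
      int best = 0;
      double bestd = R_PosInf;
      for (int k = 0; k < m; ++k) {
        double d2 = 0.0;
        for (int j = 0; j < fb; ++j) {
          const double df = bmu_w[j] * (W(k, j) - xbmu(i, j));
          d2 += df * df;
          if (d2 >= bestd) break;
        }
        if (d2 < bestd) { bestd = d2; best = k; }
      }
      const int br = best / side, bc = best % side;
      // update every neuron within the kernel support
      for (int k = 0; k < m; ++k) {
        int dr = std::abs(k / side - br);
        int dc = std::abs(k % side - bc);
        if (side - dr < dr) dr = side - dr;
        if (side - dc < dc) dc = side - dc;
        const int d = dr > dc ? dr : dc;
        const double a = 1.0 - d * inv;
        if (a <= 0.0) continue;
        const double f = et * a;
        for (int j = 0; j < F; ++j)
          W(k, j) += f * (targets(i, j) - W(k, j));
      }
    }
  }
  return W;
}
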