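#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Normalized stress: sqrt( sum (||xi-xj|| - d_ij)^2 / sum d_ij^2 )
static double normalized_stress(const NumericMatrix& x, const NumericMatrix& d) {
  const int n = x.nrow(), dims = x.ncol();
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < dims; ++k) {
        double diff = x(i, k) - x(j, k);
        s += diff * diff;
      }
      double e = std::sqrt(s) - d(i, j);
      num += e * e;
      den += d(i, j) * d(i, j);
    }
  }
  return den > 0.0 ? std::sqrt(num / den) : 0.0;
}

// Metric MDS by pairwise stochastic gradient descent.
// Each epoch visits every pair once in a fresh random order (R's RNG, so
// set.seed() controls it) and moves the pair half-way toward its target
// distance, scaled by the epoch's step size. An epoch whose normalized
// stress exceeds the previous accepted value is rolled back, which makes
// the reported stress trace non-increasing while the geometric step decay
// continues.
// [[Rcpp::export]]
List sgd_mds_cpp(NumericMatrix dist, NumericMatrix init, NumericVector etas) {
  const int n = dist.nrow();
  const int dims = init.ncol();
  const int n_epochs = etas.size();
  const int n_pairs = n * (n - 1) / 2;

  NumericMatrix x = clone(init);
  NumericMatrix best = clone(init);

  std::vector<int> pi(n_pairs), pj(n_pairs), order(n_pairs);
  {
    int c = 0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) { pi[c] = i; pj[c] = j; ++c; }
  }
  for (int k = 0; k < n_pairs; ++k) order[k] = k;

  NumericVector trace(n_epochs);
  double best_stress = normalized_stress(x, dist);

  for (int e = 0; e < n_epochs; ++e) {
    const double mu = std::min(1.0, etas[e]);
    // Fisher-Yates shuffle with R's RNG
    for (int k = n_pairs - 1; k > 0; --k) {
      int r = (int)(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(order[k], order[r]);
    }
    for (int k = 0; k < n_pairs; ++k) {
      const int i = pi[order[k]], j = pj[order[k]];
      double s = 0.0;
      for (int c = 0; c < dims; ++c) {
        double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      double cur = std::sqrt(s);
      if (cur < 1e-12) continue;  // coincident points: gradient undefined
      const double r = mu * (cur - dist(i, j)) / (2.0 * cur);
      for (int c = 0; c < dims; ++c) {
        const double step = r * (x(i, c) - x(j, c));
        x(i, c) -= step;
        x(j, c) += step;
      }
    }
    double stress = normalized_stress(x, dist);
    if (stress <= best_stress) {
      best_stress = stress;
      std::copy(x.begin(), x.end(), best.begin());
    } else {
      std::copy(best.begin(), best.end(), x.begin());  // roll back
    }
    trace[e] = best_stress;
  }

  return List::create(_["coords"] = best,
                      _["stress"] = best_stress,
                      _["stress_trace"] = trace);
}
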