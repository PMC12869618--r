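#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double col_median(std::vector<double>& v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
  return 0.5 * (v[n / 2 - 1] + hi);
}

// Full Lloyd loop for k-means under the city-block objective: assignment by
// L1 distance, centroid update by per-feature median (L1-optimal) or mean.
// Data arrive transposed (features x samples) so the inner distance loop is
// contiguous in memory. Empty clusters are re-seeded with the point
// farthest from its centroid. Iteration stops when the assignment is stable
// or the objective's relative improvement falls below 1e-10 (median updates
// can oscillate between tied label sets without improving the objective).
// [[Rcpp::export(name = ".kmeans_l1_cpp")]]
List kmeans_l1_cpp(NumericMatrix Xt, NumericMatrix init_t, int max_iter,
                   bool median_update) {
  const int p = Xt.nrow(), n = Xt.ncol(), k = init_t.ncol();
  NumericMatrix cent = clone(init_t);           // p x k
  std::vector<int> lab(n, -1), new_lab(n);
  std::vector<double> dmin(n);
  double prev_obj = R_PosInf;
  const double* x = &Xt(0, 0);

  for (int it = 0; it < max_iter; ++it) {
    const double* c = &cent(0, 0);
    for (int i = 0; i < n; ++i) {
      const double* xi = x + (size_t)i * p;
      double best = R_PosInf; int bj = 0;
      for (int j = 0; j < k; ++j) {
        const double* cj = c + (size_t)j * p;
        double acc = 0.0;
        for (int f = 0; f < p; ++f) acc += std::abs(xi[f] - cj[f]);
        if (acc < best) { best = acc; bj = j; }
      }
      new_lab[i] = bj; dmin[i] = best;
    }
    std::vector<int> count(k, 0);
    bool reseeded = false;
    for (int i = 0; i < n; ++i) ++count[new_lab[i]];
    for (int j = 0; j < k; ++j) {
      if (count[j] == 0) {
        reseeded = true;
        int far = 0; double w = -1.0;
        for (int i = 0; i < n; ++i)
          if (count[new_lab[i]] > 1 && dmin[i] > w) { w = dmin[i]; far = i; }
        --count[new_lab[far]];
        new_lab[far] = j; ++count[j];
        for (int f = 0; f < p; ++f) cent(f, j) = Xt(f, far);
        dmin[far] = 0.0;
      }
    }
    double obj = 0.0;
    for (int i = 0; i < n; ++i) obj += dmin[i];
    // stable assignment always terminates; the objective-plateau check is
    // skipped on reseed iterations, whose perturbation is transient
    if (new_lab == lab) break;
    if (!reseeded && obj >= prev_obj * (1.0 - 1e-10)) break;
    prev_obj = obj;
    lab = new_lab;
    // centroid update
    std::vector<double> col;
    for (int j = 0; j < k; ++j) {
      if (median_update) {
        for (int f = 0; f < p; ++f) {
          col.clear();
          for (int i = 0; i < n; ++i)
            if (lab[i] == j) col.push_back(Xt(f, i));
          cent(f, j) = col_median(col);
        }
      } else {
        for (int f = 0; f < p; ++f) {
          double acc = 0.0;
          for (int i = 0; i < n; ++i) if (lab[i] == j) acc += Xt(f, i);
          cent(f, j) = acc / count[j];
        }
      }
    }
  }
  // final assignment and objective against the final centroids
  double wss = 0.0;
  IntegerVector lab_out(n);
  const double* c = &cent(0, 0);
  for (int i = 0; i < n; ++i) {
    const double* xi = x + (size_t)i * p;
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < k; ++j) {
      const double* cj = c + (size_t)j * p;
      double acc = 0.0;
      for (int f = 0; f < p; ++f) acc += std::abs(xi[f] - cj[f]);
      if (acc < best) { best = acc; bj = j; }
    }
    wss += best; lab_out[i] = bj + 1;
  }
  return List::create(_["centroids_t"] = cent, _["labels"] = lab_out,
                      _["wss"] = wss);
}
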