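#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Windowed, gamma-parameterized DTW.
//
// Recursion over cells with |i - j| <= w:
//   CM(i, j) = |x_i - y_j|^gamma + min(CM(i-1,j-1), CM(i-1,j), CM(i,j-1))
// with CM(0,0) = 0 and +Inf elsewhere on the boundary. Ties in the min are
// broken preferring the diagonal predecessor, then (i-1,j), then (i,j-1),
// both while filling and while backtracking, so the returned path is
// deterministic.
//
// Returns the optimal anchored path (1-based indices), the per-step cost
// lambda_gamma along the path (not the cumulative cell values, so that
// D = sum(per_step_cost) and the time-resolved trace is recoverable),
// the total distance D and the path length L.
// [[Rcpp::export(name = ".dtw_align_cpp")]]
List dtw_align_cpp(NumericVector x, NumericVector y, double gamma, int w) {
  const int N = x.size(), M = y.size();
  const double INF = std::numeric_limits<double>::infinity();

  if (N < 2 || M < 2) stop("series must have at least 2 points");
  if (w < 1) stop("window half-width must be >= 1");
  if (std::abs(N - M) > w)
    stop("infeasible window constraint: |N - M| = %d exceeds w = %d",
         std::abs(N - M), w);
  for (int i = 0; i < N; ++i)
    if (!R_finite(x[i])) stop("non-finite value in x");
  for (int j = 0; j < M; ++j)
    if (!R_finite(y[j])) stop("non-finite value in y");

  // cumulative cost matrix, (N+1) x (M+1), row-major on index i*(M+1)+j
  std::vector<double> CM((size_t)(N + 1) * (M + 1), INF);
  CM[0] = 0.0;

  for (int i = 1; i <= N; ++i) {
    int jlo = std::max(1, i - w), jhi = std::min(M, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double c = std::pow(std::abs(x[i - 1] - y[j - 1]), gamma);
      double diag = CM[(size_t)(i - 1) * (M + 1) + (j - 1)];
      double up   = CM[(size_t)(i - 1) * (M + 1) + j];
      double left = CM[(size_t)i * (M + 1) + (j - 1)];
      double best = diag;              // tie preference: diagonal first
      if (up < best)   best = up;
      if (left < best) best = left;
      CM[(size_t)i * (M + 1) + j] = c + best;
    }
  }

  double D = CM[(size_t)N * (M + 1) + M];
  if (!R_finite(D)) stop("no feasible warping path within the window");

  // backtrack with the same tie rule
  std::vector<int> ix, iy;
  int i = N, j = M;
  ix.push_back(i); iy.push_back(j);
  while (i > 1 || j > 1) {
    double diag = CM[(size_t)(i - 1) * (M + 1) + (j - 1)];
    double up   = CM[(size_t)(i - 1) * (M + 1) + j];
    double left = CM[(size_t)i * (M + 1) + (j - 1)];
    if (diag <= up && diag <= left)      { --i; --j; }
    else if (up <= left)                 { --i; }
    else                                 { --j; }
    ix.push_back(i); iy.push_back(j);
  }
  std::reverse(ix.begin(), ix.end());
  std::reverse(iy.begin(), iy.end());

  const int L = ix.size();
  NumericVector cost(L);
  for (int t = 0; t < L; ++t)
    cost[t] = std::pow(std::abs(x[ix[t] - 1] - y[iy[t] - 1]), gamma);

  return List::create(
    _["ix"] = wrap(ix), _["iy"] = wrap(iy),
    _["per_step_cost"] = cost,
    _["D"] = D, _["L"] = L);
}
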