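#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Dynamic-programming search for the optimal boundary-anchored monotone
// warping gamma on a uniform grid, minimizing the square-root-slope
// (Fisher-Rao) misalignment
//   sum_t ( q1(t) - q2(gamma(t)) * sqrt(gamma'(t)) )^2 dt .
// Nodes are grid points (i, j); admissible local slopes are the coprime
// steps below, with the diagonal step listed first so that ties (e.g. both
// functions constant) resolve to the identity warping.
// [[Rcpp::export(name = ".dp_warp")]]
NumericVector dp_warp(NumericVector q1, NumericVector q2) {
  const int N = q1.size();
  if (q2.size() != N) stop("q1 and q2 must share a grid");
  if (N < 10) stop("need at least 10 grid samples");

  static const int step_i[] = {1, 1, 2, 1, 3, 2, 3, 1, 4, 3, 4};
  static const int step_j[] = {1, 2, 1, 3, 1, 3, 2, 4, 1, 4, 3};
  const int n_steps = 11;

  const double INF = std::numeric_limits<double>::infinity();
  const double dt = 1.0 / (N - 1);
  std::vector<double> E((size_t)N * N, INF);
  std::vector<int> pred((size_t)N * N, -1);
  E[0] = 0.0;

  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      if (i == 0 && j == 0) continue;
      double best = INF;
      int best_k = -1;
      for (int k = 0; k < n_steps; ++k) {
        const int pi = i - step_i[k];
        const int pj = j - step_j[k];
        if (pi < 0 || pj < 0) continue;
        const double base = E[(size_t)pi * N + pj];
        if (!(base < INF)) continue;
        const double m = (double)step_j[k] / step_i[k];
        const double sm = std::sqrt(m);
        // integrate the local cost along the edge, one unit step in i
        double cost = 0.0;
        for (int a = 0; a < step_i[k]; ++a) {
          const double jj = pj + a * m;
          const int j0 = (int)jj;
          const double fr = jj - j0;
          const double q2v = (j0 >= N - 1) ? q2[N - 1]
                                           : (1.0 - fr) * q2[j0] + fr * q2[j0 + 1];
          const double d = q1[pi + a] - sm * q2v;
          cost += d * d * dt;
        }
        const double tot = base + cost;
        if (tot < best) {  // strict: earlier (more diagonal) steps win ties
          best = tot;
          best_k = k;
        }
      }
      E[(size_t)i * N + j] = best;
      pred[(size_t)i * N + j] = best_k;
    }
  }

  // backtrack the optimal path from (N-1, N-1)
  std::vector<int> pi_path, pj_path;
  int i = N - 1, j = N - 1;
  pi_path.push_back(i);
  pj_path.push_back(j);
  while (i > 0 || j > 0) {
    const int k = pred[(size_t)i * N + j];
    if (k < 0) stop("dynamic programming failed to reach the origin");
    i -= step_i[k];
    j -= step_j[k];
    pi_path.push_back(i);
    pj_path.push_back(j);
  }

  // linear interpolation of the piecewise-linear path onto the full grid
  NumericVector gamma(N);
  int seg = pi_path.size() - 1;  // path is stored tip-to-origin
  for (int t = 0; t < N; ++t) {
    while (seg > 0 && pi_path[seg - 1] < t) --seg;
    if (pi_path[seg] == t) {
      gamma[t] = pj_path[seg];
    } else {
      const int i0 = pi_path[seg], i1 = pi_path[seg - 1];
      const double f = (double)(t - i0) / (i1 - i0);
      gamma[t] = pj_path[seg] + f * (pj_path[seg - 1] - pj_path[seg]);
    }
  }
  for (int t = 0; t < N; ++t) gamma[t] /= (N - 1);
  gamma[0] = 0.0;
  gamma[N - 1] = 1.0;
  return gamma;
}
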