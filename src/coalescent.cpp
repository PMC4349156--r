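#include <Rcpp.h>
using namespace Rcpp;

// Block-counting Monte Carlo for Lambda-coalescents.
//
// `rates` is an n x n matrix (1-based b, k flattened to 0-based indices)
// with rates(b-1, k-1) = choose(b, k) * lambda_{b,k}.  Accumulates, over
// `reps` genealogies, the per-class branch lengths L_i (i = number of
// subtended leaves) and the cross moments needed for delta-method standard
// errors of phi = E[L_i] / E[T].
// [[Rcpp::export]]
List sim_lambda_sfs_cpp(int n, int reps, NumericMatrix rates) {
  NumericVector sum_L(n - 1), sum_L2(n - 1), sum_LT(n - 1);
  double sum_T = 0.0, sum_T2 = 0.0;

  // per-b total rates and k-sampling tables
  std::vector<double> total(n + 1, 0.0);
  for (int b = 2; b <= n; ++b)
    for (int k = 2; k <= b; ++k) total[b] += rates(b - 1, k - 1);

  std::vector<int> sizes(n);
  std::vector<double> L(n - 1);

  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    int b = n;
    for (int i = 0; i < n; ++i) sizes[i] = 1;
    std::fill(L.begin(), L.end(), 0.0);
    while (b > 1) {
      double wait = exp_rand() / total[b];
      for (int i = 0; i < b; ++i) L[sizes[i] - 1] += wait;
      // choose merger size k proportional to rates(b, k)
      int k = 2;
      if (b > 2) {
        double u = unif_rand() * total[b];
        double acc = 0.0;
        for (k = 2; k <= b; ++k) {
          acc += rates(b - 1, k - 1);
          if (u <= acc) break;
        }
        if (k > b) k = b;  // numerical guard
      }
      // merge k uniformly chosen blocks: partial Fisher-Yates
      int merged = 0;
      for (int j = 0; j < k; ++j) {
        int idx = j + (int)(unif_rand() * (b - j));
        if (idx >= b) idx = b - 1;
        std::swap(sizes[j], sizes[idx]);
        merged += sizes[j];
      }
      sizes[0] = merged;
      for (int j = k; j < b; ++j) sizes[j - k + 1] = sizes[j];
      b -= (k - 1);
    }
    double T = 0.0;
    for (int i = 0; i < n - 1; ++i) T += L[i];
    for (int i = 0; i < n - 1; ++i) {
      sum_L[i] += L[i];
      sum_L2[i] += L[i] * L[i];
      sum_LT[i] += L[i] * T;
    }
    sum_T += T;
    sum_T2 += T * T;
  }
  return List::create(_["sum_L"] = sum_L, _["sum_L2"] = sum_L2,
                      _["sum_LT"] = sum_LT, _["sum_T"] = sum_T,
                      _["sum_T2"] = sum_T2);
}

// Growth-time-changed Kingman coalescent (pair mergers only).
// type 1: nu(t) = exp(-beta t); type 2: nu(t) = (1 + t)^(-gamma).
// Pair-coalescence intensity scales as 1/nu(t); waiting times come from
// analytic inversion of the cumulative intensity.
// [[Rcpp::export]]
List sim_growth_sfs_cpp(int n, int reps, int type, double param) {
  NumericVector sum_L(n - 1), sum_L2(n - 1), sum_LT(n - 1);
  double sum_T = 0.0, sum_T2 = 0.0;

  std::vector<int> sizes(n);
  std::vector<double> L(n - 1);

  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    int b = n;
    double t = 0.0;
    for (int i = 0; i < n; ++i) sizes[i] = 1;
    std::fill(L.begin(), L.end(), 0.0);
    while (b > 1) {
      double C = 0.5 * b * (b - 1);
      double E = exp_rand();
      double wait;
      if (param == 0.0) {
        wait = E / C;
      } else if (type == 1) {
        wait = std::log(std::exp(param * t) + param * E / C) / param - t;
      } else {
        double g1 = param + 1.0;
        wait = std::pow(std::pow(1.0 + t, g1) + g1 * E / C, 1.0 / g1) -
               (1.0 + t);
      }
      for (int i = 0; i < b; ++i) L[sizes[i] - 1] += wait;
      t += wait;
      // merge a uniform pair
      int i1 = (int)(unif_rand() * b);
      if (i1 >= b) i1 = b - 1;
      std::swap(sizes[0], sizes[i1]);
      int i2 = 1 + (int)(unif_rand() * (b - 1));
      if (i2 >= b) i2 = b - 1;
      std::swap(sizes[1], sizes[i2]);
      sizes[0] += sizes[1];
      for (int j = 2; j < b; ++j) sizes[j - 1] = sizes[j];
      b -= 1;
    }
    double T = 0.0;
    for (int i = 0; i < n - 1; ++i) T += L[i];
    for (int i = 0; i < n - 1; ++i) {
      sum_L[i] += L[i];
      sum_L2[i] += L[i] * L[i];
      sum_LT[i] += L[i] * T;
    }
    sum_T += T;
    sum_T2 += T * T;
  }
  return List::create(_["sum_L"] = sum_L, _["sum_L2"] = sum_L2,
                      _["sum_LT"] = sum_LT, _["sum_T"] = sum_T,
                      _["sum_T2"] = sum_T2);
}
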