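#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact minimizers of the 1-D weighted fused-lasso (total-variation) problem
//
//   min_theta  1/2 sum_i (y_i - theta_i)^2  +  sum_i w_i |theta_i - theta_{i+1}|
//
// by enumeration of fusion/sign patterns on the chain boundaries.  Any
// minimizer is piecewise constant over consecutive blocks; given the block
// partition and the signs of the jumps between blocks, the block values have
// the closed form
//
//   theta_B = mean(y_B) + (s_right * w_right - s_left * w_left) / |B| ,
//
// where s is the assumed sign of theta_{next} - theta_B on each cut boundary
// (0 weight at the chain ends).  Evaluating the true objective at every
// candidate and keeping the minimum is exact, because the global minimizer's
// own pattern is always among the candidates (adjacent blocks that tie in
// value are reproduced by the merged partition).  Cost is O(3^(m-1) m) for a
// chain of length m -- intended for small m (the class dimension K).

static double chain_objective(const std::vector<double>& th,
                              const std::vector<double>& y,
                              const std::vector<double>& w) {
  const int m = (int)y.size();
  double obj = 0.0;
  for (int i = 0; i < m; ++i) {
    const double r = th[i] - y[i];
    obj += 0.5 * r * r;
  }
  for (int i = 0; i + 1 < m; ++i) obj += w[i] * std::fabs(th[i] - th[i + 1]);
  return obj;
}

// states per boundary: 0 = fused, 1 = cut with jump up (+), 2 = cut with
// jump down (-).  When ascending_only is true only states {0, 1} are used,
// which is sufficient when y is sorted ascending (the minimizer then has
// ascending block values).
static void chain_fused_enum(const std::vector<double>& y,
                             const std::vector<double>& w,
                             bool ascending_only,
                             std::vector<double>& out) {
  const int m = (int)y.size();
  out.assign(m, 0.0);
  if (m == 1) { out[0] = y[0]; return; }

  std::vector<double> cy(m + 1, 0.0);  // prefix sums of y
  for (int i = 0; i < m; ++i) cy[i + 1] = cy[i] + y[i];

  const int nb = m - 1;
  const int base = ascending_only ? 2 : 3;
  long ncand = 1;
  for (int i = 0; i < nb; ++i) ncand *= base;

  std::vector<int> state(nb);
  std::vector<double> th(m);
  double best = R_PosInf;

  for (long code = 0; code < ncand; ++code) {
    long c = code;
    for (int i = 0; i < nb; ++i) { state[i] = (int)(c % base); c /= base; }

    int start = 0;
    double s_left = 0.0, w_left = 0.0;
    bool ok = true;
    for (int b = 0; b < m && ok; ) {
      int end = start;                       // block = [start, end]
      while (end < m - 1 && state[end] == 0) ++end;
      double s_right = 0.0, w_right = 0.0;
      if (end < m - 1) {
        s_right = (state[end] == 1) ? 1.0 : -1.0;
        w_right = w[end];
      }
      const int len = end - start + 1;
      const double val =
          (cy[end + 1] - cy[start] - s_left * w_left + s_right * w_right) / len;
      for (int i = start; i <= end; ++i) th[i] = val;
      if (end == m - 1) break;
      s_left = s_right;
      w_left = w_right;
      start = end + 1;
    }
    const double obj = chain_objective(th, y, w);
    if (obj < best) { best = obj; out = th; }
  }
}

// [[Rcpp::export(name = ".chain_fused_cpp")]]
NumericVector chain_fused_cpp(NumericVector y, NumericVector w) {
  const int m = y.size();
  if (m == 0) stop("empty vector");
  if (w.size() != m - 1) stop("weights must have length m - 1");
  for (int i = 0; i < m - 1; ++i)
    if (w[i] < 0) stop("fusion weights must be nonnegative");
  if (m > 14) stop("chain too long for exact enumeration (m <= 14)");
  std::vector<double> yy(y.begin(), y.end()), ww(w.begin(), w.end()), out;
  chain_fused_enum(yy, ww, false, out);
  return NumericVector(out.begin(), out.end());
}

static inline double soft(double x, double lam) {
  const double a = std::fabs(x) - lam;
  return (a > 0.0) ? ((x > 0) ? a : -a) : 0.0;
}

// Batched prox of the fused-penalty cell problem.  Columns of A are the K
// class values of one matrix cell; for each column solve
//
//   min 1/2 sum_k (t_k - a_k)^2 + alpha_j sum_k |t_k| + beta sum_{k<l} |t_k - t_l|
//
// by sorting, rewriting the complete-graph fusion on ordered values as a
// chain with weight beta * r * (K - r) between ranks r and r + 1, solving
// the chain exactly, and soft-thresholding by alpha_j (the l1 part commutes
// with the fusion-only solution).
// [[Rcpp::export(name = ".fused_prox_cpp")]]
NumericMatrix fused_prox_cpp(NumericMatrix A, NumericVector alpha, double beta) {
  const int K = A.nrow(), M = A.ncol();
  if (alpha.size() != M) stop("alpha must have one entry per column");
  if (beta < 0) stop("beta must be nonnegative");
  NumericMatrix out(K, M);

  std::vector<int> ord(K);
  std::vector<double> ys(K), w(K > 1 ? K - 1 : 0), sol;
  for (int r = 1; r < K; ++r) w[r - 1] = beta * (double)r * (double)(K - r);

  for (int j = 0; j < M; ++j) {
    for (int k = 0; k < K; ++k) ord[k] = k;
    NumericMatrix::Column col = A(_, j);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    for (int k = 0; k < K; ++k) ys[k] = col[ord[k]];
    chain_fused_enum(ys, w, true, sol);
    const double a = alpha[j];
    for (int k = 0; k < K; ++k) out(ord[k], j) = soft(sol[k], a);
  }
  return out;
}
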