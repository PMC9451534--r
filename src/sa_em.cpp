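#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Variational EM for the state-array posterior.
//
// A: N x K likelihood matrix (rows may be normalized; normalization
//    cancels in the responsibility update).
// L: jump count per trajectory (length N).
// alpha_k: Dirichlet concentration per state (alpha / K).
//
// Iterates
//   n_k = alpha_k + sum_i L_i r_ik
//   r_ik = A_ik exp(psi(n_k)) / sum_j A_ij exp(psi(n_j))
// from r^(0) = row-normalized A until the maximum change in the
// posterior mean occupations E[tau_k] = n_k / sum_j n_j drops below
// tol, or max_iter is reached.
// [[Rcpp::export]]
List sa_em_core(NumericMatrix A, NumericVector L, double alpha_k,
                int max_iter, double tol) {
  const int N = A.nrow(), K = A.ncol();
  const double *a = A.begin();
  std::vector<double> w(K, 1.0), n(K, 0.0), tau_old(K, -1.0);
  std::vector<double> denom(N);
  std::vector<double> delta_trace;
  int iters = 0;
  bool converged = false;

  for (int t = 0; t <= max_iter; ++t) {
    if (t > 0)
      for (int k = 0; k < K; ++k)
        w[k] = std::exp(R::digamma(n[k]));

    std::fill(denom.begin(), denom.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double *col = a + (size_t)k * N;
      const double wk = w[k];
      if (wk == 0.0) continue;
      for (int i = 0; i < N; ++i) denom[i] += col[i] * wk;
    }
    for (int i = 0; i < N; ++i) {
      if (!(denom[i] > 0.0) || !std::isfinite(denom[i]))
        stop("trajectory %d has zero or non-finite total responsibility", i + 1);
      denom[i] = L[i] / denom[i];
    }

    double nsum = 0.0;
    for (int k = 0; k < K; ++k) {
      const double *col = a + (size_t)k * N;
      const double wk = w[k];
      double acc = 0.0;
      if (wk > 0.0)
        for (int i = 0; i < N; ++i) acc += col[i] * denom[i];
      n[k] = alpha_k + wk * acc;
      nsum += n[k];
    }
    if (!std::isfinite(nsum)) stop("non-finite pseudocounts during EM");

    double delta = 0.0;
    for (int k = 0; k < K; ++k) {
      const double tk = n[k] / nsum;
      const double d = std::fabs(tk - tau_old[k]);
      if (d > delta) delta = d;
      tau_old[k] = tk;
    }
    iters = t;
    if (t > 0) delta_trace.push_back(delta);
    if (t > 0 && delta < tol) { converged = true; break; }
  }

  // responsibilities consistent with the final pseudocounts
  NumericMatrix r(N, K);
  for (int k = 0; k < K; ++k) w[k] = std::exp(R::digamma(n[k]));
  std::fill(denom.begin(), denom.end(), 0.0);
  for (int k = 0; k < K; ++k) {
    const double *col = a + (size_t)k * N;
    for (int i = 0; i < N; ++i) denom[i] += col[i] * w[k];
  }
  for (int k = 0; k < K; ++k) {
    const double *col = a + (size_t)k * N;
    double *rc = r.begin() + (size_t)k * N;
    for (int i = 0; i < N; ++i) rc[i] = col[i] * w[k] / denom[i];
  }

  return List::create(_["n"] = NumericVector(n.begin(), n.end()),
                      _["r"] = r,
                      _["iterations"] = iters,
                      _["converged"] = converged,
                      _["delta_trace"] = NumericVector(delta_trace.begin(),
                                                       delta_trace.end()));
}
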