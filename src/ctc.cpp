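// CTC forward-backward in log space over the alphabet {A, C, G, T, blank}.
//
// logp: (T x 5) matrix of per-frame log-scores (typically log-softmax
// output; the recursion is valid for any real scores).  labels: integer
// vector with values 1..4; blank is column 5.  Returns the negative
// log-probability of the label under the standard blank-augmented CTC
// alignment model and its gradient with respect to logp.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m, d;
  if (a > b) { m = a; d = b - a; } else { m = b; d = a - b; }
  return m + std::log1p(std::exp(d));
}

// [[Rcpp::export]]
List ctc_forward_backward(NumericMatrix logp, IntegerVector labels) {
  const int T = logp.nrow();
  const int L = labels.size();
  const int S = 2 * L + 1;

  // extended label as 0-based column indices: blank, l1, blank, ..., blank
  std::vector<int> col(S);
  // allow a skip transition into state s? (non-blank, differs from s-2)
  std::vector<bool> skip(S, false);
  for (int s = 0; s < S; ++s)
    col[s] = (s % 2 == 0) ? 4 : labels[(s - 1) / 2] - 1;
  for (int s = 3; s < S; s += 2)
    if (col[s] != col[s - 2]) skip[s] = true;

  NumericMatrix grad(T, 5);
  int need = L;
  for (int i = 1; i < L; ++i) if (labels[i] == labels[i - 1]) ++need;
  if (T < need)
    return List::create(_["nll"] = R_PosInf, _["grad"] = grad);

  const double *lp = REAL(logp);              // column-major, T x 5
  std::vector<double> alpha((size_t)T * S, R_NegInf);
  std::vector<double> beta((size_t)T * S, R_NegInf);

  alpha[0] = lp[(size_t)col[0] * T];
  if (S > 1) alpha[1] = lp[(size_t)col[1] * T];
  for (int t = 1; t < T; ++t) {
    double *at = &alpha[(size_t)t * S];
    const double *ap = &alpha[(size_t)(t - 1) * S];
    for (int s = 0; s < S; ++s) {
      double a = ap[s];
      if (s >= 1) a = logadd(a, ap[s - 1]);
      if (s >= 2 && skip[s]) a = logadd(a, ap[s - 2]);
      if (a != R_NegInf) at[s] = a + lp[(size_t)col[s] * T + t];
    }
  }
  double ll = alpha[(size_t)(T - 1) * S + S - 1];
  if (S > 1) ll = logadd(ll, alpha[(size_t)(T - 1) * S + S - 2]);
  if (ll == R_NegInf)
    return List::create(_["nll"] = R_PosInf, _["grad"] = grad);

  // beta[t][s]: log-prob of emitting frames t+1..T-1 given state s at t
  beta[(size_t)(T - 1) * S + S - 1] = 0.0;
  if (S > 1) beta[(size_t)(T - 1) * S + S - 2] = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    double *bt = &beta[(size_t)t * S];
    const double *bn = &beta[(size_t)(t + 1) * S];
    for (int s = 0; s < S; ++s) {
      double b = (bn[s] == R_NegInf) ? R_NegInf
                 : bn[s] + lp[(size_t)col[s] * T + t + 1];
      if (s + 1 < S && bn[s + 1] != R_NegInf)
        b = logadd(b, bn[s + 1] + lp[(size_t)col[s + 1] * T + t + 1]);
      if (s + 2 < S && skip[s + 2] && bn[s + 2] != R_NegInf)
        b = logadd(b, bn[s + 2] + lp[(size_t)col[s + 2] * T + t + 1]);
      bt[s] = b;
    }
  }

  // occupancy: gamma[t][s] = alpha + beta - ll; gradient wrt logp is
  // -sum_{s: col[s]=c} exp(gamma)
  double *g = REAL(grad);
  for (int t = 0; t < T; ++t) {
    const double *at = &alpha[(size_t)t * S];
    const double *bt = &beta[(size_t)t * S];
    for (int s = 0; s < S; ++s) {
      if (at[s] == R_NegInf || bt[s] == R_NegInf) continue;
      g[(size_t)col[s] * T + t] -= std::exp(at[s] + bt[s] - ll);
    }
  }
  return List::create(_["nll"] = -ll, _["grad"] = grad);
}
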