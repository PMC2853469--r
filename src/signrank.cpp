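#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact lower tail of the signed-rank sum under random signs:
// P(W+ <= w_obs) where W+ is the sum of a uniformly random subset of the
// (possibly tied, average) ranks r. Enumerates all 2^n sign assignments by
// Gray code, one rank flip per step. Intended for n <= 25.
// [[Rcpp::export]]
double signrank_exact_tail_cpp(NumericVector r, double w_obs) {
  const int n = r.size();
  if (n < 1 || n > 30) stop("exact enumeration supports 1 <= n <= 30");
  const long long total = 1LL << n;
  const double eps = 1e-9;
  std::vector<char> on(n, 0);
  double s = 0.0;
  long long cnt = (s <= w_obs + eps) ? 1 : 0;
  for (long long k = 1; k < total; ++k) {
    int b = __builtin_ctzll(k);
    if (on[b]) { s -= r[b]; on[b] = 0; }
    else       { s += r[b]; on[b] = 1; }
    if (s <= w_obs + eps) ++cnt;
  }
  return (double)cnt / (double)total;
}
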