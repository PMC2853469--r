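#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Composition-preserving label-swap Metropolis sampler on a fixed contact
// graph. The stationary distribution over label arrangements (at the fixed
// multiset of labels) is P(t) proportional to exp(-sum_pairs E[t_u, t_v, slot]).
//
// types0: initial 0-based type indices, length n
// pu, pv: 0-based endpoints of the ordered in-range pairs
// off:    0-based offset into the flattened energy array per pair, such that
//         the pair energy is energy[t_u + T * t_v + off]
// energy: flattened (T, T, n_orient, n_bins) array
// burnin_sweeps: sweeps (n proposed swaps each) before sampling
// n_samples, sample_every: label snapshots taken after burn-in; with
//         n_samples = 0 only the final state is returned
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_label_swap_cpp(IntegerVector types0, IntegerVector pu,
                          IntegerVector pv, IntegerVector off,
                          NumericVector energy, int n_types,
                          int burnin_sweeps, int n_samples, int sample_every) {
  const int n = types0.size();
  const int np = pu.size();
  const int T = n_types;
  if (n < 2) stop("need at least 2 positions");

  // CSR adjacency: pair indices incident to each position (as either endpoint)
  std::vector<int> deg(n, 0);
  for (int k = 0; k < np; ++k) { deg[pu[k]]++; deg[pv[k]]++; }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> adj(2 * (size_t)np);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int k = 0; k < np; ++k) {
    adj[fill[pu[k]]++] = k;
    adj[fill[pv[k]]++] = k;
  }

  std::vector<int> t(types0.begin(), types0.end());
  std::vector<long long> stamp(np, -1);
  std::vector<int> touched;
  touched.reserve(256);

  IntegerMatrix samples(n_samples > 0 ? n_samples : 0, n);
  long long accepted = 0, proposed = 0, ctr = 0;
  const int total_sweeps =
      burnin_sweeps + (n_samples > 0 ? n_samples * sample_every : 0);
  int srow = 0;

  RNGScope scope;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      int a = (int)(unif_rand() * n); if (a >= n) a = n - 1;
      int b = (int)(unif_rand() * (n - 1)); if (b >= n - 1) b = n - 2;
      if (b >= a) b++;
      ++proposed;
      if (t[a] == t[b]) { ++accepted; continue; }
      touched.clear();
      for (int e = 0; e < 2; ++e) {
        int x = e == 0 ? a : b;
        for (int ii = start[x]; ii < start[x + 1]; ++ii) {
          int k = adj[ii];
          if (stamp[k] == ctr) continue;
          stamp[k] = ctr;
          touched.push_back(k);
        }
      }
      ++ctr;
      double e0 = 0.0, e1 = 0.0;
      for (int k : touched) e0 += energy[t[pu[k]] + T * t[pv[k]] + off[k]];
      std::swap(t[a], t[b]);
      for (int k : touched) e1 += energy[t[pu[k]] + T * t[pv[k]] + off[k]];
      double de = e1 - e0;
      if (de <= 0.0 || unif_rand() < std::exp(-de)) {
        ++accepted;
      } else {
        std::swap(t[a], t[b]);
      }
    }
    if (n_samples > 0 && sweep >= burnin_sweeps &&
        (sweep - burnin_sweeps + 1) % sample_every == 0 && srow < n_samples) {
      for (int i = 0; i < n; ++i) samples(srow, i) = t[i];
      ++srow;
    }
  }

  return List::create(
      _["types"] = IntegerVector(t.begin(), t.end()),
      _["samples"] = samples,
      _["acceptance_rate"] = proposed > 0 ? (double)accepted / proposed : NA_REAL);
}
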