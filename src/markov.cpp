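#include <Rcpp.h>
using namespace Rcpp;

// Simulate a base sequence from an order-k Markov chain over {A,C,G,T}.
// cum_probs: 4^k x 4 matrix of row-wise cumulative transition probabilities
// (last column must be 1). init: the k seed bases as integers in 0..3.
// Returns n bases as integers in 0..3 (seed bases included at the front).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector markov_sim_cpp(NumericMatrix cum_probs, IntegerVector init, int n) {
  int k = init.size();
  int n_states = cum_probs.nrow();
  IntegerVector out(n);
  for (int i = 0; i < k && i < n; ++i) out[i] = init[i];
  // state index = sum over last k bases of base * 4^(k-1-offset)
  int state = 0;
  for (int i = 0; i < k; ++i) state = state * 4 + init[i];
  int mod = n_states / 4; // 4^(k-1); for k = 0 this is 0 and state stays 0
  for (int i = k; i < n; ++i) {
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > cum_probs(state, b)) ++b;
    out[i] = b;
    if (k > 0) state = (state % mod) * 4 + b;
  }
  return out;
}
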