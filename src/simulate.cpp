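#include <Rcpp.h>
using namespace Rcpp;

// Synchronous PBN trajectory stepper with per-node perturbation.
//
// Draw order per step (fixed for bit-reproducibility): one uniform per
// non-clamped node (flip indicators, in the given node order); if any flip
// fires the network function is NOT applied this step ("flip-wins"); else one
// uniform per updatable node (in node order) decides its next value from the
// node's mixture probability P(x_i' = 1 | state).  Clamped nodes never change;
// unclamped input nodes hold their value unless perturbed.
//
// state:      current 0/1 state, length n (modified copy returned)
// steps:      number of transitions to simulate
// p:          perturbation probability
// nonclamped: 0-based indices of perturbable nodes
// upd:        0-based indices of non-input, non-clamped nodes
// parents:    per upd node, 0-based parent indices (union over predictors)
// weights:    per upd node, integer weights 2^(0..k-1) for table lookup
// pr1:        per upd node, P(next = 1) for each parent assignment
// record:     0-based indices of nodes whose trace is returned
// [[Rcpp::export]]
List sim_steps_cpp(IntegerVector state, int steps, double p,
                   IntegerVector nonclamped, IntegerVector upd,
                   List parents, List weights, List pr1,
                   IntegerVector record) {
  int n = state.size();
  int m = nonclamped.size();
  int nu = upd.size();
  int nr = record.size();
  IntegerVector s = clone(state);
  IntegerMatrix trace(steps, nr);
  std::vector<int> next(n);

  std::vector<std::vector<int> > par(nu), w(nu);
  std::vector<std::vector<double> > pr(nu);
  for (int j = 0; j < nu; ++j) {
    par[j] = as<std::vector<int> >(parents[j]);
    w[j]   = as<std::vector<int> >(weights[j]);
    pr[j]  = as<std::vector<double> >(pr1[j]);
  }

  RNGScope scope;
  for (int t = 0; t < steps; ++t) {
    bool any_flip = false;
    std::vector<char> flip(m, 0);
    for (int i = 0; i < m; ++i) {
      if (unif_rand() < p) { flip[i] = 1; any_flip = true; }
    }
    if (any_flip) {
      for (int i = 0; i < m; ++i)
        if (flip[i]) s[nonclamped[i]] = 1 - s[nonclamped[i]];
    } else if (nu > 0) {
      for (int j = 0; j < nu; ++j) {
        int idx = 0;
        for (size_t q = 0; q < par[j].size(); ++q)
          idx += s[par[j][q]] * w[j][q];
        double u = unif_rand();
        next[upd[j]] = (u < pr[j][idx]) ? 1 : 0;
      }
      for (int j = 0; j < nu; ++j) s[upd[j]] = next[upd[j]];
    }
    for (int r = 0; r < nr; ++r) trace(t, r) = s[record[r]];
  }
  return List::create(_["trace"] = trace, _["state"] = s);
}
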