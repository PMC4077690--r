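# Three-node example network: N1 activates N3, N2 partially inhibits it;
# with both inputs ON the steady-state activity of N3 is 0.6.
fig_model <- function(p = 0.001) {
  build_pbn(c("N3 = N1 : 0.6", "N3 = N1 & ~N2 : 0.4"), p = p)
}

# Brute-force marginal from the transition matrix by long matrix powering:
# independent of the linear-solve path in stationary_distribution().
power_iteration_marginal <- function(pbn, node, clamps = NULL, p = pbn$p,
                                     iters = 200000L, tol = 1e-12) {
  chain <- transition_matrix(pbn, clamps, p = p)
  v <- rep(1 / nrow(chain$P), nrow(chain$P))
  for (i in seq_len(iters)) {
    vn <- as.vector(v %*% chain$P)
    if (max(abs(vn - v)) < tol) { v <- vn; break }
    v <- vn
  }
  sum(v[chain$bits[, node] == 1L])
}
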