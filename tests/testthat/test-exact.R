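test_that("constituent enumeration gives product probabilities summing to 1", {
  pbn <- fig_model()
  cons <- enumerate_constituents(pbn)
  expect_length(cons, 2L)
  expect_equal(sort(vapply(cons, `[[`, 0, "prob")), c(0.4, 0.6))

  bn <- build_pbn(c("B = A", "C = A & B"))
  expect_length(enumerate_constituents(bn), 1L)
  expect_equal(enumerate_constituents(bn)[[1L]]$prob, 1)

  two <- build_pbn(c("B = A : 0.3", "B = ~A : 0.7",
                     "C = A : 0.2", "C = B : 0.3", "C = A & B : 0.5"))
  cons2 <- enumerate_constituents(two)
  expect_length(cons2, 6L)
  probs <- vapply(cons2, `[[`, 0, "prob")
  expect_equal(sum(probs), 1)
  expect_true(any(abs(probs - 0.3 * 0.5) < 1e-12))
})

test_that("transition matrix reproduces the example model's two-state part", {
  pbn <- fig_model()
  chain <- transition_matrix(pbn, p = 0)
  expect_true(all(abs(rowSums(chain$P) - 1) < 1e-12))
  # states 110 and 111 (N1=N2=1) each move to N3=1 w.p. 0.6, N3=0 w.p. 0.4
  for (lab in c("110", "111")) {
    i <- match(lab, chain$labels)
    expect_equal(chain$P[i, match("111", chain$labels)], 0.6)
    expect_equal(chain$P[i, match("110", chain$labels)], 0.4)
  }
})

test_that("perturbation makes the chain ergodic", {
  pbn <- fig_model()
  chain <- transition_matrix(pbn, p = 0.01)
  # off-diagonal transitions all possible via bit flips; the diagonal can be
  # zero under flip-wins (the network part may force a move), but two steps
  # connect every pair of states strictly positively
  off <- chain$P + diag(nrow(chain$P))
  expect_true(all(off > 0))
  expect_true(all(chain$P %*% chain$P > 0))
  expect_true(all(abs(rowSums(chain$P) - 1) < 1e-12))
})

test_that("p = 0 transition matrix is the mixture of constituent networks", {
  for (s in 1:3) {
    pbn <- random_pbn(4, seed = 600 + s)
    chain <- transition_matrix(pbn, p = 0)
    cons <- enumerate_constituents(pbn)
    S <- nrow(chain$P)
    acc <- matrix(0, S, S)
    for (cn in cons) {
      for (i in seq_len(S)) {
        st <- chain$bits[i, ]
        nxt <- constituent_step(pbn, cn$choice, st)
        j <- 1L + sum(nxt * 2^(seq_along(nxt) - 1L))
        acc[i, j] <- acc[i, j] + cn$prob
      }
    }
    expect_equal(unname(chain$P), acc, tolerance = 1e-12)
  }
})

test_that("stationary distribution solves pi P = pi and matches power iteration", {
  pbn <- fig_model()
  chain <- transition_matrix(pbn, c(N1 = 1, N2 = 1), p = 0)
  pi <- stationary_distribution(chain)
  expect_equal(unname(marginal_probability(chain, pi, "N3")), 0.6)
  expect_lt(max(abs(as.vector(pi %*% chain$P) - pi)), 1e-10)

  pbn4 <- random_pbn(4, seed = 77, p = 0.001)
  pi2 <- exact_marginal(pbn4, "X3", p = 0.001)
  expect_equal(unname(pi2),
               power_iteration_marginal(pbn4, "X3", p = 0.001),
               tolerance = 1e-8)
})

test_that("reducible unperturbed chains are rejected", {
  pbn <- fig_model(p = 0)
  chain <- transition_matrix(pbn, p = 0)  # four disjoint recurrent classes
  expect_error(stationary_distribution(chain), "reducible")
})

test_that("marginals respect clamps and limits", {
  pbn <- fig_model()
  expect_equal(unname(exact_marginal(pbn, "N1", c(N1 = 1, N2 = 0), p = 0)), 1)
  expect_equal(unname(exact_marginal(pbn, "N3", c(N1 = 1, N2 = 0), p = 0)), 1)
  expect_equal(unname(exact_marginal(pbn, "N3", c(N1 = 0, N2 = 0), p = 0)), 0)
  expect_error(transition_matrix(pbn, max_nodes = 2), "cap")
})

test_that("bottom SCCs of the example model match the four absorbing parts", {
  pbn <- fig_model()
  sccs <- bottom_sccs(pbn)
  expect_equal(sccs, list("000", "010", "101", c("110", "111")))
  # any perturbation collapses the graph to one bottom SCC = whole space
  chain <- transition_matrix(pbn, p = 0.001)
  g <- igraph::graph_from_adjacency_matrix((chain$P > 0) * 1, mode = "directed")
  expect_equal(igraph::components(g, mode = "strong")$no, 1L)
})

test_that("a deterministic fixed point appears among the bottom SCCs", {
  bn <- build_pbn(c("B = A & B", "C = B"), p = 0)
  sccs <- bottom_sccs(bn)
  expect_true(any(vapply(sccs, function(s) identical(s, "000"), TRUE)))
})

test_that("influence weights predictor sensitivity by the stationary law", {
  pbn <- fig_model()
  # toggling N2 changes N3's outcome only under the AND-NOT rule and only
  # when N1 = 1, so the influence is 0.4 * P(N1 = 1)
  chain <- transition_matrix(pbn, p = 0.001)
  pi <- stationary_distribution(chain)
  pn1 <- marginal_probability(chain, pi, "N1")
  expect_equal(influence(pbn, "N2", "N3", p = 0.001), 0.4 * pn1,
               tolerance = 1e-12)
  # both rules reduce to N1 when N2 is clamped OFF
  expect_equal(influence(pbn, "N1", "N3", clamps = c(N2 = 0), p = 0.001), 1.0)
  # a non-parent has no influence
  pbn2 <- build_pbn(c("B = A", "C = A"))
  expect_equal(influence(pbn2, "B", "C", p = 0.001), 0)
})
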