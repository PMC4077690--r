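test_that("meta-state rates are counted over consecutive pairs", {
  expect_equal(estimate_alpha_beta(c(0, 1, 0, 1, 0, 1))[c("alpha", "beta")],
               list(alpha = 1, beta = 1))
  # hand count over the 9 pairs: 4 from-0 (3 to 1), 5 from-1 (2 to 0)
  ab <- estimate_alpha_beta(c(0, 0, 1, 1, 0, 1, 1, 1, 0, 1))
  expect_equal(ab$alpha, 3 / 4)
  expect_equal(ab$beta, 2 / 5)
  expect_false(ab$degenerate)
  expect_true(estimate_alpha_beta(c(0, 0, 0, 0))$degenerate)
  expect_true(estimate_alpha_beta(c(1, 1))$degenerate)
  expect_error(estimate_alpha_beta(1L), "length >= 2")
})

test_that("burn-in formula uses the absolute value of lambda", {
  expect_equal(burn_in_m0(0.1, 0.1, 0.01), 18L)
  expect_equal(burn_in_m0(0.5, 0.5, 0.01), 1L)      # lambda = 0
  # oscillatory chain, lambda = -0.8: same forgetting rate as lambda = +0.8
  expect_equal(burn_in_m0(0.9, 0.9, 0.01), burn_in_m0(0.1, 0.1, 0.01))
  # m0 never negative, non-increasing in epsilon
  expect_gte(burn_in_m0(0.4, 0.55, 0.3), 0L)
  eps <- c(0.001, 0.01, 0.1)
  m0s <- vapply(eps, function(e) burn_in_m0(0.2, 0.3, e), 0L)
  expect_true(all(diff(m0s) <= 0))
  expect_error(burn_in_m0(0, 0, 0.01), "positive")
})

test_that("run-length formula matches hand evaluation and scaling laws", {
  expect_equal(run_length_N(0.1, 0.1, 0.025, 0.95), 13830L)
  expect_equal(run_length_N(0.5, 0.5, 0.025, 0.95), 1537L)
  # quadratic in 1/r
  N1 <- run_length_N(0.2, 0.3, 0.05, 0.95)
  N2 <- run_length_N(0.2, 0.3, 0.025, 0.95)
  expect_gt(N2 / N1, 3.9)
  expect_lt(N2 / N1, 4.1)
  # monotone: N grows as r shrinks and as s grows
  expect_gt(run_length_N(0.2, 0.3, 0.01, 0.95), run_length_N(0.2, 0.3, 0.025, 0.95))
  expect_gt(run_length_N(0.2, 0.3, 0.025, 0.99), run_length_N(0.2, 0.3, 0.025, 0.95))
})

test_that("the protocol estimates the example model's steady state within r", {
  pbn <- fig_model()
  d <- estimate_marginal(pbn, "N3", clamps = c(N1 = 1, N2 = 1), seed = 1)
  expect_s3_class(d, "two_state_diag")
  expect_lt(abs(d$estimate - 0.6), 0.025)
  expect_gte(d$total_length, d$m0 + 0)
  expect_gte(d$total_length, d$N)
  expect_true(d$alpha > 0 && d$alpha < 1 && d$beta > 0 && d$beta < 1)
})

test_that("a constant-zero node estimates its perturbation-driven occupancy", {
  pbn <- build_pbn("X = 0", p = 0.001)
  ex <- exact_marginal(pbn, "X", p = 0.001)
  expect_lt(ex, 2 * 0.001)
  d <- estimate_marginal(pbn, "X", seed = 4)
  expect_lte(d$estimate, 2 * 0.001 + 0.025)
})

test_that("settings are validated and the length cap reports diagnostics", {
  expect_error(convergence_settings(p = 0), "p > 0")
  expect_error(convergence_settings(r = 0.6), "r < 0.5")
  expect_error(convergence_settings(s = 0.4), "s > 0.5")
  pbn <- build_pbn(c("A = A : 1"))   # input-free frozen node, mixes at rate p
  expect_error(
    estimate_marginal(pbn, "A",
                      settings = convergence_settings(max_length = 2000),
                      seed = 2),
    "max_length")
})

test_that("one shared trajectory serves several measured nodes", {
  b3 <- case_study3()
  clamps <- c(TGFa = 1, PI3Ki = 1, Rafi = 0, TNFa = 1)
  diags <- estimate_marginals_multi(b3$truth_pbn, c("NFkB", "ERK"),
                                    clamps = clamps, seed = 9)
  expect_named(diags, c("NFkB", "ERK"))
  expect_equal(diags$NFkB$total_length, diags$ERK$total_length)
  expect_lt(abs(diags$NFkB$estimate - 0.51), 0.025)
  expect_lt(abs(diags$ERK$estimate - 0.804), 0.025)
  # a clamped node comes back as its clamp value
  dc <- estimate_marginals_multi(b3$truth_pbn, c("TGFa", "NFkB"),
                                 clamps = clamps, seed = 9)
  expect_equal(dc$TGFa$estimate, 1)
})

test_that("a single-node request equals the multi-node path bit for bit", {
  pbn <- fig_model()
  a <- estimate_marginal(pbn, "N3", clamps = c(N1 = 1, N2 = 1), seed = 5)
  b <- estimate_marginals_multi(pbn, "N3", clamps = c(N1 = 1, N2 = 1),
                                seed = 5)[["N3"]]
  expect_identical(a, b)
})

test_that("the protocol terminates within a bounded trajectory on bundled models", {
  tight <- convergence_settings(max_length = 1e6)
  pbn <- fig_model()
  d <- estimate_marginal(pbn, "N3", clamps = c(N1 = 1, N2 = 1),
                         settings = tight, seed = 7)
  expect_lte(d$total_length, 1e6)
  for (b in list(case_study2(), case_study3())) {
    e <- b$experiments[[4L]]
    diags <- estimate_marginals_multi(b$truth_pbn, names(e$measurements),
                                      clamps = e$clamps, settings = tight,
                                      seed = 8)
    expect_true(all(vapply(diags, `[[`, 0L, "total_length") <= 1e6))
  }
})
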