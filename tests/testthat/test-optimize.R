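test_that("problem assembly validates experiments and orders free parameters", {
  b1 <- case_study1()
  p1 <- assemble_problem(b1$pbn, b1$experiments, "discrete")
  expect_equal(p1$k, 5L)
  expect_equal(p1$free$node, rep("NFkB", 5L))
  expect_equal(p1$free$predictor, 1:5)

  b2 <- case_study2()
  p2 <- assemble_problem(b2$pbn, b2$experiments, "continuous")
  expect_equal(p2$k, 4L)

  expect_error(assemble_problem(b1$pbn, list(), "discrete"), "at least one")
  fixed <- b1$truth_pbn
  expect_error(assemble_problem(fixed, b1$experiments, "discrete"), "no free")
  bad <- experiment("x", c(PI3K = 1), c(PI3K = 0, NFkB = 1))
  expect_error(assemble_problem(b1$pbn, list(bad), "discrete"), "conflicting")
  unknown <- experiment("y", c(PI3K = 1), c(Zz = 1))
  expect_error(assemble_problem(b1$pbn, list(unknown), "discrete"), "not in the PBN")
})

test_that("discrete decoding splits the mass equally over selected rules", {
  p1 <- assemble_problem(case_study1()$pbn, case_study1()$experiments,
                         "discrete")
  expect_equal(unname(decode_discrete(c(0, 1, 0, 0, 0), p1)),
               c(0, 1, 0, 0, 0))
  expect_equal(unname(decode_discrete(c(0, 1, 0, 1, 1), p1)),
               c(0, 1 / 3, 0, 1 / 3, 1 / 3))
  empty <- decode_discrete(c(0, 0, 0, 0, 0), p1)
  expect_true(attr(empty, "invalid"))
  expect_equal(sse_cost(empty, p1), Inf)
})

test_that("continuous decoding normalises per node with a uniform fallback", {
  p2 <- assemble_problem(case_study2()$pbn, case_study2()$experiments,
                         "continuous")
  expect_equal(unname(decode_continuous(c(0.3, 0.1, 0.2, 0), p2)),
               c(0.5, 1 / 6, 1 / 3, 0))
  expect_equal(unname(decode_continuous(c(1, 1, 1, 1), p2)), rep(0.25, 4))
  expect_warning(cz <- decode_continuous(c(0, 0, 0, 0), p2), "all-zero")
  expect_equal(unname(cz), rep(0.25, 4))
  expect_error(decode_continuous(c(2, 0, 0, 0), p2), "\\[0, 1\\]")
})

test_that("generating parameters reproduce their own data at zero cost", {
  b2 <- case_study2()
  p2 <- assemble_problem(b2$pbn, b2$experiments, "continuous")
  truth_vec <- unlist(b2$truth)
  expect_lt(sse_cost(setNames(truth_vec, p2$free$param), p2, "exact"), 1e-18)
  # any decoded candidate stays within the trivial bounds
  set.seed(1)
  for (i in 1:5) {
    cv <- decode_continuous(runif(4), p2)
    cost <- sse_cost(cv, p2, "exact")
    expect_gte(cost, 0)
    expect_lte(cost, length(p2$experiments))
  }
})

test_that("simulation-backend costs approach the exact cost as r shrinks", {
  b2 <- case_study2()
  truth_vec <- unlist(b2$truth)
  rs <- c(0.05, 0.025, 0.01)
  for (i in seq_along(rs)) {
    p2 <- assemble_problem(b2$pbn, b2$experiments, "continuous",
                           settings = convergence_settings(r = rs[i]))
    cv <- setNames(truth_vec, p2$free$param)
    cost <- sse_cost(cv, p2, "simulation", seed = 42 + i)
    # exact cost is 0; each of the 4 estimates errs by ~r at confidence s
    expect_lte(cost, 4 * (2 * rs[i])^2)
  }
})

test_that("exhaustive discrete search identifies the AND gate uniquely", {
  b1 <- case_study1()
  p1 <- assemble_problem(b1$pbn, b1$experiments, "discrete")
  fit <- fit_pbn(p1, backend = "exact")
  expect_equal(fit$method, "exhaustive")
  expect_equal(nrow(fit$samples), 2^5)
  zero <- fit$samples[fit$samples$cost < 1e-12, ]
  expect_equal(nrow(zero), 1L)
  expect_equal(unname(unlist(zero[, p1$free$param])), c(0, 1, 0, 0, 0))
})

test_that("the genetic bit search matches the exhaustive optimum", {
  b1 <- case_study1()
  p1 <- assemble_problem(b1$pbn, b1$experiments, "discrete")
  eval_ga <- pbnfit:::ga_bits(function(b)
    sse_cost(decode_discrete(b, p1), p1, "exact"), 5L, budget = 300L,
    seed = 3)
  expect_equal(min(eval_ga$cost), 0)
  best <- eval_ga$raw[which.min(eval_ga$cost), ]
  expect_equal(best, c(0L, 1L, 0L, 0L, 0L))
})

test_that("differential evolution recovers the continuous generating weights", {
  b2 <- case_study2()
  p2 <- assemble_problem(b2$pbn, b2$experiments, "continuous")
  fit <- suppressWarnings(fit_pbn(p2, budget = 2000, seed = 2,
                                  backend = "exact"))
  expect_equal(fit$method, "differential_evolution")
  expect_lt(fit$best$cost, 1e-4)
  expect_equal(unname(fit$best$par), c(0.6, 0, 0.4, 0), tolerance = 0.05)
  # the recorded samples are ranked consistently with their costs
  expect_equal(fit$best$cost, min(fit$samples$cost))
})

test_that("per-experiment consistency reproduces the equal-split table", {
  b1 <- case_study1()
  p1 <- assemble_problem(b1$pbn, b1$experiments, "discrete")
  cc <- discrete_consistency(p1)
  probs <- matrix(cc$prob, nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(unname(probs["A", ]), rep(0.2, 5))
  expect_equal(unname(probs["B", ]), c(0, 1/3, 0, 1/3, 1/3))
  expect_equal(unname(probs["C", ]), c(0, 1/3, 1/3, 0, 1/3))
  expect_equal(unname(probs["D", ]), c(0.25, 0.25, 0.25, 0.25, 0))
})

test_that("re-simulation reports per-condition errors matching the cost", {
  b2 <- case_study2()
  p2 <- assemble_problem(b2$pbn, b2$experiments, "continuous")
  truth_vec <- setNames(unlist(b2$truth), p2$free$param)
  tab <- resimulate(truth_vec, p2, backend = "exact")
  expect_equal(nrow(tab), 4L)
  expect_equal(attr(tab, "total"), sse_cost(truth_vec, p2, "exact"))
  # stochastic re-simulation wobbles by at most a few precision widths
  t1 <- resimulate(truth_vec, p2, backend = "simulation", seed = 11)
  t2 <- resimulate(truth_vec, p2, backend = "simulation", seed = 12)
  expect_lt(abs(attr(t1, "total") - attr(t2, "total")), 4 * 0.025)
})

test_that("experiment files round-trip through JSON", {
  b3 <- case_study3()
  path <- withr::local_tempfile(fileext = ".json")
  write_experiments(b3$experiments, path)
  back <- read_experiments(path)
  expect_length(back, 6L)
  expect_equal(back[[4L]]$clamps, b3$experiments[[4L]]$clamps)
  expect_equal(back[[4L]]$measurements, b3$experiments[[4L]]$measurements)
})
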