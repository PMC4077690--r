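test_that("single rules parse to the expected predictors", {
  r <- parse_rule("N3 = N1 : 0.6")
  expect_equal(r$target, "N3")
  expect_equal(r$parents, "N1")
  expect_equal(r$table, c(0L, 1L))
  expect_equal(r$prob, 0.6)
  expect_false(r$free)

  r2 <- parse_rule("N3 = N1 & ~N2 : 0.4")
  expect_equal(r2$parents, c("N1", "N2"))
  # rows: (N1,N2) = (0,0), (1,0), (0,1), (1,1), first parent least significant
  expect_equal(r2$table, c(0L, 1L, 0L, 0L))

  rc <- parse_rule("X = 0")
  expect_equal(rc$parents, character(0))
  expect_equal(rc$table, 0L)
  expect_equal(rc$prob, 1.0)

  rf <- parse_rule("Y = A | B : ?")
  expect_true(rf$free)
  expect_true(is.na(rf$prob))
  expect_equal(rf$table, c(0L, 1L, 1L, 1L))
})

test_that("operator precedence and parentheses evaluate correctly", {
  # & binds tighter than |
  r <- parse_rule("Z = A | B & C")
  tt <- r$table
  for (idx in 0:7) {
    b <- (idx %/% 2^(0:2)) %% 2
    expect_equal(tt[idx + 1], as.integer(b[1] == 1 || (b[2] == 1 && b[3] == 1)))
  }
  r2 <- parse_rule("Z = (A | B) & C")
  for (idx in 0:7) {
    b <- (idx %/% 2^(0:2)) %% 2
    expect_equal(r2$table[idx + 1],
                 as.integer((b[1] == 1 || b[2] == 1) && b[3] == 1))
  }
  r3 <- parse_rule("Z = ~(A & B)")
  expect_equal(r3$table, c(1L, 1L, 1L, 0L))
})

test_that("syntax errors report position and cause", {
  expect_error(parse_rule("N3 = "), "empty expression|unexpected end")
  expect_error(parse_rule("N3 N1"), "expected '='")
  expect_error(parse_rule("N3 = N1 & "), "unexpected end")
  expect_error(parse_rule("N3 = (N1 | N2"), "expected '\\)'")
  expect_error(parse_rule("N3 = N1 : 1.5"), "outside")
  expect_error(parse_rule("N3 = N1 $ N2"), "column 9")
  expect_error(parse_rule("N3 = 2"), "only literals 0/1")
  expect_error(parse_rule(""), "empty rule")
})

test_that("build_pbn assembles nodes, inputs and function sets", {
  pbn <- fig_model()
  expect_s3_class(pbn, "pbn")
  expect_equal(pbn$nodes, c("N1", "N2", "N3"))
  expect_equal(pbn$inputs, c("N1", "N2"))
  expect_equal(length(pbn$function_sets$N3$predictors), 2L)
  expect_equal(pbn$function_sets$N3$probs, c(0.6, 0.4))

  # five free candidate rules for one node
  free5 <- build_pbn(c("N = A | B : ?", "N = A & B : ?", "N = A : ?",
                       "N = B : ?", "N = 0 : ?"))
  expect_equal(length(free5$function_sets$N$predictors), 5L)
  expect_true(all(free5$function_sets$N$free))

  # single fixed rule per node: ordinary Boolean network, probability 1
  bn <- build_pbn(c("B = A", "C = A & B"))
  expect_equal(bn$function_sets$B$probs, 1)

  # comments and blank lines ignored
  pbn2 <- build_pbn(c("# comment", "", "N3 = N1 : 0.6",
                      "N3 = N1 & ~N2 : 0.4  # inline"))
  expect_equal(pbn2$nodes, pbn$nodes)
})

test_that("build_pbn validates probabilities and duplicates", {
  expect_error(build_pbn(c("A = B : 0.5", "A = ~B : 0.4")), "sum to 0.9")
  expect_error(build_pbn(c("A = B : 0.5", "A = ~B : ?")), "all fixed or all free")
  expect_error(build_pbn(c("A = B : 0.5", "A = B : 0.5")), "duplicate")
  # feedback is allowed
  expect_s3_class(build_pbn(c("A = B", "B = ~A")), "pbn")
})

test_that("mixture truth table reproduces the example model", {
  pbn <- fig_model()
  tt <- truth_table(pbn, "N3")
  get <- function(n1, n2) tt$prob[tt$N1 == n1 & tt$N2 == n2]
  expect_equal(get(1, 1), 0.6)
  expect_equal(get(1, 0), 1.0)
  expect_equal(get(0, 0), 0.0)
  expect_equal(get(0, 1), 0.0)
  expect_error(truth_table(pbn, "N1"), "input")
})

test_that("truth-table probabilities are affine in the selection weights", {
  for (x in c(0, 0.25, 0.7, 1)) {
    pbn <- build_pbn(c(sprintf("N3 = N1 : %g", x),
                       sprintf("N3 = N1 & ~N2 : %g", 1 - x)))
    tt <- truth_table(pbn, "N3")
    expect_true(all(tt$prob >= 0 & tt$prob <= 1))
    expect_equal(tt$prob[tt$N1 == 1 & tt$N2 == 1], x)
  }
})

test_that("serialised rules re-parse to identical truth tables", {
  models <- c(list(fig_model()),
              lapply(1:5, function(s) random_pbn(4, seed = s)))
  for (pbn in models) {
    back <- build_pbn(pbn_rules(pbn), p = pbn$p, nodes = pbn$nodes)
    for (nd in names(pbn$function_sets))
      expect_equal(truth_table(back, nd), truth_table(pbn, nd))
  }
})

test_that("fixed per-node probabilities always sum to one", {
  for (s in 1:10) {
    pbn <- random_pbn(5, seed = 100 + s)
    for (fs in pbn$function_sets)
      expect_lt(abs(sum(fs$probs) - 1), 1e-9)
  }
})

test_that("rule files round-trip through disk", {
  pbn <- fig_model()
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(pbn_rules(pbn), path)
  back <- read_pbn(path)
  expect_equal(truth_table(back, "N3"), truth_table(pbn, "N3"))
})
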