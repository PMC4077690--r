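## ---------------------------------------------------------------------------
## Bundled case-study generators.  Each bundle carries the candidate-rule
## template (free probabilities), the generating ("truth") probabilities, and
## experimental conditions whose measured values are computed from the exact
## stationary marginals of the truth model in the p = 0 limit -- so the
## fixtures are self-consistent with the exact-chain oracle by construction.
## ---------------------------------------------------------------------------

make_bundle <- function(name, rules, truth, experiments, mode) {
  template <- build_pbn(rules)
  truth_pbn <- set_selection_probs(template, truth)
  exps <- lapply(experiments, function(e) {
    meas <- exact_marginal(truth_pbn, e$measured, clamps = e$clamps, p = 0)
    experiment(e$name, e$clamps, meas)
  })
  structure(list(name = name, rules = rules, pbn = template,
                 truth = truth, truth_pbn = truth_pbn,
                 experiments = exps, mode = mode),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("Case study '%s' (%s mode): %d candidate rules, %d experiments\n",
              x$name, x$mode, sum(pbn_l(x$pbn)), length(x$experiments)))
  invisible(x)
}

#' Case study: Boolean rule identification (discrete mode)
#'
#' Three-node network with inputs PI3K and TNFa and five candidate rules for
#' NFkB (OR, AND, PI3K alone, TNFa alone, constant 0).  The generating
#' network uses the AND rule only; the four conditions clamp the inputs to
#' (0,0), (1,0), (0,1) and (1,1) with NFkB measured at the corresponding
#' exact steady state (0, 0, 0, 1).  Fitting all four conditions in discrete
#' mode identifies the AND gate as the unique zero-cost rule; individual
#' conditions admit several consistent rules that share the probability mass
#' equally.
#'
#' @return a `case_study` bundle: `rules`, `pbn` (template with free
#'   probabilities), `truth`, `truth_pbn`, `experiments`, `mode`.
#' @export
case_study1 <- function() {
  rules <- c(
    "NFkB = PI3K | TNFa : ?",
    "NFkB = PI3K & TNFa : ?",
    "NFkB = PI3K : ?",
    "NFkB = TNFa : ?",
    "NFkB = 0 : ?")
  truth <- list(NFkB = c(0, 1, 0, 0, 0))
  exps <- list(
    list(name = "A", clamps = c(PI3K = 0, TNFa = 0), measured = "NFkB"),
    list(name = "B", clamps = c(PI3K = 1, TNFa = 0), measured = "NFkB"),
    list(name = "C", clamps = c(PI3K = 0, TNFa = 1), measured = "NFkB"),
    list(name = "D", clamps = c(PI3K = 1, TNFa = 1), measured = "NFkB"))
  make_bundle("rule identification", rules, truth, exps, "discrete")
}

#' Case study: selection-probability inference (continuous mode)
#'
#' Regulation of PIP3 by PI3K (activator) and PTEN (partial inhibitor): four
#' candidate rules (PI3K alone, PTEN alone, PI3K & ~PTEN, constant 0) with
#' generating probabilities (0.6, 0, 0.4, 0).  The four conditions clamp
#' (PI3K, PTEN) to (0,0), (1,0), (0,1), (1,1); the measured PIP3 values are
#' the exact stationary marginals 0, 1, 0, 0.6.  Fitting all four conditions
#' recovers the generating weights; fitting only conditions A and D leaves a
#' non-identifiable ridge `c_PI3K + c_PTEN = 0.6`.
#'
#' @return a `case_study` bundle, see [case_study1()].
#' @export
case_study2 <- function() {
  rules <- c(
    "PIP3 = PI3K : ?",
    "PIP3 = PTEN : ?",
    "PIP3 = PI3K & ~PTEN : ?",
    "PIP3 = 0 : ?")
  truth <- list(PIP3 = c(0.6, 0, 0.4, 0))
  exps <- list(
    list(name = "A", clamps = c(PI3K = 0, PTEN = 0), measured = "PIP3"),
    list(name = "B", clamps = c(PI3K = 1, PTEN = 0), measured = "PIP3"),
    list(name = "C", clamps = c(PI3K = 0, PTEN = 1), measured = "PIP3"),
    list(name = "D", clamps = c(PI3K = 1, PTEN = 1), measured = "PIP3"))
  make_bundle("selection-probability inference", rules, truth, exps,
              "continuous")
}

#' Case study: weighted signal flows with inhibitors (continuous mode)
#'
#' Eight-node signalling toy model: inputs TGFa and TNFa, inhibitor inputs
#' PI3Ki and Rafi, intermediates PI3K and Raf (activated by TGFa, inhibited
#' at 70% efficacy by their inhibitor), and outputs NFkB and ERK with free
#' branch weights.  NFkB receives disjoint activating signals from PI3K
#' (generating weight 0.7) and TNFa (0.3); ERK from Raf (0.6) and NFkB
#' (0.4).  Inhibition is realised inside the fixed PBN: the inhibited node
#' has predictors `source & ~inhibitor` with probability 0.7 (the efficacy)
#' and `source` with probability 0.3, so the inhibited steady-state activity
#' is reduced to 30% of the source signal.  Six conditions (A: TGFa; B:
#' TNFa; C: both; D: both + PI3K inhibitor; E: both + Raf inhibitor; F:
#' none) measure PI3K, Raf, NFkB and ERK at their exact stationary
#' marginals; under condition D the NFkB activity is
#' `0.3 * 0.7 + 0.3 = 0.51`.
#'
#' @return a `case_study` bundle, see [case_study1()].
#' @export
case_study3 <- function() {
  rules <- c(
    "PI3K = TGFa & ~PI3Ki : 0.7",
    "PI3K = TGFa : 0.3",
    "Raf = TGFa & ~Rafi : 0.7",
    "Raf = TGFa : 0.3",
    "NFkB = PI3K : ?",
    "NFkB = TNFa : ?",
    "ERK = Raf : ?",
    "ERK = NFkB : ?")
  truth <- list(NFkB = c(0.7, 0.3), ERK = c(0.6, 0.4))
  base <- c(TGFa = 0, PI3Ki = 0, Rafi = 0, TNFa = 0)
  cond <- function(name, on) {
    cl <- base
    cl[on] <- 1
    list(name = name, clamps = cl, measured = c("PI3K", "Raf", "NFkB", "ERK"))
  }
  exps <- list(
    cond("A", "TGFa"),
    cond("B", "TNFa"),
    cond("C", c("TGFa", "TNFa")),
    cond("D", c("TGFa", "TNFa", "PI3Ki")),
    cond("E", c("TGFa", "TNFa", "Rafi")),
    cond("F", character(0)))
  make_bundle("weighted signal flows", rules, truth, exps, "continuous")
}

#' Printed steady-state table of the apoptosis benchmark
#'
#' The published steady-state activities of the three output nodes
#' (Apoptosis, the p17 fragment of active Caspase 3, NFkB) across six
#' conditions, for the original Boolean model (`orig`), the initial and
#' extended PBN variants (`init`, `ext`) and the normalised measurements
#' (`meas`).  Used only for the SSE arithmetic between printed columns; the
#' underlying 96-node model is not reconstructed.
#'
#' @return data.frame with 18 rows (condition x output) and the four value
#'   columns.
#' @export
table5_data <- function() {
  conditions <- c("Mock", "FasL(2)", "IL-1", "TNF", "UV1", "UV2")
  out <- rbind(
    data.frame(condition = conditions, output = "Apoptosis",
               orig = c(0, 1, 0, 0, 1, 0),
               init = c(0.0000, 0.9208, 0.0028, 0.0020, 0.9920, 0.4681),
               ext  = c(0.0054, 0.7170, 0.0063, 0.0018, 0.9868, 0.4914),
               meas = c(0.00, 0.63, 0.00, 0.10, 1.00, 0.49)),
    data.frame(condition = conditions, output = "C3ap17",
               orig = c(0, 1, 0, 0, 1, 0),
               init = c(0.0168, 0.9505, 0.0042, 0.4073, 0.9966, 0.0016),
               ext  = c(0.0082, 0.8491, 0.0013, 0.4049, 0.9901, 0.0012),
               meas = c(0.00, 1.00, 0.03, 0.39, 1.00, 0.00)),
    data.frame(condition = conditions, output = "NFkB",
               orig = c(0, 0, 1, 1, 0, 1),
               init = c(0.0168, 0.0198, 0.8873, 0.7889, 0.0023, 0.3083),
               ext  = c(0.0027, 0.1501, 0.8481, 0.8723, 0.0033, 0.2932),
               meas = c(0.00, 0.32, 1.00, 0.98, 0.26, 0.46)))
  rownames(out) <- NULL
  out
}

#' SSE between a model column and the measurements of the apoptosis table
#'
#' @param model one of `"orig"`, `"init"`, `"ext"`.
#' @param data the table from [table5_data()] (supplied for testing).
#' @return sum of squared errors against the `meas` column.
#' @export
table5_sse <- function(model = c("orig", "init", "ext"), data = table5_data()) {
  model <- match.arg(model)
  sum((data[[model]] - data$meas)^2)
}

## Sum-of-minterms expression text for a truth table over given parents
## (first parent = least significant bit of the row index).
minterm_expression <- function(parents, table) {
  ones <- which(table == 1L) - 1L
  if (length(ones) == 0L) return("0")
  if (length(ones) == 2^length(parents)) return("1")
  terms <- vapply(ones, function(idx) {
    bits <- (idx %/% 2^(seq_along(parents) - 1L)) %% 2L
    paste(ifelse(bits == 1L, parents, paste0("~", parents)), collapse = " & ")
  }, "")
  paste(terms, collapse = " | ")
}

#' Generate a random PBN for property tests
#'
#' Random networks with 2 to 10 nodes, every node carrying 1 to `max_rules`
#' predictors over random parent sets of at most 3 parents (self-loops and
#' feedback allowed) with uniformly random truth tables, and Dirichlet(1)
#' selection probabilities.  Rules are materialised as sum-of-minterms
#' expressions so the model serialises and re-parses exactly.  Reproducible
#' by seed.
#'
#' @param n_nodes number of nodes (2..10).
#' @param max_rules maximum predictors per node.
#' @param seed optional RNG seed.
#' @param p perturbation probability of the returned PBN.
#' @return a validated `pbn`.
#' @export
random_pbn <- function(n_nodes, max_rules = 3L, seed = NULL, p = 0.001) {
  stopifnot(n_nodes >= 2, n_nodes <= 10, max_rules >= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("X", seq_len(n_nodes))
  lines <- character(0)
  for (nd in nodes) {
    l <- sample.int(max_rules, 1L)
    probs <- rgamma(l, 1)
    probs <- probs / sum(probs)
    exprs <- character(0)
    sigs <- character(0)
    tries <- 0L
    while (length(exprs) < l && tries < 100L) {
      tries <- tries + 1L
      k <- sample.int(3L, 1L)
      pars <- sample(nodes, k)
      tab <- as.integer(runif(2^k) < 0.5)
      r <- parse_rule(paste(nd, "=", minterm_expression(pars, tab)))
      sig <- paste(paste(r$parents, collapse = ","),
                   paste(r$table, collapse = ""), sep = "|")
      if (sig %in% sigs) next
      sigs <- c(sigs, sig)
      exprs <- c(exprs, minterm_expression(pars, tab))
    }
    probs <- probs[seq_along(exprs)] / sum(probs[seq_along(exprs)])
    lines <- c(lines, sprintf("%s = %s : %.17g", nd, exprs, probs))
  }
  build_pbn(lines, p = p, nodes = nodes)
}

#' Write a case-study bundle to disk
#'
#' Writes the rule file (`rules.txt`), the experiment conditions
#' (`experiments.json`) and the measured data (`data.csv`) of a bundle.
#'
#' @param bundle a `case_study` from [case_study1()], [case_study2()] or
#'   [case_study3()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_case_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(bundle$rules, file.path(dir, "rules.txt"))
  writeLines(pbn_rules(bundle$truth_pbn), file.path(dir, "rules_truth.txt"))
  write_experiments(bundle$experiments, file.path(dir, "experiments.json"))
  rows <- do.call(rbind, lapply(bundle$experiments, function(e)
    data.frame(experiment = e$name, node = names(e$measurements),
               value = as.numeric(e$measurements), row.names = NULL)))
  write.csv(rows, file.path(dir, "data.csv"), row.names = FALSE)
  invisible(dir)
}
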