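## ---------------------------------------------------------------------------
## Multi-experiment optimisation: SSE objective over steady-state marginals,
## discrete (rule-subset) and continuous (simplex) parameter decoding, and
## pluggable optimisers (exhaustive / genetic bit search, differential
## evolution).
## ---------------------------------------------------------------------------

#' Define an experimental condition
#'
#' A named condition with input-node clamps and measured steady-state values
#' (normalised to `[0, 1]`).
#'
#' @param name condition label.
#' @param clamps named 0/1 vector of input-node values.
#' @param measurements named numeric vector of measured node activities in
#'   `[0, 1]`.
#' @return a `pbn_experiment` object.
#' @export
experiment <- function(name, clamps, measurements) {
  clamps <- unlist(clamps)
  measurements <- unlist(measurements)
  stopifnot(is.character(name), length(name) == 1L,
            length(measurements) >= 1L, !is.null(names(measurements)))
  if (!all(clamps %in% c(0, 1)))
    stop("clamp values must be 0 or 1", call. = FALSE)
  if (any(measurements < 0 | measurements > 1))
    stop("measurements must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, clamps = clamps, measurements = measurements),
            class = "pbn_experiment")
}

#' Read experiment conditions from a JSON or YAML file
#'
#' The file holds a list of objects with fields `name`, `clamps` (node -> 0/1)
#' and `measurements` (node -> value in `[0, 1]`).
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return list of `pbn_experiment` objects.
#' @export
read_experiments <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  lapply(raw, function(e)
    experiment(e$name, unlist(e$clamps), unlist(e$measurements)))
}

#' Write experiment conditions to a JSON file
#'
#' @param experiments list of `pbn_experiment` objects.
#' @param path output path.
#' @export
write_experiments <- function(experiments, path) {
  jsonlite::write_json(
    lapply(experiments, function(e)
      list(name = e$name, clamps = as.list(e$clamps),
           measurements = as.list(e$measurements))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Assemble a multi-experiment optimisation problem
#'
#' Combines a PBN template with free selection probabilities and a set of
#' experimental conditions into one problem whose objective is the sum of
#' squared errors between estimated steady-state marginals and measurements
#' over all conditions.  Free parameters are ordered by node declaration
#' order, then predictor order.
#'
#' @param pbn a `pbn` with at least one free (`?`) selection probability.
#' @param experiments non-empty list of [experiment()] conditions.
#' @param mode `"discrete"` (rule subsets, equal split) or `"continuous"`
#'   (per-node simplex weights).
#' @param settings [convergence_settings()] used by the simulation backend.
#' @return a `pbn_problem` with fields `pbn`, `free` (parameter table),
#'   `experiments`, `mode`, `settings`, `k`.
#' @export
assemble_problem <- function(pbn, experiments,
                             mode = c("continuous", "discrete"),
                             settings = convergence_settings()) {
  stopifnot(inherits(pbn, "pbn"))
  mode <- match.arg(mode)
  if (inherits(experiments, "pbn_experiment")) experiments <- list(experiments)
  if (length(experiments) == 0L)
    stop("at least one experiment is required", call. = FALSE)
  stopifnot(all(vapply(experiments, inherits, TRUE, "pbn_experiment")))
  if (!has_free_params(pbn))
    stop("PBN has no free selection probabilities to optimise", call. = FALSE)

  free <- do.call(rbind, lapply(names(pbn$function_sets), function(nd) {
    fs <- pbn$function_sets[[nd]]
    wh <- which(fs$free)
    if (length(wh) == 0L) return(NULL)
    data.frame(node = nd, predictor = wh,
               param = paste0(nd, ".", wh),
               rule = vapply(fs$predictors[wh], `[[`, "", "source_text"),
               stringsAsFactors = FALSE)
  }))

  for (e in experiments) {
    check_clamps(pbn, e$clamps)
    unknown <- setdiff(names(e$measurements), pbn$nodes)
    if (length(unknown) > 0L)
      stop(sprintf("experiment '%s': measured node(s) %s not in the PBN",
                   e$name, paste(unknown, collapse = ", ")), call. = FALSE)
    both <- intersect(names(e$measurements), names(e$clamps))
    bad <- both[e$measurements[both] != e$clamps[both]]
    if (length(bad) > 0L)
      stop(sprintf(
        "experiment '%s': node(s) %s measured at a value conflicting with their clamp",
        e$name, paste(bad, collapse = ", ")), call. = FALSE)
  }

  structure(list(pbn = pbn, free = free, experiments = experiments,
                 mode = mode, settings = settings, k = nrow(free)),
            class = "pbn_problem")
}

decoded_by_node <- function(problem, c_vec) {
  split(setNames(c_vec, problem$free$param), problem$free$node)
}

#' Decode a discrete candidate (rule subset) into selection probabilities
#'
#' Selected predictors (bit 1) of each node share the probability mass
#' equally (`1/k` for `k` selected); unselected predictors get 0.  A node
#' with no selected predictor makes the candidate invalid (scored `+Inf` by
#' [sse_cost()], not repaired).
#'
#' @param bits 0/1 vector aligned to the problem's free-parameter order.
#' @param problem a `pbn_problem`.
#' @return numeric vector of selection probabilities named by parameter, with
#'   attribute `invalid = TRUE` when some node selects no rule.
#' @export
decode_discrete <- function(bits, problem) {
  stopifnot(inherits(problem, "pbn_problem"), length(bits) == problem$k)
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L)))
    stop("discrete candidates must be 0/1 vectors", call. = FALSE)
  out <- numeric(problem$k)
  invalid <- FALSE
  for (grp in split(seq_len(problem$k), problem$free$node)) {
    ksel <- sum(bits[grp])
    if (ksel == 0L) invalid <- TRUE else out[grp] <- bits[grp] / ksel
  }
  names(out) <- problem$free$param
  if (invalid) attr(out, "invalid") <- TRUE
  out
}

#' Decode a continuous candidate into selection probabilities
#'
#' Per node, the raw box-constrained variables in `[0, 1]` are normalised to
#' sum to 1; an all-zero node falls back to the uniform distribution (with a
#' warning).
#'
#' @param raw numeric vector in `[0, 1]^k` aligned to the free-parameter
#'   order.
#' @param problem a `pbn_problem`.
#' @return numeric vector of selection probabilities named by parameter.
#' @export
decode_continuous <- function(raw, problem) {
  stopifnot(inherits(problem, "pbn_problem"), length(raw) == problem$k)
  if (any(raw < 0 | raw > 1))
    stop("raw continuous candidates must lie in [0, 1]", call. = FALSE)
  out <- numeric(problem$k)
  for (grp in split(seq_len(problem$k), problem$free$node)) {
    s <- sum(raw[grp])
    if (s == 0) {
      warning(sprintf("node '%s': all-zero raw weights, using uniform probabilities",
                      problem$free$node[grp[1L]]), call. = FALSE)
      out[grp] <- 1 / length(grp)
    } else {
      out[grp] <- raw[grp] / s
    }
  }
  names(out) <- problem$free$param
  out
}

derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) * 48271 + a * 7919 + b * 104729) %% 2147483647)
}

#' Sum-of-squared-errors cost of decoded selection probabilities
#'
#' For each experiment, clamps the inputs, obtains the steady-state marginal
#' of every measured node and accumulates the squared deviation from the
#' measurement.  The `"exact"` backend solves the p = 0 stationary
#' distribution of each clamped subchain (small networks); the
#' `"simulation"` backend runs the two-state protocol of
#' [estimate_marginals_multi()] with one shared trajectory per experiment.
#'
#' @param c_vec decoded selection probabilities (from [decode_discrete()] or
#'   [decode_continuous()]); an invalid discrete candidate returns `+Inf`.
#' @param problem a `pbn_problem`.
#' @param backend `"exact"` or `"simulation"`.
#' @param seed base seed for the simulation backend; per-experiment seeds are
#'   derived deterministically from it.
#' @return non-negative cost (at most the number of measurements).
#' @export
sse_cost <- function(c_vec, problem, backend = c("exact", "simulation"),
                     seed = NULL) {
  stopifnot(inherits(problem, "pbn_problem"))
  backend <- match.arg(backend)
  if (isTRUE(attr(c_vec, "invalid"))) return(Inf)
  fitted <- set_selection_probs(problem$pbn, decoded_by_node(problem, c_vec))
  cost <- 0
  for (ei in seq_along(problem$experiments)) {
    e <- problem$experiments[[ei]]
    nodes <- names(e$measurements)
    est <- if (backend == "exact") {
      exact_marginal(fitted, nodes, clamps = e$clamps, p = 0)
    } else {
      if (!is.null(seed)) set.seed(derive_seed(seed, ei))
      diags <- tryCatch(
        estimate_marginals_multi(fitted, nodes, clamps = e$clamps,
                                 settings = problem$settings),
        error = function(err)
          stop(sprintf("experiment '%s': %s", e$name, conditionMessage(err)),
               call. = FALSE))
      vapply(diags, `[[`, 0, "estimate")
    }
    cost <- cost + sum((est - e$measurements)^2)
  }
  cost
}

## ---- optimisers -----------------------------------------------------------

## Differential evolution (rand/1/bin) over [0,1]^k, recording every
## evaluated candidate.  Returns list(raw = matrix, cost = vector).
de_minimise <- function(fn, k, budget, NP = max(20L, 10L * k), F = 0.8,
                        CR = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  NP <- min(NP, budget)
  X <- matrix(runif(NP * k), NP, k)
  cost <- apply(X, 1L, fn)
  raw_all <- X
  cost_all <- cost
  evals <- NP
  while (evals < budget) {
    for (i in seq_len(NP)) {
      if (evals >= budget) break
      r <- sample(setdiff(seq_len(NP), i), 3L)
      v <- X[r[1L], ] + F * (X[r[2L], ] - X[r[3L], ])
      v <- pmin(pmax(v, 0), 1)
      jrand <- sample.int(k, 1L)
      cross <- runif(k) < CR
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, X[i, ])
      cu <- fn(u)
      evals <- evals + 1L
      raw_all <- rbind(raw_all, u)
      cost_all <- c(cost_all, cu)
      if (cu <= cost[i]) {
        X[i, ] <- u
        cost[i] <- cu
      }
    }
  }
  list(raw = raw_all, cost = cost_all)
}

## Exhaustive enumeration of all 0/1 candidate vectors.
exhaustive_bits <- function(fn, k) {
  S <- 2^k
  raw <- matrix(0L, S, k)
  cost <- numeric(S)
  for (idx in seq_len(S) - 1L) {
    bits <- as.integer((idx %/% 2^(seq_len(k) - 1L)) %% 2L)
    raw[idx + 1L, ] <- bits
    cost[idx + 1L] <- fn(bits)
  }
  list(raw = raw, cost = cost)
}

## Small generational GA over bit strings (tournament selection, uniform
## crossover, per-bit mutation, elitism), for discrete problems too large to
## enumerate.
ga_bits <- function(fn, k, budget, NP = 50L, pmut = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pmut)) pmut <- 1 / k
  NP <- min(NP, budget)
  X <- matrix(as.integer(runif(NP * k) < 0.5), NP, k)
  cost <- apply(X, 1L, fn)
  raw_all <- X
  cost_all <- cost
  evals <- NP
  while (evals < budget) {
    elite <- X[which.min(cost), , drop = FALSE]
    newX <- elite
    while (nrow(newX) < NP) {
      pick <- function() {
        cand <- sample.int(NP, 2L)
        X[cand[which.min(cost[cand])], ]
      }
      a <- pick(); b <- pick()
      child <- ifelse(runif(k) < 0.5, a, b)
      flip <- runif(k) < pmut
      child[flip] <- 1L - child[flip]
      newX <- rbind(newX, child)
    }
    X <- newX[seq_len(NP), , drop = FALSE]
    ncost <- apply(X, 1L, fn)
    take <- min(NP, budget - evals)
    raw_all <- rbind(raw_all, X[seq_len(take), , drop = FALSE])
    cost_all <- c(cost_all, ncost[seq_len(take)])
    cost <- ncost
    evals <- evals + take
  }
  list(raw = raw_all, cost = cost_all)
}

#' Fit the free selection probabilities of a PBN to experimental data
#'
#' Minimises the SSE objective of [sse_cost()].  In discrete mode all rule
#' subsets are enumerated exhaustively when there are at most `2^20`
#' candidates, otherwise a genetic bit-string search is used.  In continuous
#' mode differential evolution (rand/1/bin, `F = 0.8`, `CR = 0.9`) explores
#' the box `[0, 1]^k`, which is decoded per node onto the probability
#' simplex.  Every evaluated candidate is retained with its decoded
#' parameters and cost.
#'
#' @param problem a `pbn_problem`.
#' @param budget number of cost evaluations (ignored by the exhaustive
#'   search).
#' @param seed RNG seed (drives the optimiser and, for the simulation
#'   backend, the per-evaluation trajectory seeds).
#' @param backend `"exact"` or `"simulation"` marginals, see [sse_cost()].
#' @param NP population size for the evolutionary optimisers.
#' @return a `pbn_fit`: `samples` (data.frame with `iteration`, `cost` and
#'   one column per decoded parameter, ranked as evaluated), `best` (list
#'   with `par`, `cost`, `iteration`), `problem`, `method`.
#' @export
fit_pbn <- function(problem, budget = 5000L, seed = NULL,
                    backend = c("exact", "simulation"), NP = NULL) {
  stopifnot(inherits(problem, "pbn_problem"), budget >= 1)
  backend <- match.arg(backend)
  k <- problem$k
  eval_count <- 0L
  if (problem$mode == "discrete") {
    fn <- function(bits) {
      eval_count <<- eval_count + 1L
      sse_cost(decode_discrete(bits, problem), problem, backend,
               seed = if (is.null(seed)) NULL else derive_seed(seed, 0L, eval_count))
    }
    if (2^k <= 2^20) {
      res <- exhaustive_bits(fn, k)
      method <- "exhaustive"
    } else {
      res <- ga_bits(fn, k, budget, NP = if (is.null(NP)) 50L else NP,
                     seed = seed)
      method <- "genetic"
    }
    decode <- function(x) decode_discrete(x, problem)
  } else {
    fn <- function(raw) {
      eval_count <<- eval_count + 1L
      sse_cost(decode_continuous(raw, problem), problem, backend,
               seed = if (is.null(seed)) NULL else derive_seed(seed, 0L, eval_count))
    }
    res <- de_minimise(fn, k, budget, NP = if (is.null(NP)) max(20L, 10L * k) else NP,
                       seed = seed)
    method <- "differential_evolution"
    decode <- function(x) decode_continuous(x, problem)
  }

  dec <- do.call(rbind, lapply(seq_len(nrow(res$raw)), function(i)
    as.numeric(suppressWarnings(decode(res$raw[i, ])))))
  colnames(dec) <- problem$free$param
  samples <- data.frame(iteration = seq_along(res$cost), cost = res$cost)
  samples <- cbind(samples, as.data.frame(dec))
  ibest <- order(res$cost, samples$iteration)[1L]
  best <- list(par = setNames(dec[ibest, ], problem$free$param),
               cost = res$cost[ibest], iteration = ibest)
  structure(list(samples = samples, best = best, problem = problem,
                 method = method, backend = backend),
            class = "pbn_fit")
}

#' @export
print.pbn_fit <- function(x, ...) {
  cat(sprintf("PBN fit (%s, %s backend): %d evaluations, best cost %.6g\n",
              x$method, x$backend, nrow(x$samples), x$best$cost))
  print(round(x$best$par, 4))
  invisible(x)
}

#' Per-experiment rule consistency (discrete mode)
#'
#' For a discrete problem whose free parameters all belong to a single node,
#' scores each candidate rule alone against each experiment: a rule is
#' consistent with an experiment when the singleton PBN reproduces its
#' measurements exactly (zero cost).  Consistent rules share the probability
#' mass `1/k` per experiment, reproducing the equal-split reporting of the
#' discrete mode.
#'
#' @param problem a discrete-mode `pbn_problem` with one free node.
#' @param tol zero-cost tolerance.
#' @return data.frame: one row per (experiment, rule) with `consistent` and
#'   `prob` columns.
#' @export
discrete_consistency <- function(problem, tol = 1e-9) {
  stopifnot(inherits(problem, "pbn_problem"))
  if (length(unique(problem$free$node)) != 1L)
    stop("per-rule consistency is defined for a single free node", call. = FALSE)
  k <- problem$k
  out <- NULL
  for (e in problem$experiments) {
    sub <- assemble_problem(problem$pbn, list(e), mode = "discrete",
                            settings = problem$settings)
    costs <- vapply(seq_len(k), function(j) {
      bits <- integer(k); bits[j] <- 1L
      sse_cost(decode_discrete(bits, sub), sub, backend = "exact")
    }, 0)
    cons <- costs <= tol
    out <- rbind(out, data.frame(
      experiment = e$name, param = problem$free$param,
      rule = problem$free$rule, consistent = cons,
      prob = ifelse(cons, 1 / sum(cons), 0), row.names = NULL))
  }
  out
}

#' Re-simulate a fitted parameter set against the data
#'
#' Evaluates a decoded parameter vector (or the best sample of a fit) per
#' experiment and measured node, returning estimates, measurements and
#' squared errors.  With the simulation backend a fresh seed gives slightly
#' different estimates; the total matches [sse_cost()] exactly for the exact
#' backend.
#'
#' @param fit a `pbn_fit` or a decoded parameter vector.
#' @param problem the `pbn_problem` (taken from the fit when omitted).
#' @param backend `"exact"` or `"simulation"`.
#' @param seed seed for the simulation backend.
#' @return data.frame with columns `experiment`, `node`, `estimate`,
#'   `measured`, `sq_error`; total SSE in attribute `"total"`.
#' @export
resimulate <- function(fit, problem = NULL, backend = c("exact", "simulation"),
                       seed = NULL) {
  backend <- match.arg(backend)
  if (inherits(fit, "pbn_fit")) {
    if (is.null(problem)) problem <- fit$problem
    par <- fit$best$par
  } else {
    stopifnot(inherits(problem, "pbn_problem"))
    par <- fit
  }
  fitted <- set_selection_probs(problem$pbn, decoded_by_node(problem, par))
  rows <- NULL
  for (ei in seq_along(problem$experiments)) {
    e <- problem$experiments[[ei]]
    nodes <- names(e$measurements)
    est <- if (backend == "exact") {
      exact_marginal(fitted, nodes, clamps = e$clamps, p = 0)
    } else {
      if (!is.null(seed)) set.seed(derive_seed(seed, ei))
      vapply(estimate_marginals_multi(fitted, nodes, clamps = e$clamps,
                                      settings = problem$settings),
             `[[`, 0, "estimate")
    }
    rows <- rbind(rows, data.frame(
      experiment = e$name, node = nodes, estimate = as.numeric(est),
      measured = as.numeric(e$measurements),
      sq_error = as.numeric((est - e$measurements)^2), row.names = NULL))
  }
  attr(rows, "total") <- sum(rows$sq_error)
  rows
}
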