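## ---------------------------------------------------------------------------
## PBN dynamics: synchronous instantaneously-random update with per-node
## perturbation and input clamping.
## ---------------------------------------------------------------------------

check_clamps <- function(pbn, clamps, allow_internal = FALSE) {
  if (is.null(clamps) || length(clamps) == 0L) return(setNames(integer(0), character(0)))
  cl <- unlist(clamps)
  if (is.null(names(cl)) || any(!nzchar(names(cl))))
    stop("clamps must be a named vector/list of 0/1 values", call. = FALSE)
  if (!all(names(cl) %in% pbn$nodes))
    stop(sprintf("unknown clamped node(s): %s",
                 paste(setdiff(names(cl), pbn$nodes), collapse = ", ")),
         call. = FALSE)
  if (!all(cl %in% c(0, 1)))
    stop("clamp values must be 0 or 1", call. = FALSE)
  if (!allow_internal && !all(names(cl) %in% pbn$inputs))
    stop(sprintf(
      "clamping non-input node(s) %s requires allow_internal = TRUE",
      paste(setdiff(names(cl), pbn$inputs), collapse = ", ")), call. = FALSE)
  storage.mode(cl) <- "integer"
  cl
}

## Mixture probability table of a node over the union of its predictors'
## parents: pr1[idx] = P(next = 1 | parent assignment), idx with the first
## union-parent as least significant bit.
node_mixture <- function(fs) {
  if (any(fs$free))
    stop(sprintf("node '%s' has free selection probabilities", fs$node),
         call. = FALSE)
  parents <- unique(unlist(lapply(fs$predictors, `[[`, "parents")))
  k <- length(parents)
  if (k > 20L)
    stop(sprintf("node '%s': %d distinct parents exceed the supported limit",
                 fs$node, k), call. = FALSE)
  nr <- 2^k
  pr1 <- numeric(nr)
  for (idx in seq_len(nr) - 1L) {
    bits <- if (k > 0L) (idx %/% 2^(seq_len(k) - 1L)) %% 2L else integer(0)
    val <- 0
    for (j in seq_along(fs$predictors)) {
      pr <- fs$predictors[[j]]
      pidx <- if (length(pr$parents) > 0L) {
        b <- bits[match(pr$parents, parents)]
        1L + sum(b * 2^(seq_along(b) - 1L))
      } else 1L
      val <- val + fs$probs[j] * pr$table[pidx]
    }
    pr1[idx + 1L] <- val
  }
  list(parents = parents, pr1 = pr1)
}

## Precompute the flattened update tables used by the C stepper.
compile_dynamics <- function(pbn, clamps = NULL, allow_internal = FALSE) {
  cl <- check_clamps(pbn, clamps, allow_internal)
  n <- length(pbn$nodes)
  clamped <- pbn$nodes %in% names(cl)
  nonclamped <- which(!clamped)
  upd_nodes <- setdiff(setdiff(pbn$nodes, pbn$inputs), names(cl))
  upd <- match(upd_nodes, pbn$nodes)
  mix <- lapply(pbn$function_sets[upd_nodes], node_mixture)
  list(
    n = n, clamps = cl,
    nonclamped0 = as.integer(nonclamped - 1L),
    upd0 = as.integer(upd - 1L),
    parents0 = lapply(mix, function(m) as.integer(match(m$parents, pbn$nodes) - 1L)),
    weights = lapply(mix, function(m) as.integer(2^(seq_along(m$parents) - 1L))),
    pr1 = lapply(mix, `[[`, "pr1")
  )
}

apply_clamps <- function(pbn, state, cl) {
  if (length(cl) > 0L) state[match(names(cl), pbn$nodes)] <- cl
  state
}

random_initial_state <- function(pbn, cl) {
  state <- as.integer(runif(length(pbn$nodes)) < 0.5)
  apply_clamps(pbn, state, cl)
}

#' One synchronous update step of a PBN
#'
#' Per non-clamped node, an independent Bernoulli(p) flip indicator is drawn
#' first; if any indicator fires, the next state is the current state with
#' those bits flipped and the network function is not applied ("flip-wins").
#' Otherwise every non-input, non-clamped node takes the value of a predictor
#' drawn according to its selection probabilities, independently across nodes
#' (equivalently, a Bernoulli draw from the node's mixture probability);
#' unclamped input nodes hold their value.  Clamped nodes never change.
#'
#' @param pbn a `pbn` with all selection probabilities fixed.
#' @param state 0/1 vector aligned to `pbn$nodes`.
#' @param clamps named 0/1 vector of clamped input nodes.
#' @param allow_internal allow clamping non-input nodes.
#' @return the next state (0/1 vector with node names).
#' @export
pbn_step <- function(pbn, state, clamps = NULL, allow_internal = FALSE) {
  dyn <- compile_dynamics(pbn, clamps, allow_internal)
  state <- as.integer(state)
  if (length(state) != dyn$n)
    stop("state length does not match the number of nodes", call. = FALSE)
  state <- apply_clamps(pbn, state, dyn$clamps)
  res <- sim_steps_cpp(state, 1L, pbn$p, dyn$nonclamped0, dyn$upd0,
                       dyn$parents0, dyn$weights, dyn$pr1,
                       as.integer(seq_len(dyn$n) - 1L))
  setNames(as.integer(res$state), pbn$nodes)
}

#' Simulate a PBN trajectory
#'
#' Simulates `steps` synchronous transitions of the instantaneously random
#' PBN (see [pbn_step()] for the update semantics).  The trajectory is fully
#' reproducible given `seed`: the RNG stream is consumed in a fixed order
#' (flip indicators for all non-clamped nodes first, then one draw per
#' updatable node, in node order).
#'
#' @param pbn a `pbn` with fixed selection probabilities.
#' @param steps number of transitions (trajectory has `steps + 1` rows).
#' @param clamps named 0/1 vector of clamped input nodes.
#' @param init initial state (0/1 vector) or `"random"`: uniform over the
#'   non-clamped bits.
#' @param seed optional RNG seed.
#' @param allow_internal allow clamping non-input nodes.
#' @return integer matrix of shape `(steps + 1) x n`, one column per node,
#'   first row the initial state.
#' @examples
#' pbn <- build_pbn(c("N3 = N1 : 0.6", "N3 = N1 & ~N2 : 0.4"))
#' tr <- simulate_pbn(pbn, 20, clamps = c(N1 = 1, N2 = 1), seed = 1)
#' mean(binary_trace(tr, "N3")[-1])   # close to 0.6
#' @export
simulate_pbn <- function(pbn, steps, clamps = NULL, init = "random",
                         seed = NULL, allow_internal = FALSE) {
  stopifnot(inherits(pbn, "pbn"))
  if (has_free_params(pbn))
    stop("PBN has free selection probabilities; fix them before simulating",
         call. = FALSE)
  if (!is.numeric(steps) || steps < 1)
    stop("steps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dyn <- compile_dynamics(pbn, clamps, allow_internal)
  state <- if (identical(init, "random")) {
    random_initial_state(pbn, dyn$clamps)
  } else {
    st <- as.integer(init)
    if (length(st) != dyn$n)
      stop("initial state length does not match the number of nodes",
           call. = FALSE)
    apply_clamps(pbn, st, dyn$clamps)
  }
  res <- sim_steps_cpp(state, as.integer(steps), pbn$p, dyn$nonclamped0,
                       dyn$upd0, dyn$parents0, dyn$weights, dyn$pr1,
                       as.integer(seq_len(dyn$n) - 1L))
  out <- rbind(state, res$trace)
  dimnames(out) <- list(NULL, pbn$nodes)
  out
}

#' Extract a single node's binary trace from a trajectory
#'
#' @param trajectory matrix from [simulate_pbn()] (columns named by node).
#' @param node node identifier.
#' @return integer 0/1 vector, same length as the trajectory.
#' @export
binary_trace <- function(trajectory, node) {
  if (!node %in% colnames(trajectory))
    stop(sprintf("unknown node '%s'", node), call. = FALSE)
  as.integer(trajectory[, node])
}
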