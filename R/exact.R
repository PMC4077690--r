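## ---------------------------------------------------------------------------
## Exact Markov-chain oracle for small PBNs: transition matrices, stationary
## distributions, bottom SCCs, constituent enumeration, influences.
##
## The chain lives on the 2^m states of the non-clamped nodes (m = n minus the
## number of clamped nodes).  State index: 1 + sum(bit_i * 2^(i-1)) over the
## non-clamped nodes in node order (first non-clamped node = least significant
## bit).  Rendered state labels list ALL nodes, first declared node leftmost.
## ---------------------------------------------------------------------------

#' Exact transition matrix of a (clamped) PBN
#'
#' Builds the row-stochastic transition matrix of the Markov chain on the
#' non-clamped state space.  Entry (s, t) is
#' `p^h (1-p)^(m-h)` for Hamming distance `h >= 1` (perturbation part) plus
#' `(1-p)^m * prod_i P(x_i' = t_i | s)` (network part), where each non-input
#' node's probability is the mixture over its predictors and unclamped input
#' nodes hold their value.
#'
#' @param pbn a `pbn` with fixed selection probabilities.
#' @param clamps named 0/1 vector of clamped input nodes.
#' @param p perturbation probability (default: the PBN's own).
#' @param max_nodes cap on the number of non-clamped nodes (matrix dimension
#'   `2^m`); exceeded caps raise an error.
#' @param allow_internal allow clamping non-input nodes.
#' @return an object of class `pbn_chain`: `P` (matrix), `bits` (2^m x m 0/1
#'   matrix), `chain_nodes`, `clamps`, `labels` (full-state strings), `p`.
#' @export
transition_matrix <- function(pbn, clamps = NULL, p = pbn$p, max_nodes = 10L,
                              allow_internal = FALSE) {
  stopifnot(inherits(pbn, "pbn"))
  if (has_free_params(pbn))
    stop("PBN has free selection probabilities", call. = FALSE)
  cl <- check_clamps(pbn, clamps, allow_internal)
  chain_nodes <- setdiff(pbn$nodes, names(cl))
  m <- length(chain_nodes)
  if (m > max_nodes)
    stop(sprintf("state space 2^%d exceeds the cap 2^%d; raise max_nodes at your own risk",
                 m, max_nodes), call. = FALSE)
  S <- 2^m
  bits <- matrix(0L, S, m, dimnames = list(NULL, chain_nodes))
  for (i in seq_len(m))
    bits[, i] <- (seq_len(S) - 1L) %/% 2^(i - 1L) %% 2L

  ## full states (including clamp values), one row per chain state
  full <- matrix(0L, S, length(pbn$nodes), dimnames = list(NULL, pbn$nodes))
  full[, chain_nodes] <- bits
  if (length(cl) > 0L) full[, names(cl)] <- matrix(cl, S, length(cl), byrow = TRUE)

  ## per chain node: q[s] = P(node' = 1 | full state s) under the network part
  q <- matrix(0, S, m, dimnames = list(NULL, chain_nodes))
  for (i in seq_len(m)) {
    nd <- chain_nodes[i]
    if (nd %in% pbn$inputs) {
      q[, i] <- bits[, i]                       # unclamped input: identity
    } else {
      mix <- node_mixture(pbn$function_sets[[nd]])
      if (length(mix$parents) == 0L) {
        q[, i] <- mix$pr1
      } else {
        pidx <- as.vector(1L + full[, mix$parents, drop = FALSE] %*%
                            2^(seq_along(mix$parents) - 1L))
        q[, i] <- mix$pr1[pidx]
      }
    }
  }

  Pn <- matrix(1, S, S)
  for (i in seq_len(m)) {
    ti <- bits[, i]
    Pn <- Pn * t(ifelse(matrix(ti, S, S), matrix(q[, i], S, S, byrow = TRUE),
                        1 - matrix(q[, i], S, S, byrow = TRUE)))
  }

  H <- matrix(0L, S, S)
  for (i in seq_len(m))
    H <- H + abs(outer(bits[, i], bits[, i], `-`))
  pert <- ifelse(H >= 1L, p^H * (1 - p)^(m - H), 0)

  P <- pert + (1 - p)^m * Pn
  labels <- apply(full, 1L, state_to_string)
  structure(list(P = P, bits = bits, chain_nodes = chain_nodes,
                 clamps = cl, labels = labels, p = p, nodes = pbn$nodes,
                 inputs = pbn$inputs),
            class = "pbn_chain")
}

#' Stationary distribution of a chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1`, `pi >= 0` by the linear system
#' `(I - t(P)) pi = 0` with a normalisation row (QR solve); falls back to
#' damped power iteration on `(P + I)/2` if the solve is numerically unstable.
#' A chain whose stationary law is not unique (more than one recurrent class,
#' possible only at p = 0) raises an error.
#'
#' @param chain a `pbn_chain` from [transition_matrix()].
#' @param tol residual tolerance.
#' @return stationary probability vector (length `2^m`, named by state label).
#' @export
stationary_distribution <- function(chain, tol = 1e-12) {
  stopifnot(inherits(chain, "pbn_chain"))
  P <- chain$P
  S <- nrow(P)
  M <- rbind(t(P) - diag(S), rep(1, S))
  qrM <- qr(M)
  if (qrM$rank < S)
    stop("chain is reducible: stationary distribution is not unique (use p > 0 or restrict to an ergodic subchain)",
         call. = FALSE)
  pi <- tryCatch(qr.coef(qrM, c(rep(0, S), 1)), error = function(e) NULL)
  ok <- !is.null(pi) && !anyNA(pi) &&
    max(abs(as.vector(pi %*% P) - pi)) < 1e-8
  if (!ok) {
    Pd <- (P + diag(S)) / 2
    pi <- rep(1 / S, S)
    for (it in seq_len(200000L)) {
      pin <- as.vector(pi %*% Pd)
      if (max(abs(pin - pi)) < tol) { pi <- pin; break }
      pi <- pin
    }
  }
  pi[pi < 0 & pi > -1e-10] <- 0
  if (any(pi < 0))
    stop("stationary solve produced negative probabilities", call. = FALSE)
  pi <- pi / sum(pi)
  names(pi) <- chain$labels
  pi
}

#' Marginal steady-state probability of a node
#'
#' Sums the stationary probability over states in which the node is 1.
#' A clamped node returns its clamp value.
#'
#' @param chain a `pbn_chain`.
#' @param pi stationary vector from [stationary_distribution()].
#' @param node node identifier.
#' @return probability in `[0, 1]`.
#' @export
marginal_probability <- function(chain, pi, node) {
  stopifnot(inherits(chain, "pbn_chain"))
  if (node %in% names(chain$clamps)) return(as.numeric(chain$clamps[[node]]))
  i <- match(node, chain$chain_nodes)
  if (is.na(i)) stop(sprintf("unknown node '%s'", node), call. = FALSE)
  sum(pi[chain$bits[, i] == 1L])
}

#' Exact marginal steady-state probability (convenience wrapper)
#'
#' Builds the clamped chain, solves the stationary distribution and returns
#' the requested marginals in one call.
#'
#' @param pbn a `pbn` with fixed probabilities.
#' @param nodes node identifier(s).
#' @param clamps named 0/1 vector of clamped input nodes.
#' @param p perturbation probability; `p = 0` gives the limit in which the
#'   bundled case-study data are defined (requires a uniquely stationary
#'   subchain).
#' @param ... passed to [transition_matrix()].
#' @return named numeric vector of marginals.
#' @export
exact_marginal <- function(pbn, nodes, clamps = NULL, p = 0, ...) {
  chain <- transition_matrix(pbn, clamps, p = p, ...)
  pi <- stationary_distribution(chain)
  setNames(vapply(nodes, function(nd) marginal_probability(chain, pi, nd), 0),
           nodes)
}

#' Enumerate the constituent Boolean networks of a PBN
#'
#' An independent PBN with `l(i)` predictors per node has `prod l(i)`
#' constituent deterministic Boolean networks; the probability of each is the
#' product of the selected predictors' selection probabilities.
#'
#' @param pbn a `pbn` with fixed probabilities.
#' @param cap maximum number of constituents.
#' @return list of `list(choice = named predictor indices, prob)`; the probs
#'   sum to 1.
#' @export
enumerate_constituents <- function(pbn, cap = 2^20) {
  stopifnot(inherits(pbn, "pbn"))
  if (has_free_params(pbn))
    stop("PBN has free selection probabilities", call. = FALSE)
  l <- pbn_l(pbn)
  if (prod(l) > cap)
    stop(sprintf("%.0f constituent networks exceed the cap %.0f", prod(l), cap),
         call. = FALSE)
  grid <- expand.grid(lapply(l, seq_len))
  names(grid) <- names(pbn$function_sets)
  lapply(seq_len(nrow(grid)), function(r) {
    choice <- unlist(grid[r, , drop = FALSE])
    names(choice) <- names(grid)
    prob <- prod(vapply(names(choice), function(nd)
      pbn$function_sets[[nd]]$probs[choice[[nd]]], 0))
    list(choice = choice, prob = prob)
  })
}

#' Deterministic step of one constituent network
#'
#' @param pbn a `pbn`.
#' @param choice named predictor index per non-input node (as returned in
#'   [enumerate_constituents()]).
#' @param state 0/1 state vector aligned to `pbn$nodes`.
#' @param clamps named 0/1 clamp vector.
#' @return next state under the chosen deterministic Boolean network (inputs
#'   hold their value; clamped nodes keep their clamp).
#' @export
constituent_step <- function(pbn, choice, state, clamps = NULL) {
  cl <- check_clamps(pbn, clamps, allow_internal = TRUE)
  state <- apply_clamps(pbn, as.integer(state), cl)
  nxt <- state
  for (nd in names(pbn$function_sets)) {
    if (nd %in% names(cl)) next
    pr <- pbn$function_sets[[nd]]$predictors[[choice[[nd]]]]
    idx <- if (length(pr$parents) > 0L) {
      b <- state[match(pr$parents, pbn$nodes)]
      1L + sum(b * 2^(seq_along(b) - 1L))
    } else 1L
    nxt[match(nd, pbn$nodes)] <- pr$table[idx]
  }
  setNames(nxt, pbn$nodes)
}

#' Bottom strongly connected components of the p = 0 state graph
#'
#' The absorbing state sets (irreducible subchains) of the unperturbed chain:
#' strongly connected components of the directed state-transition graph with
#' no edges leaving them.
#'
#' @param pbn a `pbn` with fixed probabilities.
#' @param clamps named 0/1 clamp vector.
#' @param ... passed to [transition_matrix()].
#' @return list of character vectors of full-state labels (first declared
#'   node leftmost), sorted by their first state.
#' @export
bottom_sccs <- function(pbn, clamps = NULL, ...) {
  chain <- transition_matrix(pbn, clamps, p = 0, ...)
  adj <- (chain$P > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  memb <- igraph::components(g, mode = "strong")$membership
  S <- nrow(adj)
  out <- list()
  for (cc in sort(unique(memb))) {
    inside <- which(memb == cc)
    leaves <- any(adj[inside, -inside, drop = FALSE] > 0)
    if (!leaves) out[[length(out) + 1L]] <- chain$labels[inside]
  }
  out[order(vapply(out, `[`, "", 1L))]
}

#' Influence of one node on another
#'
#' The influence of a source node k on a target node j is the probability,
#' under the stationary distribution, that toggling bit k changes the output
#' of the target's predictor, averaged over predictors with their selection
#' probabilities: `sum_j c_ij * P_pi( f_j(x) != f_j(x with bit k toggled) )`.
#'
#' @param pbn a `pbn` with fixed probabilities.
#' @param source,target node identifiers.
#' @param clamps named 0/1 clamp vector.
#' @param p perturbation probability used for the stationary law.
#' @param pi optional precomputed stationary vector (with `chain`).
#' @param chain optional precomputed `pbn_chain` matching `pi`.
#' @return influence value in `[0, 1]`; 0 for a non-parent.
#' @export
influence <- function(pbn, source, target, clamps = NULL, p = pbn$p,
                      pi = NULL, chain = NULL) {
  stopifnot(inherits(pbn, "pbn"))
  fs <- pbn$function_sets[[target]]
  if (is.null(fs))
    stop(sprintf("node '%s' has no predictor set", target), call. = FALSE)
  if (any(fs$free))
    stop(sprintf("node '%s' has free selection probabilities", target),
         call. = FALSE)
  if (!source %in% pbn$nodes)
    stop(sprintf("unknown node '%s'", source), call. = FALSE)
  if (is.null(chain)) {
    chain <- transition_matrix(pbn, clamps, p = p)
    pi <- stationary_distribution(chain)
  }
  ## full states with clamp values
  S <- length(pi)
  full <- matrix(0L, S, length(pbn$nodes), dimnames = list(NULL, pbn$nodes))
  full[, chain$chain_nodes] <- chain$bits
  if (length(chain$clamps) > 0L)
    full[, names(chain$clamps)] <- matrix(chain$clamps, S,
                                          length(chain$clamps), byrow = TRUE)
  si <- match(source, pbn$nodes)
  val <- 0
  for (j in seq_along(fs$predictors)) {
    pr <- fs$predictors[[j]]
    if (!(source %in% pr$parents)) next
    eval_pred <- function(states) {
      b <- states[, pr$parents, drop = FALSE]
      idx <- as.vector(1L + b %*% 2^(seq_along(pr$parents) - 1L))
      pr$table[idx]
    }
    f0 <- eval_pred(full)
    toggled <- full
    toggled[, si] <- 1L - toggled[, si]
    f1 <- eval_pred(toggled)
    val <- val + fs$probs[j] * sum(pi[f0 != f1])
  }
  val
}
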