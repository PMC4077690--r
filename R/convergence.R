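## ---------------------------------------------------------------------------
## Two-state Markov chain run-length method: project the full chain onto
## {node = 0, node = 1}, estimate the meta-state transition rates alpha, beta,
## derive the burn-in m0 and run length N needed for precision r at confidence
## s, and iterate on a growing trajectory until m0 + N stabilises.
## ---------------------------------------------------------------------------

#' Settings for the two-state convergence protocol
#'
#' @param p per-node perturbation probability used during simulation (must be
#'   positive so the clamped subchain is ergodic).
#' @param r required half-width (precision) of the steady-state estimate.
#' @param epsilon burn-in tolerance: the first-state distribution must be
#'   within `epsilon` of stationarity after `m0` steps.
#' @param s confidence level for the precision requirement.
#' @param initial_m0,initial_N starting values of burn-in and run length.
#' @param max_length safety cap on the total trajectory length (a
#'   slow-mixing node needs of the order of 1/p^2 steps at precision r, so
#'   the cap is generous by default).
#' @return a `convergence_settings` list.
#' @export
convergence_settings <- function(p = 0.001, r = 0.025, epsilon = 0.01,
                                 s = 0.95, initial_m0 = 0L, initial_N = 100L,
                                 max_length = 1e7) {
  stopifnot(p > 0, p < 1, r > 0, r < 0.5, epsilon > 0, epsilon < 1,
            s > 0.5, s < 1, initial_m0 >= 0, initial_N >= 2,
            max_length >= initial_m0 + initial_N)
  structure(list(p = p, r = r, epsilon = epsilon, s = s,
                 initial_m0 = as.integer(initial_m0),
                 initial_N = as.integer(initial_N),
                 max_length = max_length),
            class = "convergence_settings")
}

#' Meta-state transition rates of a binary trace
#'
#' `alpha` is the fraction of transitions out of 0 that land in 1, `beta` the
#' fraction of transitions out of 1 that land in 0, counted over consecutive
#' pairs.  A constant trace (or one with an undefined denominator) is flagged
#' degenerate; rates of exactly 0 or 1 in one direction are usable for
#' counting but make the run-length formulas break down, so callers extend
#' the trajectory in that case too.
#'
#' @param trace integer 0/1 vector, length >= 2.
#' @return list with `alpha`, `beta`, `degenerate` and the pair counts
#'   `n0`, `n1` (transitions observed out of each meta-state).
#' @export
estimate_alpha_beta <- function(trace) {
  if (length(trace) < 2L) stop("trace must have length >= 2", call. = FALSE)
  from <- trace[-length(trace)]
  to <- trace[-1L]
  n0 <- sum(from == 0L)
  n1 <- sum(from == 1L)
  if (n0 == 0L || n1 == 0L)
    return(list(alpha = NA_real_, beta = NA_real_, degenerate = TRUE,
                n0 = n0, n1 = n1))
  alpha <- sum(from == 0L & to == 1L) / n0
  beta <- sum(from == 1L & to == 0L) / n1
  list(alpha = alpha, beta = beta, degenerate = FALSE, n0 = n0, n1 = n1)
}

#' Burn-in length of the two-state chain
#'
#' `m0 = max(0, ceiling( log(epsilon * (alpha + beta) / max(alpha, beta)) /
#' log(|1 - alpha - beta|) ))`.  The absolute value of
#' `lambda = 1 - alpha - beta` handles oscillatory chains (negative lambda),
#' where the chain forgets its start at rate `|lambda|`; `lambda = 0` forgets
#' in a single step, so `m0 = 1`.
#'
#' @param alpha,beta meta-state transition rates in `(0, 1)`.
#' @param epsilon burn-in tolerance.
#' @return integer burn-in length.
#' @export
burn_in_m0 <- function(alpha, beta, epsilon) {
  if (alpha + beta <= 0) stop("alpha + beta must be positive", call. = FALSE)
  lambda <- 1 - alpha - beta
  # lambda = 0 forgets in one step; |lambda| = 1 only for the deterministic
  # alternator (alpha = beta = 1), which also mixes immediately
  if (abs(lambda) < .Machine$double.eps || abs(lambda) >= 1) return(1L)
  m0 <- ceiling(log(epsilon * (alpha + beta) / max(alpha, beta)) /
                  log(abs(lambda)))
  as.integer(max(0L, m0))
}

#' Required run length of the two-state chain
#'
#' `N = ceiling( alpha * beta * (2 - alpha - beta) / (alpha + beta)^3 *
#' (qnorm((s + 1)/2) / r)^2 )`: the number of post-burn-in steps needed to
#' estimate the marginal to within `r` with confidence `s`, accounting for
#' the chain's autocorrelation through alpha and beta.
#'
#' @param alpha,beta meta-state transition rates in `(0, 1)`.
#' @param r required precision.
#' @param s confidence level.
#' @return integer run length.
#' @export
run_length_N <- function(alpha, beta, r, s) {
  if (alpha + beta <= 0) stop("alpha + beta must be positive", call. = FALSE)
  z <- qnorm((s + 1) / 2)
  as.integer(ceiling(alpha * beta * (2 - alpha - beta) / (alpha + beta)^3 *
                       (z / r)^2))
}

new_two_state_diag <- function(alpha, beta, m0, N, estimate, total_length) {
  structure(list(alpha = alpha, beta = beta, lambda = 1 - alpha - beta,
                 m0 = as.integer(m0), N = as.integer(N),
                 estimate = estimate, total_length = as.integer(total_length)),
            class = "two_state_diag")
}

#' @export
print.two_state_diag <- function(x, ...) {
  cat(sprintf(
    "Two-state MC diagnostic: estimate = %.4f (alpha = %.4f, beta = %.4f, m0 = %d, N = %d, trajectory = %d steps)\n",
    x$estimate, x$alpha, x$beta, x$m0, x$N, x$total_length))
  invisible(x)
}

#' Estimate marginal steady-state probabilities of several nodes
#'
#' Runs the iterative two-state protocol on a single shared trajectory: start
#' from `m0 + N` steps; per node, estimate alpha and beta from the last `N`
#' states of its binary trace, recompute `m0` and `N`, and if the new
#' `m0 + N` exceeds the previous one extend the same trajectory (the existing
#' prefix is reused) and repeat; a degenerate (constant) window doubles the
#' trajectory instead, giving up after 10 doublings or at `max_length`.  When
#' every node's requirement has stabilised, each node's marginal is the
#' frequency of 1 in its own last-`N` window.
#'
#' @param pbn a `pbn` with fixed selection probabilities.
#' @param nodes node identifiers to estimate.
#' @param clamps named 0/1 vector of clamped input nodes (a clamped node's
#'   estimate is its clamp value, with a trivial diagnostic).
#' @param settings a [convergence_settings()] object (its `p` overrides the
#'   PBN's perturbation parameter).
#' @param seed optional RNG seed.
#' @param allow_internal allow clamping non-input nodes.
#' @return named list of `two_state_diag` objects.
#' @export
estimate_marginals_multi <- function(pbn, nodes, clamps = NULL,
                                     settings = convergence_settings(),
                                     seed = NULL, allow_internal = FALSE) {
  stopifnot(inherits(pbn, "pbn"), inherits(settings, "convergence_settings"))
  if (has_free_params(pbn))
    stop("PBN has free selection probabilities", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pbn$p <- settings$p

  if (!all(nodes %in% pbn$nodes))
    stop(sprintf("unknown node(s): %s",
                 paste(setdiff(nodes, pbn$nodes), collapse = ", ")),
         call. = FALSE)
  dyn <- compile_dynamics(pbn, clamps, allow_internal)
  clamped_req <- intersect(nodes, names(dyn$clamps))
  est_nodes <- setdiff(nodes, clamped_req)

  out <- list()
  for (nd in clamped_req)
    out[[nd]] <- new_two_state_diag(NA_real_, NA_real_, 0L, 0L,
                                    as.numeric(dyn$clamps[[nd]]), 0L)
  if (length(est_nodes) == 0L) return(out[nodes])

  rec0 <- as.integer(match(est_nodes, pbn$nodes) - 1L)
  state <- random_initial_state(pbn, dyn$clamps)
  trace <- matrix(integer(0), 0L, length(est_nodes),
                  dimnames = list(NULL, est_nodes))
  L <- 0L

  extend_to <- function(target) {
    if (target <= L) return(invisible(NULL))
    add <- as.integer(target - L)
    res <- sim_steps_cpp(state, add, pbn$p, dyn$nonclamped0, dyn$upd0,
                         dyn$parents0, dyn$weights, dyn$pr1, rec0)
    state <<- res$state
    trace <<- rbind(trace, res$trace)
    L <<- L + add
    invisible(NULL)
  }

  k <- length(est_nodes)
  m0 <- rep(settings$initial_m0, k)
  N <- rep(settings$initial_N, k)
  last_req <- rep(settings$initial_m0 + settings$initial_N, k)
  done <- rep(FALSE, k)
  doublings <- rep(0L, k)
  alpha <- beta <- rep(NA_real_, k)
  target <- settings$initial_m0 + settings$initial_N

  repeat {
    if (target > settings$max_length)
      stop(sprintf(
        "two-state protocol exceeded max_length = %g (nodes: %s; current m0 = %s, N = %s)",
        settings$max_length, paste(est_nodes, collapse = ", "),
        paste(m0, collapse = "/"), paste(N, collapse = "/")), call. = FALSE)
    extend_to(target)
    grew <- FALSE
    for (i in seq_len(k)) {
      if (done[i]) next
      win <- trace[(L - min(N[i], L) + 1L):L, i]
      ab <- estimate_alpha_beta(win)
      ## The run-length formulas assume alpha, beta inside (0, 1).  A
      ## constant window doubles the trajectory, giving up after 10
      ## doublings.  A rate estimated at 0 means the rare direction has not
      ## been observed yet (with p > 0 no direction is truly impossible), so
      ## the trajectory keeps doubling up to the safety cap.  A rate
      ## estimated at 1 can be structural (a deterministic exit from that
      ## meta-state); it is accepted once its source state has been sampled
      ## at least 20 times, and treated as unsampled before that.
      zero_rate <- !ab$degenerate && (ab$alpha == 0 || ab$beta == 0)
      one_rate_unsure <- !ab$degenerate && !zero_rate &&
        ((ab$alpha == 1 && ab$n0 < 20L) || (ab$beta == 1 && ab$n1 < 20L))
      if (ab$degenerate || zero_rate || one_rate_unsure) {
        if (ab$degenerate) {
          doublings[i] <- doublings[i] + 1L
          if (doublings[i] > 10L)
            stop(sprintf(
              "node '%s': trace still constant after 10 trajectory doublings (length %d); the node may be (almost) frozen at this perturbation level",
              est_nodes[i], L), call. = FALSE)
        }
        m0[i] <- 0L
        N[i] <- 2L * L
        target <- max(target, 2L * L)
        grew <- TRUE
        next
      }
      m0_new <- burn_in_m0(ab$alpha, ab$beta, settings$epsilon)
      N_new <- run_length_N(ab$alpha, ab$beta, settings$r, settings$s)
      alpha[i] <- ab$alpha
      beta[i] <- ab$beta
      ## the stopping rule compares successive formula-derived requirements
      ## (a doubling round for a degenerate window does not lower the bar).
      ## On termination the estimate window stays at the length the obtained
      ## trajectory was extended for: the newly computed (not larger)
      ## requirement only certifies that no further extension is needed.
      if (m0_new + N_new > last_req[i]) {
        m0[i] <- m0_new
        N[i] <- N_new
        last_req[i] <- m0_new + N_new
        target <- max(target, m0_new + N_new)
        grew <- TRUE
      } else {
        done[i] <- TRUE
      }
    }
    if (!grew && all(done)) break
  }

  for (i in seq_len(k)) {
    win <- trace[(L - N[i] + 1L):L, i]
    out[[est_nodes[i]]] <- new_two_state_diag(alpha[i], beta[i], m0[i], N[i],
                                              mean(win), L)
  }
  out[nodes]
}

#' Estimate the marginal steady-state probability of one node
#'
#' Single-node wrapper around [estimate_marginals_multi()] (identical result
#' for the same seed).
#'
#' @inheritParams estimate_marginals_multi
#' @param node node identifier.
#' @return a `two_state_diag` object.
#' @examples
#' pbn <- build_pbn(c("N3 = N1 : 0.6", "N3 = N1 & ~N2 : 0.4"))
#' d <- estimate_marginal(pbn, "N3", clamps = c(N1 = 1, N2 = 1), seed = 1)
#' abs(d$estimate - 0.6) < 0.025
#' @export
estimate_marginal <- function(pbn, node, clamps = NULL,
                              settings = convergence_settings(), seed = NULL,
                              allow_internal = FALSE) {
  estimate_marginals_multi(pbn, node, clamps, settings, seed,
                           allow_internal)[[node]]
}
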