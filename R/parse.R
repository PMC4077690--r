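#' @useDynLib pbnfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rgamma setNames qnorm
#' @importFrom utils head tail write.csv
NULL

## ---------------------------------------------------------------------------
## Rule grammar
##
##   rule  := NODE "=" expr [ ":" ( FLOAT | "?" ) ]
##   expr  := term { "|" term }
##   term  := factor { "&" factor }
##   factor:= "~" factor | "(" expr ")" | IDENT | "0" | "1"
##
## "#" starts a comment; blank lines are ignored.  A missing probability means
## c = 1; "?" marks the selection probability as a free optimisation parameter.
## ---------------------------------------------------------------------------

rule_tokenize <- function(line) {
  toks <- list()
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch == "#") break
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest <- substr(line, i, n)
    if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_.]*", rest))
      toks[[length(toks) + 1L]] <- list(type = "IDENT", text = m, col = i)
      i <- i + nchar(m)
    } else if (grepl("^[0-9.]", ch)) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", rest))
      toks[[length(toks) + 1L]] <- list(type = "NUM", text = m, col = i)
      i <- i + nchar(m)
    } else if (ch %in% c("&", "|", "~", "(", ")", "=", ":", "?")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, col = i)
      i <- i + 1L
    } else {
      stop(sprintf("rule syntax error at column %d: unexpected character '%s'",
                   i, ch), call. = FALSE)
    }
  }
  toks
}

## Recursive-descent parser over the token stream.  Builds a nested-list
## expression tree and records parents in order of first appearance.
parse_expr_tokens <- function(toks, pos, parents_env) {
  parse_or <- function(pos) {
    res <- parse_and(pos)
    while (res$pos <= length(toks) && toks[[res$pos]]$type == "|") {
      rhs <- parse_and(res$pos + 1L)
      res <- list(node = list(op = "or", args = list(res$node, rhs$node)),
                  pos = rhs$pos)
    }
    res
  }
  parse_and <- function(pos) {
    res <- parse_factor(pos)
    while (res$pos <= length(toks) && toks[[res$pos]]$type == "&") {
      rhs <- parse_factor(res$pos + 1L)
      res <- list(node = list(op = "and", args = list(res$node, rhs$node)),
                  pos = rhs$pos)
    }
    res
  }
  parse_factor <- function(pos) {
    if (pos > length(toks))
      stop("rule syntax error: unexpected end of expression", call. = FALSE)
    tk <- toks[[pos]]
    if (tk$type == "~") {
      res <- parse_factor(pos + 1L)
      return(list(node = list(op = "not", args = list(res$node)), pos = res$pos))
    }
    if (tk$type == "(") {
      res <- parse_or(pos + 1L)
      if (res$pos > length(toks) || toks[[res$pos]]$type != ")")
        stop(sprintf("rule syntax error at column %d: expected ')'",
                     if (res$pos <= length(toks)) toks[[res$pos]]$col
                     else nchar_end(toks)), call. = FALSE)
      return(list(node = res$node, pos = res$pos + 1L))
    }
    if (tk$type == "IDENT") {
      seen <- get("parents", envir = parents_env)
      if (!(tk$text %in% seen))
        assign("parents", c(seen, tk$text), envir = parents_env)
      return(list(node = list(op = "var", name = tk$text), pos = pos + 1L))
    }
    if (tk$type == "NUM") {
      if (!(tk$text %in% c("0", "1")))
        stop(sprintf("rule syntax error at column %d: only literals 0/1 allowed in expressions",
                     tk$col), call. = FALSE)
      return(list(node = list(op = "const", value = as.integer(tk$text)),
                  pos = pos + 1L))
    }
    stop(sprintf("rule syntax error at column %d: unexpected token '%s'",
                 tk$col, tk$text), call. = FALSE)
  }
  parse_or(pos)
}

nchar_end <- function(toks) {
  tk <- toks[[length(toks)]]
  tk$col + nchar(tk$text)
}

eval_expr <- function(node, values) {
  switch(node$op,
    var   = values[[node$name]],
    const = node$value == 1L,
    not   = !eval_expr(node$args[[1L]], values),
    and   = eval_expr(node$args[[1L]], values) && eval_expr(node$args[[2L]], values),
    or    = eval_expr(node$args[[1L]], values) || eval_expr(node$args[[2L]], values),
    stop("internal: unknown expression node"))
}

## Truth table over the predictor's own parents.  Assignments are enumerated
## with the FIRST parent as the least significant bit, i.e. row index is
## 1 + sum(bits * 2^(seq_along(parents) - 1)).
expr_truth_table <- function(node, parents) {
  k <- length(parents)
  if (k == 0L)
    return(as.integer(eval_expr(node, list())))
  tab <- integer(2^k)
  for (idx in seq_len(2^k) - 1L) {
    bits <- (idx %/% 2^(seq_len(k) - 1L)) %% 2L
    vals <- as.list(bits == 1L)
    names(vals) <- parents
    tab[idx + 1L] <- as.integer(eval_expr(node, vals))
  }
  tab
}

#' Parse a single Boolean rule
#'
#' Parses one line of the rule grammar `NODE = EXPR [: prob | : ?]` into a
#' predictor function: the target node, its parents (in order of first
#' appearance in the expression), the truth table over the parents, and the
#' selection probability (or a free-parameter marker `?`).
#'
#' Expressions use identifiers, `&` (and), `|` (or), `~` (not), parentheses
#' and the constants `0`/`1`.  A constant predictor has zero parents and a
#' length-1 truth table.  Truth-table rows enumerate parent assignments with
#' the first parent as the least significant bit.
#'
#' @param line a single rule string.
#' @return an object of class `pbn_rule` with fields `target`, `parents`,
#'   `table`, `prob` (`NA` when free), `free` and `source_text`.
#' @examples
#' r <- parse_rule("N3 = N1 & ~N2 : 0.4")
#' r$parents   # "N1" "N2"
#' r$table     # 0 1 0 0
#' @export
parse_rule <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  toks <- rule_tokenize(line)
  if (length(toks) == 0L)
    stop("rule syntax error: empty rule", call. = FALSE)
  if (toks[[1L]]$type != "IDENT")
    stop(sprintf("rule syntax error at column %d: expected target node name",
                 toks[[1L]]$col), call. = FALSE)
  target <- toks[[1L]]$text
  if (length(toks) < 2L || toks[[2L]]$type != "=")
    stop("rule syntax error: expected '=' after target node", call. = FALSE)
  if (length(toks) < 3L)
    stop("rule syntax error: empty expression", call. = FALSE)
  env <- new.env()
  assign("parents", character(0), envir = env)
  res <- parse_expr_tokens(toks, 3L, env)
  prob <- 1.0
  free <- FALSE
  pos <- res$pos
  if (pos <= length(toks)) {
    if (toks[[pos]]$type != ":")
      stop(sprintf("rule syntax error at column %d: unexpected token '%s'",
                   toks[[pos]]$col, toks[[pos]]$text), call. = FALSE)
    if (pos + 1L > length(toks))
      stop("rule syntax error: expected probability or '?' after ':'",
           call. = FALSE)
    ptk <- toks[[pos + 1L]]
    if (ptk$type == "?") {
      free <- TRUE
      prob <- NA_real_
    } else if (ptk$type == "NUM") {
      prob <- as.numeric(ptk$text)
      if (prob < 0 || prob > 1)
        stop(sprintf("selection probability %g outside [0, 1]", prob),
             call. = FALSE)
    } else {
      stop(sprintf("rule syntax error at column %d: expected probability or '?'",
                   ptk$col), call. = FALSE)
    }
    if (pos + 1L < length(toks))
      stop(sprintf("rule syntax error at column %d: trailing tokens",
                   toks[[pos + 2L]]$col), call. = FALSE)
  }
  parents <- get("parents", envir = env)
  structure(list(
    target      = target,
    parents     = parents,
    table       = expr_truth_table(res$node, parents),
    expr        = res$node,
    prob        = prob,
    free        = free,
    source_text = trimws(sub("#.*$", "", line))
  ), class = "pbn_rule")
}

deparse_expr <- function(node) {
  switch(node$op,
    var   = node$name,
    const = as.character(node$value),
    not   = paste0("~", wrap_expr(node$args[[1L]], c("and", "or"))),
    and   = paste(vapply(node$args, wrap_expr, "", c("or")), collapse = " & "),
    or    = paste(vapply(node$args, deparse_expr, ""), collapse = " | "),
    stop("internal: unknown expression node"))
}

wrap_expr <- function(node, outer_binds) {
  txt <- deparse_expr(node)
  if (node$op %in% outer_binds) paste0("(", txt, ")") else txt
}

#' Build a probabilistic Boolean network from parsed rules
#'
#' Assembles a validated PBN from a set of Boolean rules.  Multiple rules for
#' the same target form that node's predictor set; identifiers that never
#' appear on a left-hand side become input nodes whose values are set by
#' clamping.  Node order fixes the state-vector layout: input nodes first (in
#' order of first reference), then targets in declaration order, so that the
#' string rendering of a state lists the first declared node leftmost.
#'
#' Per node, the selection probabilities must either all be fixed and sum to 1
#' (within 1e-9) or all be free (`?`); duplicated predictors (same parents and
#' truth table) are rejected.  Feedback (cyclic definitions) is allowed.
#'
#' @param rules character vector of rule lines, or a list of [parse_rule()]
#'   results.  Comment (`#`) and blank lines are ignored.
#' @param p per-node, per-step perturbation (bit-flip) probability; `p > 0`
#'   makes every clamped subchain ergodic.
#' @param nodes optional character vector fixing the full node order.
#' @return an object of class `pbn`: fields `nodes`, `inputs`,
#'   `function_sets` (one per non-input node, each with `predictors`, `probs`,
#'   `free`) and `p`.
#' @examples
#' pbn <- build_pbn(c("N3 = N1 : 0.6", "N3 = N1 & ~N2 : 0.4"))
#' pbn$nodes   # "N1" "N2" "N3"
#' @export
build_pbn <- function(rules, p = 0.001, nodes = NULL) {
  if (is.character(rules)) {
    lines <- rules[nzchar(trimws(sub("#.*$", "", rules)))]
    rules <- lapply(lines, parse_rule)
  }
  if (length(rules) == 0L) stop("no rules given", call. = FALSE)
  stopifnot(all(vapply(rules, inherits, TRUE, "pbn_rule")))
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1)
    stop("perturbation probability p must lie in [0, 1)", call. = FALSE)

  targets <- unique(vapply(rules, `[[`, "", "target"))
  referenced <- unique(unlist(lapply(rules, `[[`, "parents")))
  inputs <- setdiff(referenced, targets)
  if (is.null(nodes)) {
    nodes <- c(inputs, targets)
  } else {
    if (!setequal(nodes, c(inputs, targets)))
      stop("'nodes' must name exactly the declared and referenced nodes",
           call. = FALSE)
  }

  fsets <- list()
  for (tg in targets) {
    rs <- rules[vapply(rules, function(r) r$target == tg, TRUE)]
    sig <- vapply(rs, function(r)
      paste(paste(r$parents, collapse = ","), paste(r$table, collapse = ""),
            sep = "|"), "")
    if (anyDuplicated(sig))
      stop(sprintf("node '%s': duplicate identical predictor", tg),
           call. = FALSE)
    free <- vapply(rs, `[[`, TRUE, "free")
    probs <- vapply(rs, `[[`, 1.0, "prob")
    if (any(free) && !all(free))
      stop(sprintf(
        "node '%s': selection probabilities must be all fixed or all free", tg),
        call. = FALSE)
    if (!any(free) && abs(sum(probs) - 1) > 1e-9)
      stop(sprintf("node '%s': fixed selection probabilities sum to %g, not 1",
                   tg, sum(probs)), call. = FALSE)
    fsets[[tg]] <- list(node = tg, predictors = rs, probs = probs, free = free)
  }

  structure(list(nodes = nodes, inputs = inputs,
                 function_sets = fsets, p = p),
            class = "pbn")
}

#' Read a PBN from a rule file
#'
#' @param path path to a UTF-8 text file with one rule per line (see
#'   [build_pbn()] for the grammar).
#' @param ... passed to [build_pbn()].
#' @return a `pbn` object.
#' @export
read_pbn <- function(path, ...) {
  build_pbn(readLines(path, encoding = "UTF-8"), ...)
}

#' Serialise a PBN back to rule lines
#'
#' The output re-parses to a PBN with identical truth tables for every node
#' (round-trip property).  Free probabilities are written as `?`.
#'
#' @param pbn a `pbn` object.
#' @return character vector of rule lines.
#' @export
pbn_rules <- function(pbn) {
  stopifnot(inherits(pbn, "pbn"))
  out <- character(0)
  for (fs in pbn$function_sets) {
    for (j in seq_along(fs$predictors)) {
      pr <- fs$predictors[[j]]
      marker <- if (fs$free[j]) "?" else format(fs$probs[j], digits = 15)
      out <- c(out, sprintf("%s = %s : %s", fs$node, deparse_expr(pr$expr),
                            marker))
    }
  }
  out
}

n_free_params <- function(pbn) {
  sum(vapply(pbn$function_sets, function(fs) sum(fs$free), 0L))
}

has_free_params <- function(pbn) n_free_params(pbn) > 0L

## Number of predictors per node, l(i)
pbn_l <- function(pbn) {
  vapply(pbn$function_sets, function(fs) length(fs$predictors), 0L)
}

#' Mixture truth table of a node
#'
#' For each assignment of the node's parents (the union of the parents of all
#' its predictors, in order of first appearance), gives the probability that
#' the node is 1 at the next step: `P = sum_j c_ij * f_j(assignment)`.
#'
#' @param pbn a `pbn` with fixed (non-free) probabilities for `node`.
#' @param node node identifier.
#' @return a data.frame with one 0/1 column per parent and a `prob` column;
#'   rows enumerate assignments with the first parent as least significant bit.
#' @export
truth_table <- function(pbn, node) {
  stopifnot(inherits(pbn, "pbn"))
  fs <- pbn$function_sets[[node]]
  if (is.null(fs))
    stop(sprintf("node '%s' has no predictor set (input node?)", node),
         call. = FALSE)
  if (any(fs$free))
    stop(sprintf("node '%s' has free selection probabilities", node),
         call. = FALSE)
  parents <- unique(unlist(lapply(fs$predictors, `[[`, "parents")))
  k <- length(parents)
  nr <- 2^k
  grid <- matrix(0L, nr, k, dimnames = list(NULL, parents))
  prob <- numeric(nr)
  for (idx in seq_len(nr) - 1L) {
    bits <- if (k > 0L) (idx %/% 2^(seq_len(k) - 1L)) %% 2L else integer(0)
    if (k > 0L) grid[idx + 1L, ] <- bits
    val <- 0
    for (j in seq_along(fs$predictors)) {
      pr <- fs$predictors[[j]]
      pidx <- if (length(pr$parents) > 0L) {
        b <- bits[match(pr$parents, parents)]
        1L + sum(b * 2^(seq_along(b) - 1L))
      } else 1L
      val <- val + fs$probs[j] * pr$table[pidx]
    }
    prob[idx + 1L] <- val
  }
  out <- as.data.frame(grid)
  out$prob <- prob
  out
}

## Replace free selection probabilities with concrete values.
## values: named list/vector per node, or a flat vector aligned to the
## free-parameter order (node declaration order, then predictor order).
set_selection_probs <- function(pbn, values) {
  stopifnot(inherits(pbn, "pbn"))
  if (is.list(values)) {
    for (nd in names(values)) {
      fs <- pbn$function_sets[[nd]]
      if (is.null(fs)) stop(sprintf("unknown node '%s'", nd), call. = FALSE)
      v <- values[[nd]]
      if (length(v) != length(fs$predictors))
        stop(sprintf("node '%s': expected %d probabilities", nd,
                     length(fs$predictors)), call. = FALSE)
      pbn$function_sets[[nd]]$probs <- as.numeric(v)
      pbn$function_sets[[nd]]$free <- rep(FALSE, length(v))
    }
  } else {
    i <- 1L
    for (nd in names(pbn$function_sets)) {
      fs <- pbn$function_sets[[nd]]
      wh <- which(fs$free)
      if (length(wh) == 0L) next
      pbn$function_sets[[nd]]$probs[wh] <- as.numeric(values[i:(i + length(wh) - 1L)])
      pbn$function_sets[[nd]]$free[wh] <- FALSE
      i <- i + length(wh)
    }
    if (i - 1L != length(values))
      stop("length of 'values' does not match the number of free parameters",
           call. = FALSE)
  }
  for (nd in names(pbn$function_sets)) {
    s <- sum(pbn$function_sets[[nd]]$probs)
    if (abs(s - 1) > 1e-9)
      stop(sprintf("node '%s': probabilities sum to %g after substitution",
                   nd, s), call. = FALSE)
  }
  pbn
}

#' @export
print.pbn <- function(x, ...) {
  cat(sprintf("Probabilistic Boolean network: %d nodes (%d inputs), p = %g\n",
              length(x$nodes), length(x$inputs), x$p))
  cat("Nodes:", paste(x$nodes, collapse = ", "), "\n")
  for (fs in x$function_sets) {
    for (j in seq_along(fs$predictors)) {
      marker <- if (fs$free[j]) "?" else format(fs$probs[j])
      cat(sprintf("  %s = %s : %s\n", fs$node,
                  deparse_expr(fs$predictors[[j]]$expr), marker))
    }
  }
  invisible(x)
}

## State <-> string rendering: leftmost character is the first declared node.
state_to_string <- function(state) paste(state, collapse = "")
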