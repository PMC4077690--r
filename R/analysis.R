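## ---------------------------------------------------------------------------
## Ensemble statistics over fitted parameter samples: top-K selection,
## per-parameter mean/SD for identifiability assessment, scatter exports.
## ---------------------------------------------------------------------------

fit_samples <- function(x) {
  if (inherits(x, "pbn_fit")) x$samples
  else if (is.data.frame(x) && all(c("iteration", "cost") %in% names(x))) x
  else stop("expected a 'pbn_fit' or a samples data.frame with 'iteration' and 'cost'",
            call. = FALSE)
}

param_cols <- function(samples) setdiff(names(samples), c("iteration", "cost"))

#' Select the K best parameter samples
#'
#' The K lowest-cost samples, ties broken by iteration order (earlier
#' evaluations first).
#'
#' @param x a `pbn_fit` or its `samples` data.frame.
#' @param K ensemble size (default mirrors the usual best-500 analysis).
#' @return data.frame of at most K rows.
#' @export
top_k <- function(x, K = 500L) {
  samples <- fit_samples(x)
  stopifnot(K >= 1)
  if (K > nrow(samples)) {
    warning(sprintf("K = %d exceeds the %d available samples; returning all",
                    K, nrow(samples)), call. = FALSE)
    K <- nrow(samples)
  }
  samples[order(samples$cost, samples$iteration)[seq_len(K)], , drop = FALSE]
}

#' Summarise a parameter ensemble
#'
#' Per-parameter mean, population standard deviation (divide by K, not
#' K - 1), minimum and maximum over the selected samples.  A low SD relative
#' to the mean flags an identifiable (sensitive) parameter; a wide spread
#' flags questionable relevance of the corresponding rule.
#'
#' @param subset data.frame from [top_k()] (or any sample subset).
#' @return an `ensemble_summary` data.frame with columns `param`, `mean`,
#'   `sd`, `min`, `max`; attributes `K` and `cost_range`.
#' @export
summarise_ensemble <- function(subset) {
  samples <- fit_samples(subset)
  if (nrow(samples) == 0L) stop("empty sample subset", call. = FALSE)
  pars <- param_cols(samples)
  out <- data.frame(
    param = pars,
    mean = vapply(pars, function(p) mean(samples[[p]]), 0),
    sd = vapply(pars, function(p) {
      x <- samples[[p]]; sqrt(mean((x - mean(x))^2))
    }, 0),
    min = vapply(pars, function(p) min(samples[[p]]), 0),
    max = vapply(pars, function(p) max(samples[[p]]), 0),
    row.names = NULL)
  attr(out, "K") <- nrow(samples)
  attr(out, "cost_range") <- range(samples$cost)
  class(out) <- c("ensemble_summary", class(out))
  out
}

#' Export ensemble values for scatter plots
#'
#' Long-format table (sample id, parameter, value, cost) suitable for
#' pairwise scatter plots of fitted selection probabilities.
#'
#' @param subset data.frame from [top_k()].
#' @param parameters parameter names to export (columns of the samples).
#' @return long data.frame with columns `sample`, `parameter`, `value`,
#'   `cost`.
#' @export
scatter_export <- function(subset, parameters) {
  samples <- fit_samples(subset)
  if (nrow(samples) == 0L) stop("empty sample subset", call. = FALSE)
  if (length(parameters) < 1L) stop("name at least one parameter", call. = FALSE)
  unknown <- setdiff(parameters, param_cols(samples))
  if (length(unknown) > 0L)
    stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(rbind, lapply(parameters, function(p)
    data.frame(sample = samples$iteration, parameter = p,
               value = samples[[p]], cost = samples$cost, row.names = NULL)))
}
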