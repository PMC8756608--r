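#' Decision-by-sampling choice-rule parameters
#'
#' Decision by sampling (DbS) scores an amount by its relative rank among
#' comparison values, so the same gain feels larger in a context of small
#' gains than in a context of large ones. The package turns rank differences
#' into choices through a logistic rule with a tremble (uniform lapse)
#' probability.
#'
#' @param sensitivity Non-negative slope of the logistic rule on the
#'   gain-rank minus loss-rank difference. 0 gives indifferent (0.5)
#'   responding everywhere.
#' @param tremble Probability in [0, 0.5) of a uniformly random response.
#' @return An object of class `dbs_params`.
#' @export
dbs_params <- function(sensitivity = 3, tremble = 0.05) {
  if (!is_scalar_number(sensitivity) || sensitivity < 0) {
    lr_error("sensitivity must be a non-negative number", "invalid_params")
  }
  if (!is_scalar_number(tremble) || tremble < 0 || tremble >= 0.5) {
    lr_error("tremble must lie in [0, 0.5)", "invalid_params")
  }
  structure(list(sensitivity = sensitivity, tremble = tremble), class = "dbs_params")
}

#' Comparison context for rank-based valuation
#'
#' The multisets of gains and of loss magnitudes against which a gamble's
#' outcomes are ranked. In the experiments modelled here the context is
#' task-endogenous: a condition's own attribute levels (see
#' [context_from_condition()]).
#'
#' @param gain_pool,loss_pool Non-empty numeric vectors of strictly positive
#'   amounts (losses as magnitudes). Duplicates are meaningful.
#' @return An object of class `comparison_context`.
#' @export
comparison_context <- function(gain_pool, loss_pool) {
  for (pool in list(gain_pool, loss_pool)) {
    if (!is.numeric(pool) || length(pool) == 0L || any(!is.finite(pool)) || any(pool <= 0)) {
      lr_error("context pools must be non-empty and strictly positive", "invalid_context")
    }
  }
  structure(list(gain_pool = as.numeric(gain_pool), loss_pool = as.numeric(loss_pool)),
            class = "comparison_context")
}

#' @describeIn comparison_context Context built from a condition's own
#'   attribute levels (the default context in all simulations here).
#' @param condition A `gamble_condition`.
#' @export
context_from_condition <- function(condition) {
  stopifnot(inherits(condition, "gamble_condition"))
  comparison_context(condition$gain_levels, condition$loss_levels)
}

#' Uniformly dense comparison pool over (0, max_value)
#'
#' The n midpoints (k - 1/2) * max_value / n, k = 1..n. This is the
#' idealised "amounts experienced run from 0 to max" context: the relative
#' rank of x equals x / max_value exactly whenever x * n / max_value is an
#' integer (e.g. rank 0.25 for a 10-unit amount when max_value = 40), all
#' entries are strictly positive, and no target amount coincides with a pool
#' entry.
#'
#' @param max_value Upper end of the experienced range (> 0).
#' @param n Number of pool entries (default 100).
#' @return Numeric vector of length `n`.
#' @export
uniform_context <- function(max_value, n = 100) {
  if (!is_scalar_number(max_value) || max_value <= 0) {
    lr_error("max_value must be > 0", "invalid_context")
  }
  (seq_len(n) - 0.5) * max_value / n
}

#' Relative rank of an amount within a comparison pool
#'
#' Mid-rank convention: the rank of `x` is the count of pool entries below
#' `x` plus half the count of ties, divided by the pool size; if `x` itself
#' occurs in the pool, one instance is excluded from its own comparison set
#' (an experienced value is not compared against itself). The result lies in
#' [0, 1]: 0 for an amount below every comparison value, 1 for a unique pool
#' maximum.
#'
#' @param x Numeric vector of amounts to rank.
#' @param pool Non-empty numeric comparison pool (a `comparison_context`
#'   pool or any positive vector).
#' @return Numeric vector of ranks in [0, 1], same length as `x`.
#' @examples
#' relative_rank(10, uniform_context(40))  # 0.25: larger than a quarter
#' relative_rank(10, uniform_context(20))  # 0.50: larger than half
#' @export
relative_rank <- function(x, pool) {
  if (!is.numeric(pool) || length(pool) == 0L) {
    lr_error("comparison pool must be non-empty", "invalid_context")
  }
  vapply(x, function(xi) {
    less <- sum(pool < xi)
    ties <- sum(pool == xi)
    self <- as.integer(ties > 0L)  # exclude one instance of xi itself
    denom <- length(pool) - self
    if (denom == 0L) return(0.5)   # pool was just xi itself: no comparisons
    (less + 0.5 * (ties - self)) / denom
  }, numeric(1))
}

#' DbS accept probability for mixed gambles
#'
#' The latent probability of accepting a 50-50 mixed gamble under rank-based
#' valuation: a logistic function of the difference between the gain's rank
#' in the gain pool and the loss's rank in the loss pool, mixed with a
#' tremble. Equal ranks give 0.5 (indifference); a loss that ranks higher
#' than the gain pushes towards rejection.
#'
#' @param gambles Data frame with columns `gain` and `loss` (losses as
#'   positive magnitudes), e.g. a condition's `$gambles`.
#' @param context A `comparison_context`.
#' @param params A `dbs_params` object.
#' @return Numeric vector of accept probabilities in [0, 1].
#' @export
dbs_accept_probability <- function(gambles, context, params = dbs_params()) {
  stopifnot(inherits(context, "comparison_context"), inherits(params, "dbs_params"))
  stopifnot(is.data.frame(gambles), all(c("gain", "loss") %in% names(gambles)))
  rg <- relative_rank(gambles$gain, context$gain_pool)
  rl <- relative_rank(gambles$loss, context$loss_pool)
  p <- stats::plogis(params$sensitivity * (rg - rl))
  (1 - 2 * params$tremble) * p + params$tremble
}

#' Predicted accept proportions on the common gambles, by condition
#'
#' For each condition, the unweighted mean DbS accept probability over the
#' gambles common to all conditions, ranking each gamble within that
#' condition's own levels. This is the model's prediction for the
#' model-free analysis: symmetric conditions sit at 0.5, a high-gain-range /
#' low-loss-range condition falls below 0.5 (the common gains rank low, the
#' common losses rank high), and the mirror-image condition rises above 0.5.
#'
#' @param conditions List of `gamble_condition` objects.
#' @param common Data frame of common gambles; defaults to
#'   [common_gambles()] of `conditions`.
#' @param params A `dbs_params` object.
#' @return Data frame with columns `condition`, `mean_accept`,
#'   `n_common_gambles`.
#' @examples
#' predicted_proportion_table(range_design(20, 40, n_levels = 10))
#' @export
predicted_proportion_table <- function(conditions, common = NULL, params = dbs_params()) {
  if (is.null(common)) common <- common_gambles(conditions)
  if (!is.data.frame(common) || nrow(common) == 0L) {
    lr_error("the common gamble set is empty", "invalid_input")
  }
  rows <- lapply(conditions, function(cn) {
    p <- dbs_accept_probability(common, context_from_condition(cn), params)
    data.frame(condition = cn$label, mean_accept = mean(p),
               n_common_gambles = nrow(common))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
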