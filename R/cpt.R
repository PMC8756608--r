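#' Prospect-theory accept-reject model parameters
#'
#' The reduced prospect-theory form used throughout for 50-50 mixed
#' gambles: a power value function with loss-aversion coefficient lambda,
#' and a logistic choice rule on the gamble's subjective expected value with
#' sensitivity `mu` and an accept/reject intercept `bias`. Because both
#' outcomes occur with probability one half, probability weighting of 1/2 is
#' absorbed into `mu` and is not modelled separately.
#'
#' @param alpha Gain curvature exponent (> 0).
#' @param beta Loss curvature exponent (> 0); defaults to `alpha`.
#' @param lam Loss-aversion coefficient lambda (> 0); lam > 1 means losses
#'   loom larger than gains.
#' @param mu Choice sensitivity (>= 0); 0 gives flat 50/50 responding
#'   (up to `bias`).
#' @param bias Intercept pushing towards accepting (positive) or rejecting
#'   (negative) every gamble, irrespective of the amounts on offer.
#' @return An object of class `cpt_params`.
#' @examples
#' cpt_params(lam = 2)                       # losses weighted twice
#' cpt_accept_probability(
#'   data.frame(gain = 20, loss = 10),
#'   cpt_params(alpha = 1, lam = 2, mu = 1)  # knife-edge: exactly 0.5
#' )
#' @export
cpt_params <- function(alpha = 0.9, beta = alpha, lam = 2, mu = 1, bias = 0) {
  if (!is_scalar_number(alpha) || alpha <= 0 ||
      !is_scalar_number(beta) || beta <= 0 ||
      !is_scalar_number(lam) || lam <= 0) {
    lr_error("alpha, beta and lam must be strictly positive", "invalid_params")
  }
  if (!is_scalar_number(mu) || mu < 0 || !is_scalar_number(bias)) {
    lr_error("mu must be >= 0 and bias finite", "invalid_params")
  }
  structure(list(alpha = alpha, beta = beta, lam = lam, mu = mu, bias = bias),
            class = "cpt_params")
}

#' @export
print.cpt_params <- function(x, ...) {
  cat(sprintf("<cpt_params> alpha=%.3g beta=%.3g lambda=%.3g mu=%.3g bias=%.3g\n",
              x$alpha, x$beta, x$lam, x$mu, x$bias))
  invisible(x)
}

#' Prospect-theory value of a signed amount
#'
#' `x^alpha` for gains, `-lam * (-x)^beta` for losses. Losses enter as
#' negative signed amounts here even though the package stores loss
#' magnitudes as positive numbers everywhere else.
#'
#' @param x Numeric vector of signed amounts.
#' @param params A `cpt_params` object.
#' @return Numeric vector of subjective values.
#' @export
cpt_value <- function(x, params) {
  stopifnot(inherits(params, "cpt_params"))
  ifelse(x >= 0, x^params$alpha, -params$lam * (-x)^params$beta)
}

#' Prospect-theory accept probability for mixed gambles
#'
#' The subjective expected value of a 50-50 gamble is
#' `U = (gain^alpha - lam * loss^beta) / 2`; the accept probability is
#' `plogis(mu * U + bias)`. At `alpha == beta`, `bias == 0`, a gamble with
#' `gain == lam * loss^(beta/alpha)` (e.g. win 20 / lose 10 at lam = 2,
#' linear value) sits exactly at indifference.
#'
#' @param gambles Data frame with columns `gain` and `loss` (positive
#'   magnitudes).
#' @param params A `cpt_params` object.
#' @return Numeric vector of accept probabilities.
#' @export
cpt_accept_probability <- function(gambles, params) {
  stopifnot(inherits(params, "cpt_params"),
            is.data.frame(gambles), all(c("gain", "loss") %in% names(gambles)))
  u <- 0.5 * gambles$gain^params$alpha - 0.5 * params$lam * gambles$loss^params$beta
  stats::plogis(params$mu * u + params$bias)
}

# Probabilities are clamped away from 0/1 so boundary parameter vectors keep
# the likelihood finite.
LL_EPS <- 1e-9

#' Bernoulli log-likelihood of accept-reject data
#'
#' Sum over records of `log(p)` for accepts and `log(1 - p)` for rejects,
#' with `p` the model accept probability clamped to `[1e-9, 1 - 1e-9]`.
#'
#' @param records Data frame of choice records with columns `gain`, `loss`,
#'   and `accepted` (0/1 or logical). An empty frame gives 0.
#' @param params A `cpt_params` object.
#' @return Scalar log-likelihood (<= 0).
#' @export
cpt_log_likelihood <- function(records, params) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(0)
  stopifnot(all(c("gain", "loss", "accepted") %in% names(records)))
  p <- cpt_accept_probability(records, params)
  p <- pmin(pmax(p, LL_EPS), 1 - LL_EPS)
  acc <- as.numeric(records$accepted)
  sum(acc * log(p) + (1 - acc) * log1p(-p))
}
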