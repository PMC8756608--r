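#' Specification of the maximum-likelihood fit
#'
#' Box constraints, the curvature constraint, and the multi-start schedule
#' for per-agent estimation. Lambda is optimized on the log scale internally
#' (positivity and symmetric multiplicative error) but bounded and reported
#' on the natural scale. The accept-reject likelihood has pronounced ridges
#' along the lambda-bias trade-off, so several seeded random starts are used
#' and the best local optimum kept.
#'
#' @param lam_bounds,mu_bounds,bias_bounds,alpha_bounds Length-2 numeric
#'   lower/upper bounds. `alpha_bounds` also bound beta when it is free.
#' @param alpha_equals_beta Constrain the gain and loss curvature exponents
#'   to be equal (default). On mixed gambles lambda trades off severely
#'   against unequal curvatures, so the tied form is the standard fitted
#'   configuration.
#' @param n_starts Number of random starts (>= 1), drawn uniformly within
#'   the bounds (uniform in log-lambda).
#' @param seed Seed for the start draws; fits are deterministic given
#'   `(records, spec)`.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(lam_bounds = c(0.05, 20), mu_bounds = c(0, 50),
                     bias_bounds = c(-10, 10), alpha_bounds = c(0.2, 2),
                     alpha_equals_beta = TRUE, n_starts = 10, seed = 1) {
  bounds <- list(lam = lam_bounds, mu = mu_bounds, bias = bias_bounds, alpha = alpha_bounds)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (!is.numeric(b) || length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      lr_error(sprintf("%s_bounds must be finite with lower < upper", nm), "invalid_params")
    }
  }
  if (lam_bounds[1] <= 0 || alpha_bounds[1] <= 0) {
    lr_error("lam and alpha bounds must be strictly positive", "invalid_params")
  }
  if (mu_bounds[1] < 0) lr_error("mu lower bound must be >= 0", "invalid_params")
  if (!is_scalar_number(n_starts) || n_starts < 1) {
    lr_error("n_starts must be >= 1", "invalid_params")
  }
  structure(list(
    lam_bounds = lam_bounds, mu_bounds = mu_bounds, bias_bounds = bias_bounds,
    alpha_bounds = alpha_bounds, alpha_equals_beta = isTRUE(alpha_equals_beta),
    n_starts = as.integer(n_starts), seed = as.integer(seed)
  ), class = "fit_spec")
}

# Aggregate records to unique gambles with trial and accept counts; the
# likelihood and its gradient are then vectorized over unique gambles only.
aggregate_records <- function(records) {
  key <- gamble_key(records$gain, records$loss)
  acc <- as.numeric(records$accepted)
  n <- rowsum(rep(1, length(key)), key)
  k <- rowsum(acc, key)
  first <- !duplicated(key)
  ord <- match(rownames(n), key[first])
  g <- records$gain[first][ord]
  l <- records$loss[first][ord]
  list(g = g, l = l, n = as.numeric(n), k = as.numeric(k))
}

# Negative log-likelihood and analytic gradient in the optimizer
# parameterization theta = (log lam, mu, bias, alpha[, beta]).
nll_factory <- function(agg, tied) {
  g <- agg$g; l <- agg$l; n <- agg$n; k <- agg$k
  lg <- log(g); ll <- log(l)
  log_eps <- log(LL_EPS)
  list(
    fn = function(theta) {
      lam <- exp(theta[1]); mu <- theta[2]; bias <- theta[3]
      a <- theta[4]; b <- if (tied) a else theta[5]
      u <- 0.5 * exp(a * lg) - 0.5 * lam * exp(b * ll)
      z <- mu * u + bias
      lp <- pmax(stats::plogis(z, log.p = TRUE), log_eps)
      lq <- pmax(stats::plogis(-z, log.p = TRUE), log_eps)
      -sum(k * lp + (n - k) * lq)
    },
    gr = function(theta) {
      lam <- exp(theta[1]); mu <- theta[2]; bias <- theta[3]
      a <- theta[4]; b <- if (tied) a else theta[5]
      vg <- exp(a * lg)
      vl <- exp(b * ll)
      u <- 0.5 * vg - 0.5 * lam * vl
      z <- mu * u + bias
      p <- stats::plogis(z)
      dz <- k - n * p                        # d loglik / d z_i
      d_llam <- sum(dz * (-mu * 0.5 * lam * vl))
      d_mu <- sum(dz * u)
      d_bias <- sum(dz)
      if (tied) {
        d_a <- sum(dz * mu * 0.5 * (vg * lg - lam * vl * ll))
        -c(d_llam, d_mu, d_bias, d_a)
      } else {
        d_a <- sum(dz * mu * 0.5 * vg * lg)
        d_b <- sum(dz * mu * (-0.5) * lam * vl * ll)
        -c(d_llam, d_mu, d_bias, d_a, d_b)
      }
    }
  )
}

#' Per-agent maximum-likelihood fit of the accept-reject model
#'
#' Fits `cpt_params` to one agent's choice records by maximizing the
#' Bernoulli log-likelihood with box-constrained quasi-Newton optimization
#' (`optim(method = "L-BFGS-B")`, analytic gradient) from `n_starts` seeded
#' random starts. Estimates lying on a box constraint are reported in
#' `at_bound`; data with no accepts or no rejects (perfect separation, which
#' split-half designs routinely produce) are fitted anyway, flagged on
#' `bias`, and warned about rather than raising an error.
#'
#' @param records Data frame of one agent's choice records (columns `gain`,
#'   `loss`, `accepted`; an `agent_id` column, if present, must be
#'   constant).
#' @param spec A [fit_spec()].
#' @return An object of class `cpt_fit`: list with `params` (`cpt_params`),
#'   `loglik`, `converged`, `at_bound` (character vector of parameter
#'   names), `n_trials`.
#' @export
fit_mle <- function(records, spec = fit_spec()) {
  stopifnot(inherits(spec, "fit_spec"), is.data.frame(records))
  if (nrow(records) == 0L) lr_error("no records to fit", "insufficient_data")
  if ("agent_id" %in% names(records) && length(unique(records$agent_id)) > 1L) {
    lr_error("fit_mle() fits one agent; use fit_population() for several", "invalid_input")
  }
  agg <- aggregate_records(records)
  separated <- sum(agg$k) == 0 || sum(agg$k) == sum(agg$n)

  tied <- spec$alpha_equals_beta
  lower <- c(log(spec$lam_bounds[1]), spec$mu_bounds[1], spec$bias_bounds[1], spec$alpha_bounds[1])
  upper <- c(log(spec$lam_bounds[2]), spec$mu_bounds[2], spec$bias_bounds[2], spec$alpha_bounds[2])
  if (!tied) {
    lower <- c(lower, spec$alpha_bounds[1])
    upper <- c(upper, spec$alpha_bounds[2])
  }
  npar <- length(lower)
  obj <- nll_factory(agg, tied)

  starts <- with_seed(spec$seed, {
    matrix(stats::runif(spec$n_starts * npar, rep(lower, each = spec$n_starts),
                        rep(upper, each = spec$n_starts)),
           nrow = spec$n_starts, ncol = npar)
  })

  best <- NULL
  for (s in seq_len(spec$n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) lr_error("all optimization starts failed", "fit_failure")

  theta <- best$par
  est <- list(
    lam = exp(theta[1]), mu = theta[2], bias = theta[3],
    alpha = theta[4], beta = if (tied) theta[4] else theta[5]
  )
  tol <- 1e-6
  at <- character(0)
  nms <- c("lam", "mu", "bias", "alpha", if (!tied) "beta")
  for (i in seq_len(npar)) {
    if (theta[i] - lower[i] < tol || upper[i] - theta[i] < tol) at <- c(at, nms[i])
  }
  if (separated) {
    warning("perfect separation: all responses identical; bias estimate is degenerate")
    at <- union(at, "bias")
  }
  structure(list(
    params = cpt_params(alpha = est$alpha, beta = est$beta, lam = est$lam,
                        mu = est$mu, bias = est$bias),
    loglik = -best$value,
    converged = best$convergence == 0L,
    at_bound = at,
    n_trials = nrow(records)
  ), class = "cpt_fit")
}

#' @export
print.cpt_fit <- function(x, ...) {
  cat(sprintf("<cpt_fit> loglik=%.2f over %d trials; converged=%s%s\n",
              x$loglik, x$n_trials, x$converged,
              if (length(x$at_bound)) paste0("; at bound: ", paste(x$at_bound, collapse = ",")) else ""))
  print(x$params)
  invisible(x)
}

#' Fit every agent in a choice-record table
#'
#' Splits `records` by `agent_id`, fits each agent with [fit_mle()], and
#' returns one row per agent. Separation warnings from individual agents
#' are collected silently into the `at_bound` column.
#'
#' @param records Choice records for one or more agents.
#' @param spec A [fit_spec()], shared across agents.
#' @return Data frame with columns `agent_id`, `alpha`, `beta`, `lam`,
#'   `mu`, `bias`, `loglik`, `converged`, `at_bound` (`;`-separated names,
#'   `""` if none), `n_trials`.
#' @export
fit_population <- function(records, spec = fit_spec()) {
  stopifnot(is.data.frame(records), "agent_id" %in% names(records))
  ids <- sort(unique(records$agent_id))
  rows <- lapply(ids, function(id) {
    f <- withCallingHandlers(
      fit_mle(records[records$agent_id == id, , drop = FALSE], spec),
      warning = function(w) invokeRestart("muffleWarning")
    )
    data.frame(
      agent_id = id, alpha = f$params$alpha, beta = f$params$beta,
      lam = f$params$lam, mu = f$params$mu, bias = f$params$bias,
      loglik = f$loglik, converged = f$converged,
      at_bound = paste(f$at_bound, collapse = ";"), n_trials = f$n_trials
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank correlation between lambda and bias estimates
#'
#' Across a population of fitted agents, lambda and the accept/reject bias
#' are strongly confounded: the data constrain mostly a ridge in
#' (lambda, bias) space, so estimation error in one shows up in the other.
#' This returns the Spearman correlation between the two estimates across
#' converged fits.
#'
#' @param fits Data frame from [fit_population()] (or a list of `cpt_fit`
#'   objects).
#' @return Scalar rank correlation in [-1, 1].
#' @export
lambda_bias_correlation <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      data.frame(agent_id = as.character(i), lam = f$params$lam,
                 bias = f$params$bias, converged = f$converged)
    }))
  }
  ok <- fits[fits$converged, , drop = FALSE]
  if (nrow(ok) < 3L) {
    lr_error("need at least 3 converged fits", "insufficient_data")
  }
  if (stats::sd(ok$lam) == 0 || stats::sd(ok$bias) == 0) {
    lr_error("lambda or bias estimates have no variation", "insufficient_variation")
  }
  stats::cor(ok$lam, ok$bias, method = "spearman")
}
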