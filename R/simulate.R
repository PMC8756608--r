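#' Specification of a synthetic agent population
#'
#' Populations come from one of two generators: `"cpt"` agents choose from
#' the prospect-theory accept-reject model (the well-specified case for the
#' fitting pipeline), `"dbs"` agents choose by relative rank within their
#' condition's own attribute levels (the misspecified case). Heterogeneity
#' defaults: for `"cpt"`, lambda is log-normal with median 2 and log-sd 0.3,
#' bias is normal(0, 0.5), and mu = 1, alpha = beta = 0.9 are fixed; for
#' `"dbs"`, sensitivity is normal(3, 0.5) truncated at 0 and tremble is
#' fixed at 0.05.
#'
#' @param n_agents Number of agents (>= 1).
#' @param generator `"cpt"` or `"dbs"`.
#' @param seed Master seed; sampling is deterministic given the spec.
#' @param hyperparams Named list overriding any of the defaults above
#'   (`lam_meanlog`, `lam_sdlog`, `bias_mean`, `bias_sd`, `mu`, `alpha` for
#'   cpt; `sensitivity_mean`, `sensitivity_sd`, `tremble` for dbs). A zero
#'   sd makes that parameter degenerate at its mean.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_agents, generator = c("cpt", "dbs"), seed = 1,
                            hyperparams = list()) {
  generator <- match.arg(generator)
  if (!is_scalar_number(n_agents) || n_agents < 1) {
    lr_error("n_agents must be >= 1", "invalid_params")
  }
  defaults <- switch(generator,
    cpt = list(lam_meanlog = log(2), lam_sdlog = 0.3,
               bias_mean = 0, bias_sd = 0.5, mu = 1, alpha = 0.9),
    dbs = list(sensitivity_mean = 3, sensitivity_sd = 0.5, tremble = 0.05)
  )
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown)) {
    lr_error(paste("unknown hyperparams:", paste(unknown, collapse = ", ")), "invalid_params")
  }
  defaults[names(hyperparams)] <- hyperparams
  if (!all(vapply(defaults, is_scalar_number, logical(1)))) {
    lr_error("all hyperparameters must be finite numbers", "invalid_params")
  }
  structure(list(n_agents = as.integer(n_agents), generator = generator,
                 seed = as.integer(seed), hyperparams = defaults),
            class = "population_spec")
}

#' Draw an agent population
#'
#' Samples agent-level parameters from the population distributions in a
#' [population_spec()]. Agent ids are stable, zero-padded, and ordered.
#'
#' @param spec A `population_spec`.
#' @return Data frame, one row per agent: `agent_id`, `generator`, plus
#'   `lam`, `bias`, `mu`, `alpha` (cpt) or `sensitivity`, `tremble` (dbs).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_agents
  h <- spec$hyperparams
  width <- max(2L, nchar(as.character(n)))
  ids <- sprintf(paste0("a%0", width, "d"), seq_len(n))
  with_seed(spec$seed, {
    if (spec$generator == "cpt") {
      data.frame(
        agent_id = ids, generator = "cpt",
        lam = exp(stats::rnorm(n, h$lam_meanlog, h$lam_sdlog)),
        bias = stats::rnorm(n, h$bias_mean, h$bias_sd),
        mu = rep(h$mu, n), alpha = rep(h$alpha, n)
      )
    } else {
      data.frame(
        agent_id = ids, generator = "dbs",
        sensitivity = pmax(stats::rnorm(n, h$sensitivity_mean, h$sensitivity_sd), 0),
        tremble = rep(h$tremble, n)
      )
    }
  })
}

# Latent accept probabilities of one agent (a one-row population frame) for
# every gamble in a condition. DbS agents rank within the condition's own
# levels; CPT agents evaluate amounts directly.
agent_accept_probabilities <- function(agent, condition) {
  stopifnot(inherits(condition, "gamble_condition"))
  if (is.data.frame(agent)) {
    stopifnot(nrow(agent) == 1L)
    agent <- as.list(agent)
  }
  if (agent$generator == "cpt") {
    cpt_accept_probability(
      condition$gambles,
      cpt_params(alpha = agent$alpha, lam = agent$lam, mu = agent$mu, bias = agent$bias)
    )
  } else {
    dbs_accept_probability(
      condition$gambles, context_from_condition(condition),
      dbs_params(sensitivity = agent$sensitivity, tremble = agent$tremble)
    )
  }
}

#' Simulate one agent's choices in a condition
#'
#' Presents each gamble of the condition `n_reps` times and resolves the
#' agent's latent accept probabilities into Bernoulli accept/reject
#' responses.
#'
#' @param agent One row of a [sample_population()] frame (or an equivalent
#'   named list including `agent_id` and `generator`).
#' @param condition A `gamble_condition`.
#' @param n_reps Presentations of each gamble (>= 1).
#' @param seed Seed for the Bernoulli draws; `NULL` uses (and advances) the
#'   global stream.
#' @return Data frame of choice records: `agent_id`, `condition`, `gain`,
#'   `loss`, `accepted` (integer 0/1).
#' @export
simulate_choices <- function(agent, condition, n_reps = 1, seed = NULL) {
  if (!is_scalar_number(n_reps) || n_reps < 1) {
    lr_error("n_reps must be >= 1", "invalid_params")
  }
  p <- agent_accept_probabilities(agent, condition)
  gm <- condition$gambles[rep(seq_len(nrow(condition$gambles)), times = n_reps), , drop = FALSE]
  p <- rep(p, times = n_reps)
  acc <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  aid <- if (is.data.frame(agent)) agent$agent_id else agent$agent_id
  data.frame(
    agent_id = rep(as.character(aid), length(p)),
    condition = rep(condition$label, length(p)),
    gain = gm$gain, loss = gm$loss, accepted = acc,
    row.names = NULL
  )
}

#' Simulate a whole population across one or more conditions
#'
#' Every agent responds to every gamble of every condition `n_reps` times.
#' Reproducible piecewise: agent `i` draws with sub-seed `seed + i`, so the
#' same agent's data can be regenerated without simulating the rest of the
#' population. With the default 20-level conditions and `n_reps = 1`, each
#' agent contributes 400 trials per condition, enough that random halves
#' remain fittable.
#'
#' @param population Data frame from [sample_population()].
#' @param conditions A `gamble_condition` or list of them.
#' @param n_reps Presentations of each gamble per agent.
#' @param seed Master seed for the Bernoulli draws.
#' @return Data frame of choice records for all agents and conditions.
#' @export
simulate_population <- function(population, conditions, n_reps = 1, seed = 1) {
  stopifnot(is.data.frame(population), nrow(population) >= 1L)
  if (inherits(conditions, "gamble_condition")) conditions <- list(conditions)
  out <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    agent <- population[i, , drop = FALSE]
    out[[i]] <- with_seed(seed + i, {
      do.call(rbind, lapply(conditions, function(cn) {
        simulate_choices(agent, cn, n_reps = n_reps, seed = NULL)
      }))
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
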