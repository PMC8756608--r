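#' Randomly split each agent's records into two halves
#'
#' Partitions every agent's choice records into two random halves whose
#' sizes differ by at most one. Agents with fewer than two records are
#' dropped with a warning.
#'
#' @param records Choice-record data frame with an `agent_id` column.
#' @param seed Seed; the partition is deterministic given `(records, seed)`.
#' @return List with data frames `half_a` and `half_b`; their union is the
#'   input (minus dropped agents).
#' @export
split_half <- function(records, seed = 1) {
  stopifnot(is.data.frame(records), "agent_id" %in% names(records))
  ids <- sort(unique(records$agent_id))
  with_seed(seed, {
    a <- vector("list", length(ids))
    b <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      rec <- records[records$agent_id == ids[j], , drop = FALSE]
      n <- nrow(rec)
      if (n < 2L) {
        warning(sprintf("agent %s has fewer than 2 records; skipped", ids[j]))
        next
      }
      perm <- sample.int(n)
      na <- ceiling(n / 2)
      a[[j]] <- rec[perm[seq_len(na)], , drop = FALSE]
      b[[j]] <- rec[perm[(na + 1):n], , drop = FALSE]
    }
    half_a <- do.call(rbind, a)
    half_b <- do.call(rbind, b)
    rownames(half_a) <- rownames(half_b) <- NULL
    list(half_a = half_a, half_b = half_b)
  })
}

# Usable agents: converged on both halves with no estimate on a box bound.
usable_agents <- function(fits_a, fits_b) {
  ok_a <- fits_a$agent_id[fits_a$converged & fits_a$at_bound == ""]
  ok_b <- fits_b$agent_id[fits_b$converged & fits_b$at_bound == ""]
  sort(intersect(ok_a, ok_b))
}

# Deterministic ranks of lambda estimates: ties broken by agent id.
lambda_ranks <- function(fits, ids) {
  lam <- fits$lam[match(ids, fits$agent_id)]
  ord <- order(lam, ids)
  rk <- integer(length(ids))
  rk[ord] <- seq_along(ids)
  stats::setNames(rk, ids)
}

# Nearest-rank index for a percentile among n ranked agents.
percentile_rank_index <- function(p, n) {
  max(1L, min(n, as.integer(ceiling(p / 100 * n))))
}

# One stochasticity-only replicate: resample Bernoulli choices from each
# agent's half-A fitted probabilities on its half-B gambles, refit, re-rank.
null_replicate <- function(fits_a, half_b, ids, fit_specification, seed) {
  sim <- with_seed(seed, {
    do.call(rbind, lapply(ids, function(id) {
      rec <- half_b[half_b$agent_id == id, , drop = FALSE]
      row <- fits_a[fits_a$agent_id == id, , drop = FALSE]
      pars <- cpt_params(alpha = row$alpha, beta = row$beta, lam = row$lam,
                        mu = row$mu, bias = row$bias)
      rec$accepted <- stats::rbinom(nrow(rec), 1L, cpt_accept_probability(rec, pars))
      rec
    }))
  })
  fits_null <- fit_population(sim, fit_specification)
  lambda_ranks(fits_null, ids)
}

#' Stochasticity-only null for the split-half rank experiment
#'
#' How much would lambda ranks move between halves if the fitted model were
#' exactly right and only Bernoulli response noise intervened? For each
#' replicate, fresh accept/reject choices are simulated from each agent's
#' half-A fitted probabilities on its half-B gambles, the model is refitted,
#' and the agents at each half-A percentile are re-ranked.
#'
#' @param fits_a Data frame of half-A fits from [fit_population()].
#' @param half_b Half-B choice records (the designs on which null choices
#'   are simulated).
#' @param fit_specification A [fit_spec()] used for the refits.
#' @param percentiles Target percentiles of the half-A lambda ranking.
#' @param n_replicates Number of null resamples.
#' @param seed Master seed; replicate `r` uses `seed + 100000 + r`.
#' @return List with `percentiles`, `null_distributions` (one integer
#'   vector of ranks per percentile), and `n_agents`.
#' @export
stochasticity_null <- function(fits_a, half_b, fit_specification = fit_spec(),
                               percentiles = c(5, 25, 50, 75, 95),
                               n_replicates = 50, seed = 1) {
  ids <- sort(intersect(fits_a$agent_id[fits_a$converged], unique(half_b$agent_id)))
  n <- length(ids)
  if (n < 10L) lr_error("fewer than 10 usable agents", "insufficient_data")
  rank_a <- lambda_ranks(fits_a, ids)
  targets <- vapply(percentiles, function(p) {
    names(rank_a)[rank_a == percentile_rank_index(p, n)]
  }, character(1))
  dists <- matrix(NA_integer_, nrow = n_replicates, ncol = length(percentiles))
  for (r in seq_len(n_replicates)) {
    rank_null <- null_replicate(fits_a, half_b, ids, fit_specification, seed + 100000 + r)
    dists[r, ] <- rank_null[targets]
  }
  list(
    percentiles = percentiles,
    null_distributions = stats::setNames(
      lapply(seq_along(percentiles), function(j) dists[, j]),
      paste0("p", percentiles)
    ),
    n_agents = n
  )
}

#' Split-half rank-generalization experiment for lambda
#'
#' The central reliability probe: within each replicate, every agent's
#' records are randomly halved; lambda is estimated on each half; agents are
#' ranked by their half-A lambda; and the half-B rank of the agent sitting
#' at each target percentile of the half-A ranking is recorded. If lambda
#' measures a stable property of the agent, those half-B ranks concentrate
#' near the target percentile; if estimates are dominated by
#' choice-set-dependent bias (as when the generating process departs from
#' the fitted model), they scatter over the whole ranking. An optional
#' stochasticity-only null ([stochasticity_null()]) isolates the scatter
#' attributable to Bernoulli response noise alone.
#'
#' Agents whose fit fails to converge or lands on a parameter bound on
#' either half are excluded from that replicate's ranking (with a warning if
#' fewer than `min_usable_frac` remain).
#'
#' @param records Choice records of the population.
#' @param fit_specification A [fit_spec()] shared by all fits.
#' @param percentiles Target percentiles (defaults 5, 25, 50, 75, 95),
#'   mapped to ranks by the nearest-rank rule with ties broken by agent id.
#' @param n_replicates Number of independent split replicates.
#' @param seed Master seed; replicate `r` splits with `seed + r`.
#' @param include_null Also run the stochasticity-only null within each
#'   replicate (on the same split and half-A fits).
#' @param min_usable_frac Warn when fewer than this fraction of agents
#'   survive the convergence/bound filter in a replicate.
#' @return An object of class `recovery_report`: list with `percentiles`,
#'   `rank_distributions` and (if requested) `null_distributions` (per
#'   percentile, the integer half-B ranks across replicates),
#'   `split_rank_correlation` (mean Spearman correlation of half-A and
#'   half-B lambdas), `replicate_correlations`, `n_usable` per replicate,
#'   `n_agents`, `n_replicates`.
#' @export
rank_generalization <- function(records, fit_specification = fit_spec(),
                                percentiles = c(5, 25, 50, 75, 95),
                                n_replicates = 50, seed = 1,
                                include_null = FALSE, min_usable_frac = 0.8) {
  stopifnot(is.data.frame(records), "agent_id" %in% names(records))
  n_agents <- length(unique(records$agent_id))
  np <- length(percentiles)
  ranks_b <- matrix(NA_integer_, nrow = n_replicates, ncol = np)
  ranks_null <- if (include_null) matrix(NA_integer_, nrow = n_replicates, ncol = np)
  rho <- numeric(n_replicates)
  n_usable <- integer(n_replicates)

  for (r in seq_len(n_replicates)) {
    halves <- split_half(records, seed + r)
    fits_a <- fit_population(halves$half_a, fit_specification)
    fits_b <- fit_population(halves$half_b, fit_specification)
    ids <- usable_agents(fits_a, fits_b)
    n <- length(ids)
    if (n < 10L) lr_error("fewer than 10 usable agents in a replicate", "insufficient_data")
    if (n < min_usable_frac * n_agents) {
      warning(sprintf("replicate %d: only %d of %d agents usable", r, n, n_agents))
    }
    n_usable[r] <- n
    rank_a <- lambda_ranks(fits_a, ids)
    rank_b <- lambda_ranks(fits_b, ids)
    lam_a <- fits_a$lam[match(ids, fits_a$agent_id)]
    lam_b <- fits_b$lam[match(ids, fits_b$agent_id)]
    rho[r] <- stats::cor(lam_a, lam_b, method = "spearman")
    targets <- vapply(percentiles, function(p) {
      names(rank_a)[rank_a == percentile_rank_index(p, n)]
    }, character(1))
    ranks_b[r, ] <- rank_b[targets]
    if (include_null) {
      rank_null <- null_replicate(fits_a, halves$half_b, ids, fit_specification,
                                  seed + 100000 + r)
      ranks_null[r, ] <- rank_null[targets]
    }
  }

  pnames <- paste0("p", percentiles)
  structure(list(
    percentiles = percentiles,
    rank_distributions = stats::setNames(
      lapply(seq_len(np), function(j) ranks_b[, j]), pnames),
    null_distributions = if (include_null) stats::setNames(
      lapply(seq_len(np), function(j) ranks_null[, j]), pnames),
    split_rank_correlation = mean(rho),
    replicate_correlations = rho,
    n_usable = n_usable,
    n_agents = n_agents,
    n_replicates = n_replicates
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d agents, %d replicates\n", x$n_agents, x$n_replicates))
  cat(sprintf("  mean split-half lambda rank correlation: %.3f\n", x$split_rank_correlation))
  for (j in seq_along(x$percentiles)) {
    rb <- x$rank_distributions[[j]]
    line <- sprintf("  %2dth pct: half-B rank median %.0f, IQR %.1f",
                    x$percentiles[j], stats::median(rb), stats::IQR(rb))
    if (!is.null(x$null_distributions)) {
      line <- paste0(line, sprintf(" (null IQR %.1f)", stats::IQR(x$null_distributions[[j]])))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Serialize a recovery report as structured text
#'
#' Writes the per-percentile rank histograms (and null histograms when
#' present) plus the summary correlation to a plain-text file that
#' [read_recovery_report()] can parse back.
#'
#' @param report A `recovery_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_recovery_report <- function(report, path) {
  stopifnot(inherits(report, "recovery_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n_agents: %d", report$n_agents), con)
  writeLines(sprintf("n_replicates: %d", report$n_replicates), con)
  writeLines(sprintf("split_rank_correlation: %.6f", report$split_rank_correlation), con)
  for (j in seq_along(report$percentiles)) {
    writeLines(sprintf("percentile %d ranks: %s", report$percentiles[j],
                       paste(report$rank_distributions[[j]], collapse = " ")), con)
    if (!is.null(report$null_distributions)) {
      writeLines(sprintf("percentile %d null_ranks: %s", report$percentiles[j],
                         paste(report$null_distributions[[j]], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname write_recovery_report
#' @export
read_recovery_report <- function(path) {
  lines <- readLines(path)
  get_num <- function(key) {
    as.numeric(sub(paste0("^", key, ": "), "", grep(paste0("^", key, ":"), lines, value = TRUE)))
  }
  parse_ranks <- function(pattern) {
    hits <- grep(pattern, lines, value = TRUE)
    if (!length(hits)) return(NULL)
    pct <- as.integer(sub("^percentile (\\d+) .*", "\\1", hits))
    vals <- lapply(strsplit(sub(".*: ", "", hits), " "), as.integer)
    stats::setNames(vals, paste0("p", pct))
  }
  rd <- parse_ranks("^percentile \\d+ ranks:")
  structure(list(
    percentiles = as.integer(sub("^p", "", names(rd))),
    rank_distributions = rd,
    null_distributions = parse_ranks("^percentile \\d+ null_ranks:"),
    split_rank_correlation = get_num("split_rank_correlation"),
    replicate_correlations = NULL,
    n_usable = NULL,
    n_agents = as.integer(get_num("n_agents")),
    n_replicates = as.integer(get_num("n_replicates"))
  ), class = "recovery_report")
}
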