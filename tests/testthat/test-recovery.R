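test_that("split_half partitions each agent evenly, reproducibly, and losslessly", {
  recs <- data.frame(
    agent_id = c(rep("a01", 4), rep("a02", 5)),
    condition = "X", gain = 1:9, loss = 9:1, accepted = rep(c(0L, 1L), length.out = 9)
  )
  h <- split_half(recs, seed = 6)
  na <- table(h$half_a$agent_id)
  nb <- table(h$half_b$agent_id)
  expect_equal(as.integer(na["a01"]), 2L)
  expect_equal(as.integer(nb["a01"]), 2L)
  expect_true(abs(na[["a02"]] - nb[["a02"]]) <= 1)
  # union is the input
  both <- rbind(h$half_a, h$half_b)
  expect_setequal(paste(both$agent_id, both$gain), paste(recs$agent_id, recs$gain))
  # deterministic
  expect_identical(split_half(recs, seed = 6), split_half(recs, seed = 6))
  # an agent with a single record is dropped with a warning
  solo <- rbind(recs, data.frame(agent_id = "a03", condition = "X",
                                 gain = 5, loss = 5, accepted = 1L))
  expect_warning(h2 <- split_half(solo, seed = 6), "fewer than 2")
  expect_false("a03" %in% c(h2$half_a$agent_id, h2$half_b$agent_id))
})

test_that("rank_generalization is deterministic and returns proper rank distributions", {
  hh <- range_design()$HH
  pop <- sample_population(population_spec(20, "cpt", seed = 41))
  recs <- simulate_population(pop, hh, n_reps = 1, seed = 42)  # 400 trials each
  rep1 <- rank_generalization(recs, quick_spec(), percentiles = c(25, 50, 75),
                              n_replicates = 2, seed = 43, include_null = TRUE)
  rep2 <- rank_generalization(recs, quick_spec(), percentiles = c(25, 50, 75),
                              n_replicates = 2, seed = 43, include_null = TRUE)
  expect_identical(rep1, rep2)
  for (d in c(rep1$rank_distributions, rep1$null_distributions)) {
    expect_length(d, 2L)   # one rank per replicate
    expect_true(all(d >= 1 & d <= rep1$n_agents))
  }
  expect_true(all(abs(rep1$replicate_correlations) <= 1))
  expect_equal(rep1$split_rank_correlation, mean(rep1$replicate_correlations))
})

test_that("too few usable agents raises an insufficient-data error", {
  des <- small_design()
  pop <- sample_population(population_spec(5, "cpt", seed = 51))
  recs <- simulate_population(pop, des$HH, n_reps = 4, seed = 52)
  expect_error(rank_generalization(recs, quick_spec(), n_replicates = 1, seed = 53),
               class = "lossrange_insufficient_data")
})

test_that("near-deterministic agents barely move under the stochasticity-only null", {
  # agents whose fitted probabilities are almost 0/1 regenerate nearly the
  # same data every resample, so their null rank pins to the original rank
  des <- small_design()
  n <- 12
  # lambdas placed between adjacent gain/loss ratios of the 5-level grid so
  # every fitted probability is pinned hard against 0 or 1
  lam_mid <- c(0.632, 0.707, 0.775, 0.894, 1.118, 1.291,
               1.414, 1.581, 1.826, 2.236, 2.739, 3.464)
  fits_a <- data.frame(
    agent_id = sprintf("a%02d", 1:n), alpha = 1, beta = 1,
    lam = lam_mid,
    mu = 30, bias = 0, loglik = -1, converged = TRUE, at_bound = "", n_trials = 50
  )
  half_b <- do.call(rbind, lapply(fits_a$agent_id, function(id) {
    data.frame(agent_id = id, condition = "HH", des$HH$gambles,
               accepted = 0L)
  }))
  null <- stochasticity_null(fits_a, half_b, quick_spec(), percentiles = 50,
                             n_replicates = 5, seed = 61)
  ranks <- null$null_distributions$p50
  target <- ceiling(0.5 * n)
  expect_true(all(abs(ranks - target) <= 1))
  # reproducible
  null2 <- stochasticity_null(fits_a, half_b, quick_spec(), percentiles = 50,
                              n_replicates = 5, seed = 61)
  expect_identical(null, null2)
})

test_that("recovery reports round-trip through their text serialization", {
  rep1 <- structure(list(
    percentiles = c(25L, 50L),
    rank_distributions = list(p25 = c(3L, 17L, 9L), p50 = c(10L, 2L, 20L)),
    null_distributions = list(p25 = c(5L, 6L, 4L), p50 = c(10L, 11L, 9L)),
    split_rank_correlation = 0.123456,
    replicate_correlations = c(0.1, 0.15, 0.12),
    n_usable = c(18L, 19L, 20L),
    n_agents = 20L, n_replicates = 3L
  ), class = "recovery_report")
  path <- withr::local_tempfile(fileext = ".txt")
  write_recovery_report(rep1, path)
  back <- read_recovery_report(path)
  expect_equal(back$rank_distributions, rep1$rank_distributions)
  expect_equal(back$null_distributions, rep1$null_distributions)
  expect_equal(back$split_rank_correlation, rep1$split_rank_correlation, tolerance = 1e-6)
  expect_equal(back$n_agents, rep1$n_agents)
})
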