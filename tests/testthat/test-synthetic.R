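test_that("population sampling is seeded, stable, and honours point masses", {
  spec <- population_spec(10, "cpt", seed = 4)
  p1 <- sample_population(spec)
  p2 <- sample_population(spec)
  expect_identical(p1, p2)
  expect_identical(p1$agent_id, sprintf("a%02d", 1:10))

  # degenerate distributions collapse to their medians
  pt <- sample_population(population_spec(
    1, "cpt", seed = 1, hyperparams = list(lam_sdlog = 0, bias_sd = 0)
  ))
  expect_equal(pt$lam, 2)
  expect_equal(pt$bias, 0)
  expect_equal(pt$mu, 1)
  expect_equal(pt$alpha, 0.9)

  dbs1 <- sample_population(population_spec(5, "dbs", seed = 8))
  expect_true(all(dbs1$sensitivity >= 0))
  expect_equal(unique(dbs1$tremble), 0.05)
  expect_error(population_spec(0, "cpt"), class = "lossrange_invalid_params")
  expect_error(population_spec(5, "cpt", hyperparams = list(nope = 1)),
               class = "lossrange_invalid_params")
})

test_that("the log-normal lambda sampler is centred on its stated median", {
  pop <- sample_population(population_spec(10000, "cpt", seed = 99))
  expect_gt(median(pop$lam), 1.9)
  expect_lt(median(pop$lam), 2.1)
})

test_that("simulated choices resolve latent probabilities by Bernoulli draws", {
  cond <- build_condition(20, 20, 2)  # 4 gambles
  # degenerate acceptor
  acceptor <- list(agent_id = "acc", generator = "cpt",
                   lam = 1, bias = 15, mu = 0, alpha = 1)
  recs <- simulate_choices(acceptor, cond, n_reps = 5, seed = 1)
  expect_true(all(recs$accepted == 1L))
  expect_equal(nrow(recs), 20L)

  # empirical accept rates match the closed-form probabilities within 3 SE
  agent <- list(agent_id = "a01", generator = "cpt",
                lam = 2, bias = 0, mu = 0.3, alpha = 0.9)
  n_reps <- 25000
  sim <- simulate_choices(agent, cond, n_reps = n_reps, seed = 7)
  p_true <- cpt_accept_probability(cond$gambles, cpt_params(alpha = 0.9, lam = 2, mu = 0.3))
  emp <- tapply(sim$accepted, paste(sim$gain, sim$loss), mean)
  emp <- emp[match(paste(cond$gambles$gain, cond$gambles$loss), names(emp))]
  se <- sqrt(p_true * (1 - p_true) / n_reps)
  expect_true(all(abs(emp - p_true) <= 3 * se))

  # seeding: identical records on replay
  expect_identical(simulate_choices(agent, cond, 10, seed = 3),
                   simulate_choices(agent, cond, 10, seed = 3))
})

test_that("population simulation streams per-agent sub-seeds from the master seed", {
  des <- small_design()
  pop <- sample_population(population_spec(4, "dbs", seed = 2))
  all_recs <- simulate_population(pop, des$LL, n_reps = 2, seed = 100)
  expect_identical(all_recs, simulate_population(pop, des$LL, n_reps = 2, seed = 100))
  # agent i alone can be regenerated with sub-seed master + i
  i <- 3
  solo <- simulate_choices(pop[i, ], des$LL, n_reps = 2, seed = 100 + i)
  expect_equal(all_recs[all_recs$agent_id == pop$agent_id[i], ], solo,
               ignore_attr = TRUE)
})

test_that("pooled simulated choices reproduce the predicted proportion table", {
  des <- range_design(20, 40, n_levels = 10)
  common <- common_gambles(des)
  pop <- sample_population(population_spec(
    40, "dbs", seed = 13, hyperparams = list(sensitivity_sd = 0)
  ))
  recs <- simulate_population(pop, des, n_reps = 1, seed = 14)
  obs <- accept_proportions_by_condition(recs, common, aggregation = "pooled")
  pred <- predicted_proportion_table(des, common)
  m <- merge(obs, pred, by = "condition")
  # 40 agents x 25 common gambles per condition: SE ~ 0.016
  expect_true(all(abs(m$proportion - m$mean_accept) < 0.05))
})
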