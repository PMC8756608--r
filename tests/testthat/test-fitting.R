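test_that("fits are deterministic given records and spec", {
  des <- small_design()
  pop <- sample_population(population_spec(1, "cpt", seed = 3))
  recs <- simulate_population(pop, des$HH, n_reps = 8, seed = 5)
  f1 <- fit_mle(recs, quick_spec())
  f2 <- fit_mle(recs, quick_spec())
  expect_identical(f1, f2)
  expect_lte(f1$loglik, 0)
  expect_true(f1$params$lam >= 0.05 && f1$params$lam <= 20)
})

test_that("perfect separation is flagged on bias, not raised", {
  recs <- data.frame(gain = rep(c(10, 20), 10), loss = rep(c(5, 10), 10),
                     accepted = 1L)
  expect_warning(f <- fit_mle(recs, quick_spec()), "separation")
  expect_true("bias" %in% f$at_bound)
  recs$accepted <- 0L
  expect_warning(f0 <- fit_mle(recs, quick_spec()), "separation")
  expect_true("bias" %in% f0$at_bound)
})

test_that("no local perturbation of the optimum improves the likelihood", {
  des <- small_design()
  pop <- sample_population(population_spec(1, "cpt", seed = 9))
  recs <- simulate_population(pop, des$HH, n_reps = 8, seed = 10)
  f <- fit_mle(recs, fit_spec(seed = 4))
  est <- f$params
  expect_equal(cpt_log_likelihood(recs, est), f$loglik, tolerance = 1e-8)
  for (nm in c("lam", "mu", "bias", "alpha")) {
    for (d in c(-1e-4, 1e-4)) {
      pert <- est
      pert[[nm]] <- pert[[nm]] + d
      if (nm == "alpha") pert$beta <- pert$alpha
      ll <- cpt_log_likelihood(recs, cpt_params(alpha = pert$alpha, beta = pert$beta,
                                                lam = pert$lam, mu = pert$mu,
                                                bias = pert$bias))
      expect_lte(ll, f$loglik + 1e-6)
    }
  }
})

test_that("lambda and its ranks are recovered from well-specified data", {
  # ground truth: agents share lam = 2, mu = 1, bias = 0, alpha = beta = 0.9
  des <- range_design()
  pop <- sample_population(population_spec(
    50, "cpt", seed = 21,
    hyperparams = list(lam_sdlog = 0, bias_sd = 0)
  ))
  recs <- simulate_population(pop, des$HH, n_reps = 1, seed = 22)
  fits <- fit_population(recs, fit_spec(seed = 23))
  expect_true(all(fits$converged))
  expect_gt(median(fits$lam), 1.7)
  expect_lt(median(fits$lam), 2.3)

  # heterogeneous population: estimated lambdas preserve the generating order
  # (trials per agent sized so the alpha-mu-lambda ridge does not drown the
  # between-agent lambda variation)
  pop_h <- sample_population(population_spec(50, "cpt", seed = 31))
  recs_h <- simulate_population(pop_h, des$HH, n_reps = 4, seed = 32)
  fits_h <- fit_population(recs_h, fit_spec(seed = 33))
  rho <- cor(pop_h$lam, fits_h$lam, method = "spearman")
  expect_gt(rho, 0.7)
})

test_that("lambda-bias correlation guards its preconditions and handles ties", {
  fits <- data.frame(agent_id = c("a", "b"), lam = c(1, 2), bias = c(0, 1),
                     converged = TRUE)
  expect_error(lambda_bias_correlation(fits), class = "lossrange_insufficient_data")
  frozen <- data.frame(agent_id = letters[1:5], lam = 1:5, bias = 0, converged = TRUE)
  expect_error(lambda_bias_correlation(frozen), class = "lossrange_insufficient_variation")
  # two distinct agents each replicated: tied ranks, no error
  tied <- data.frame(agent_id = as.character(1:20),
                     lam = rep(c(1, 2), each = 10),
                     bias = rep(c(0.5, -0.5), each = 10), converged = TRUE)
  expect_equal(lambda_bias_correlation(tied), -1)
})
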