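test_that("relative rank follows the mid-rank, self-excluded convention", {
  # a 10-unit amount against dense 0-40 and 0-20 experienced ranges
  expect_identical(relative_rank(10, uniform_context(40)), 0.25)
  expect_identical(relative_rank(10, uniform_context(20)), 0.5)
  # below every comparison value
  expect_identical(relative_rank(1, c(2, 5, 9)), 0)
  # self-exclusion: rank within one's own grid ignores the target instance
  expect_equal(relative_rank(3, c(1, 2, 3, 4, 5)), 2 / 4)
  # mid-rank for ties (one instance of the target removed first)
  expect_equal(relative_rank(3, c(1, 3, 3, 5)), (1 + 0.5) / 3)
  expect_error(relative_rank(1, numeric(0)), class = "lossrange_invalid_context")
})

test_that("relative rank is monotone and tops out at a unique maximum", {
  pool <- c(1, 4, 4, 9, 12, 30)
  xs <- seq(0, 35, by = 0.5)
  r <- relative_rank(xs, pool)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_identical(relative_rank(30, pool), 1)
})

test_that("rank-difference choice rule gives indifference, rejection, and tremble mixing", {
  g10 <- data.frame(gain = 10, loss = 10)
  sym <- comparison_context(uniform_context(20), uniform_context(20))
  expect_equal(dbs_accept_probability(g10, sym, dbs_params(5, 0)), 0.5)
  # wide gain range, narrow loss range: the 10-unit loss outranks the gain
  asym <- comparison_context(uniform_context(40), uniform_context(20))
  expect_lt(dbs_accept_probability(g10, asym, dbs_params(3, 0)), 0.5)
  # flat rule
  expect_equal(dbs_accept_probability(g10, asym, dbs_params(0, 0)), 0.5)
  # tremble mixes towards 0.5: p' = (1 - 2t) p + t
  p0 <- dbs_accept_probability(g10, asym, dbs_params(3, 0))
  pt <- dbs_accept_probability(g10, asym, dbs_params(3, 0.1))
  expect_equal(pt, 0.8 * p0 + 0.1)
})

test_that("swapping pools and outcomes reflects accept probability about one half", {
  set.seed(7)
  for (i in 1:20) {
    gp <- runif(8, 1, 50)
    lp <- runif(8, 1, 50)
    g <- data.frame(gain = runif(1, 1, 50), loss = runif(1, 1, 50))
    p <- dbs_accept_probability(g, comparison_context(gp, lp), dbs_params(2.5, 0))
    q <- dbs_accept_probability(data.frame(gain = g$loss, loss = g$gain),
                                comparison_context(lp, gp), dbs_params(2.5, 0))
    expect_equal(p, 1 - q, tolerance = 1e-12)
  }
})

test_that("predicted proportions show the four-condition range pattern", {
  des <- range_design(20, 40, n_levels = 20)
  tab <- predicted_proportion_table(des)
  prop <- setNames(tab$mean_accept, tab$condition)
  # symmetric conditions sit exactly at indifference
  expect_equal(prop[["LL"]], 0.5)
  expect_equal(prop[["HH"]], 0.5)
  expect_gt(prop[["LH"]], 0.5)
  expect_lt(prop[["HL"]], 0.5)
  expect_equal(unique(tab$n_common_gambles), 100L)
})

test_that("predicted proportions match hand enumeration on a two-gamble common set", {
  ll <- build_condition(20, 20, 5, "LL")     # levels 4 8 12 16 20
  common <- data.frame(gain = c(8, 16), loss = c(8, 8))
  # hand-computed ranks within the LL levels (self excluded, denominator 4):
  # rank(8) = 1/4, rank(16) = 3/4
  expected <- mean(plogis(3 * c(0.25 - 0.25, 0.75 - 0.25)))
  tab <- predicted_proportion_table(list(ll, ll), common, dbs_params(3, 0))
  expect_equal(tab$mean_accept, rep(expected, 2))
  expect_equal(expected, (0.5 + plogis(1.5)) / 2)
})

test_that("degenerate inputs raise classed errors", {
  des <- small_design()
  expect_error(predicted_proportion_table(des, data.frame(gain = numeric(0), loss = numeric(0))),
               class = "lossrange_invalid_input")
  expect_error(comparison_context(numeric(0), 1:3), class = "lossrange_invalid_context")
  expect_error(comparison_context(c(1, -2), 1:3), class = "lossrange_invalid_context")
  expect_error(dbs_params(-1), class = "lossrange_invalid_params")
  expect_error(dbs_params(1, 0.5), class = "lossrange_invalid_params")
})
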