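#!/usr/bin/env Rscript
# Prospect-theory lambda estimation on the simulated populations:
# (a) per-condition fits of the DbS agents, showing estimated loss aversion
#     "disappearing or reversing" purely through the range manipulation;
# (b) the lambda-bias confound across agents.

suppressPackageStartupMessages(library(lossrange))
dir.create("results", showWarnings = FALSE)

SEED <- 20260104
rec_dbs <- read_choices("results/choices_dbs_2x2.csv")

per_condition <- do.call(rbind, lapply(sort(unique(rec_dbs$condition)), function(cond) {
  recs <- rec_dbs[rec_dbs$condition == cond, ]
  fits <- fit_population(recs, fit_spec(seed = SEED))
  ok <- fits$converged
  data.frame(condition = cond,
             median_lambda = median(fits$lam[ok]),
             q25 = quantile(fits$lam[ok], 0.25),
             q75 = quantile(fits$lam[ok], 0.75),
             lambda_bias_cor = lambda_bias_correlation(fits),
             n_agents = sum(ok))
}))
utils::write.csv(per_condition, "results/lambda_by_condition.csv",
                 row.names = FALSE, quote = FALSE)

cat("median fitted lambda by condition (DbS agents, same rank mechanism everywhere):\n")
print(per_condition, row.names = FALSE)
cat("\nNo agent has a lambda at all, yet the fitted lambda tracks the range\n")
cat("asymmetry: far below 1 in LH, above 1 in HL. The lambda-bias rank\n")
cat("correlations show the two parameters are not separately identified.\n")
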