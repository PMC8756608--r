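#!/usr/bin/env Rscript
# Simulate the two agent populations used throughout: rank-based (DbS)
# choosers on all four conditions (for the model-free analysis and the
# lambda fits), and both generators on the symmetric high-range condition
# at the larger trial budget used by the split-half experiment.

suppressPackageStartupMessages(library(lossrange))
dir.create("results", showWarnings = FALSE)

SEED <- 20260101
design <- range_design(low = 20, high = 40, n_levels = 20)

# DbS population across the whole 2x2 design (400 trials/agent/condition)
pop_dbs <- sample_population(population_spec(100, "dbs", seed = SEED))
rec_dbs <- simulate_population(pop_dbs, design, n_reps = 1, seed = SEED + 1)
write_choices(rec_dbs, "results/choices_dbs_2x2.csv")
cat(sprintf("DbS 2x2: %d agents, %d records\n",
            length(unique(rec_dbs$agent_id)), nrow(rec_dbs)))

# Recovery-experiment populations on the symmetric high-range condition,
# 1600 trials/agent so random halves are individually fittable
pop_dbs50 <- sample_population(population_spec(50, "dbs", seed = SEED + 10))
rec_dbs50 <- simulate_population(pop_dbs50, design$HH, n_reps = 4, seed = SEED + 11)
write_choices(rec_dbs50, "results/choices_dbs_hh.csv")

pop_cpt50 <- sample_population(population_spec(50, "cpt", seed = SEED + 20))
rec_cpt50 <- simulate_population(pop_cpt50, design$HH, n_reps = 4, seed = SEED + 21)
write_choices(rec_cpt50, "results/choices_cpt_hh.csv")
utils::write.csv(pop_cpt50, "results/population_cpt_hh.csv", row.names = FALSE, quote = FALSE)

cat("recovery populations: 50 DbS and 50 CPT agents, 1600 trials each on HH\n")
cat("wrote results/choices_*.csv\n")
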