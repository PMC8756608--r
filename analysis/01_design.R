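#!/usr/bin/env Rscript
# Build the 2x2 range-manipulation design and extract the gambles common to
# all four conditions. Writes the condition tables and the common set.

suppressPackageStartupMessages(library(lossrange))
dir.create("results", showWarnings = FALSE)

design <- range_design(low = 20, high = 40, n_levels = 20)
common <- common_gambles(design)

write_condition_table(design, "results/conditions.csv")
utils::write.csv(common, "results/common_gambles.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("4 conditions x %d gambles each; %d gambles common to all four\n",
            nrow(design$LL$gambles), nrow(common)))
cat("shared levels:", paste(sort(unique(common$gain)), collapse = " "), "\n")
cat("wrote results/conditions.csv and results/common_gambles.csv\n")
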