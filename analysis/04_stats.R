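#!/usr/bin/env Rscript

# Stage 4 — the statistical battery.
#
# Oral block: multiple regression of the onset delay and each ocular
# variable on tau' and repetition number; frequency ANOVAs. Silent
# block: repetition regressions. Cross-block: SEM-weighted regressions
# of per-CCV silent ocular means on oral tau' means (the headline
# FFD-transition coupling).

suppressPackageStartupMessages({
  library(ccvreading)
  library(dplyr)
})

clean <- utils::read.table("results/trial_records_clean.tsv", header = TRUE,
                           sep = "\t", comment.char = "#")
analysis_set <- analysis_ccvs()
oral <- filter(clean, block == "oral", ccv %in% analysis_set$ccv)
silent <- filter(clean, block == "silent", ccv %in% analysis_set$ccv)

battery <- block_statistics(oral, silent, analysis_set, alpha = 0.01)
utils::write.table(battery, "results/statistics.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

aggregates <- cross_block_aggregates(clean)
utils::write.table(aggregates, "results/ccv_aggregates.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cross <- purrr::map_dfr(c("ffd", "fprt", "tft"), function(v) {
  res <- wls_regression(aggregates, v, "tau_norm")
  mutate(filter(res, term == "tau_norm"), response = v, .before = 1)
})
utils::write.table(cross, "results/cross_block_regressions.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cat("oral block (regression on tau' and repetition):\n")
print(as.data.frame(filter(battery, test == "regression", block == "oral")),
      row.names = FALSE, digits = 3)
cat("\ncross-block SEM-weighted regressions (silent ocular vs oral tau'):\n")
print(as.data.frame(cross), row.names = FALSE, digits = 3)
cat("\nwrote results/statistics.tsv, results/ccv_aggregates.tsv,",
    "results/cross_block_regressions.tsv\n")
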