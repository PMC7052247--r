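#!/usr/bin/env Rscript

# Stage 3 — the exclusion cascade.
#
# Applies the three screening stages in order (high-mispronunciation
# participants, flagged trials, per-participant 2-SD outliers) and writes
# the retained trial table plus the stage report.

suppressPackageStartupMessages(library(ccvreading))

records <- utils::read.table("results/trial_records.tsv", header = TRUE,
                             sep = "\t", comment.char = "#")
out <- qc_cascade(records)

utils::write.table(out$report, "results/qc_report.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(out$records, "results/trial_records_clean.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

print(as.data.frame(out$report), row.names = FALSE)
pp <- out$records[out$records$ccv %in% analysis_ccvs()$ccv &
                    out$records$block == "oral", ]
cat(sprintf("retained %d trials overall; %d oral plosive-plosive records\n",
            nrow(out$records), nrow(pp)))
cat("wrote results/qc_report.tsv and results/trial_records_clean.tsv\n")
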