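#!/usr/bin/env Rscript

# Stage 5 — the vocal-effort model.
#
# Computes the effort functional for the 15 analysis CCVs with the
# packaged geometry (calibrated devoicing constant, 200-ms inter-closure
# interval), sweeps the interval over 100-300 ms, and regresses the
# per-CCV oral tau' aggregates on the modelled effort.

suppressPackageStartupMessages({
  library(ccvreading)
  library(dplyr)
})

clean <- utils::read.table("results/trial_records_clean.tsv", header = TRUE,
                           sep = "\t", comment.char = "#")
cfg <- default_effort_config()
cat(sprintf("calibrated devoicing constant E0 = %.3f cm^2 s\n", cfg$E0))

efforts <- effort_table(analysis_ccvs(), cfg)
write_effort_table(efforts, "results/effort_table.tsv",
                   comment = sprintf("dt_closure=%.3f E0=%.4f",
                                     cfg$dt_closure, cfg$E0))

sweep <- effort_dt_sweep(analysis_ccvs(), cfg)
write_effort_table(sweep, "results/effort_sweep.tsv")

oral <- filter(clean, block == "oral", ccv %in% analysis_ccvs()$ccv)
tau_agg <- aggregate_by_ccv(oral, "tau_norm")
j <- inner_join(efforts, tau_agg, by = "ccv")
fit <- lm(tau_norm_mean ~ E_total, data = j, weights = 1 / j$tau_norm_sem^2)
sm <- summary(fit)$coefficients
assoc <- tibble::tibble(term = "E_total", estimate = sm[2, 1], se = sm[2, 2],
                        statistic = sm[2, 3], df = fit$df.residual,
                        p = sm[2, 4])
utils::write.table(assoc, "results/effort_vs_tau.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

rho <- sweep |>
  inner_join(tau_agg, by = "ccv") |>
  group_by(dt_closure) |>
  summarise(spearman = cor(E_total, tau_norm_mean, method = "spearman"))

cat("\neffort table (15 plosive-plosive CCVs):\n")
print(as.data.frame(efforts), row.names = FALSE, digits = 4)
cat(sprintf("\ntau' on E_total (SEM-weighted): t(%d) = %.2f, p = %.2g\n",
            assoc$df, assoc$statistic, assoc$p))
cat("Spearman rho across the closure-interval sweep:",
    sprintf("%.2f", rho$spearman), "\n")
cat("wrote results/effort_table.tsv, results/effort_sweep.tsv,",
    "results/effort_vs_tau.tsv\n")
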