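#!/usr/bin/env Rscript
# How much does an MZ-DZ gap in environmental correlation inflate the
# Falconer heritability estimate 2*(r_mz - r_dz)? Closed-form grid over
# variance shares, anchored at the environmental-correlation gap measured
# in the corpus (pooled bullying ICCs 0.67 vs 0.39), plus a Monte-Carlo
# check of the closed form. Writes results/falconer_bias_grid.csv.

suppressPackageStartupMessages(library(twinEEA))

cat("Pooled bullying ICCs 0.67 (MZ) vs 0.39 (DZ): doubling the difference\n")
cat(sprintf("gives a pseudo-heritability of %.2f for the exposure itself.\n\n",
            falconer_h2(0.67, 0.39)))

grid <- falconer_bias_grid(
  h2 = c(0, 0.2, 0.4, 0.6), c2 = c(0.1, 0.2, 0.3, 0.4),
  rho_env_mz = 0.67, rho_env_dz = c(0.39, 0.67)
)
cat("Falconer bias 2*c2*(rho_mz - rho_dz) over the variance-share grid:\n")
print(grid, row.names = FALSE, digits = 3)

dir.create("results", showWarnings = FALSE)
write.csv(grid, "results/falconer_bias_grid.csv", row.names = FALSE)

cat("\nMonte-Carlo check (5000 pairs per zygosity, 100 replicates):\n")
cfg <- ace_config(h2 = 0, c2 = 0.5, rho_env_mz = 0.67, rho_env_dz = 0.39,
                  seed = 11)
mc <- simulate_falconer_bias(cfg, n_pairs_per_zygosity = 5000,
                             n_replicates = 100)
closed <- expected_twin_correlations(cfg)
cat(sprintf("  closed form: falconer = %.3f; Monte-Carlo mean = %.3f (SD %.3f)\n",
            closed$falconer_h2, mc$mean_falconer, mc$sd_falconer))
cat("Wrote results/falconer_bias_grid.csv\n")
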