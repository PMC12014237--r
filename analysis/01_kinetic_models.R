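#!/usr/bin/env Rscript

# Why avoid PCR for quantitative metabarcoding? Contrast the two idealized
# kinetic models: exponential PCR amplification, where a small efficiency
# gap compounds every cycle, versus saturating Cas9 enrichment, where rate
# differences wash out as the reaction runs to completion.

suppressPackageStartupMessages(library(cas9enrich))
dir.create("results", showWarnings = FALSE)

pcr <- kinetics_table("pcr", alpha_A = 1.0, alpha_B = 0.9, n_cycles = 25)
write_tsv(pcr, "results/pcr_trajectory.tsv")
cat(sprintf(
  "PCR: with efficiencies 1.0 vs 0.9 the B/A ratio falls from 1 to %.2f by cycle 25\n",
  pcr$ratio_BA[25]))

cas9 <- kinetics_table("cas9", beta_A = 0.1, beta_B = 0.05,
                       times = seq(1, 500, by = 1))
write_tsv(cas9, "results/cas9_trajectory.tsv")
cat(sprintf(
  "Cas9: with cleavage rates 0.1 vs 0.05 the B/A ratio rises from %.3f at t = 1 to %.3f at t = 500\n",
  cas9$ratio_BA[1], cas9$ratio_BA[500]))
cat("-> amplification bias compounds; enrichment bias vanishes with time.\n")
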