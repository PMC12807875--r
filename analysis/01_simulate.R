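#!/usr/bin/env Rscript
# Stage 1: generate the synthetic clone used throughout the analysis — an
# allele-resolved RNA-seq time course of Xist induction (days 0/3/7/14/21,
# 3 replicates) with 7-day washout arms after 7/14/21 days, escapee
# clusters on chrX, and a cross-study escape matrix.

library(xciescape)

seed <- 1
outdir <- "results/sim"

sim <- simulate_dataset(simulation_config(seed = seed))
write_simulation(sim, outdir)

message(sprintf("simulated %d genes x %d samples (seed %d)",
                length(unique(sim$counts$gene_id)), nrow(sim$sheet), seed))
message(sprintf("true categories: %s",
                paste(names(table(sim$truth$category)),
                      table(sim$truth$category), collapse = ", ")))
message(sprintf("wrote tables to %s/", outdir))
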