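#!/usr/bin/env Rscript
# Stage 4: silencing kinetics. Fits r(t) = a*exp(-k*t) + b per escapee over
# the Dox course (replicate-level observations, washout excluded), selects
# full-silencing vs residual-escape models by BIC after the R^2 >= 0.3
# reliability filter, and reports half-lives.

library(xciescape)

sheet <- read_sample_sheet("results/sim/sample_sheet.tsv")
ratios <- read_stage_tsv("results/allelic_ratios.tsv", "ratios")
calls <- read_stage_tsv("results/escape_calls.tsv", "escape")
escapees <- calls$gene_id[calls$status == "escapee"]

fits <- fit_gene_kinetics(ratios, sheet, genes = escapees)
reliable <- fits[fits$selected_model != "unreliable", ]
message(sprintf("fitted %d escapees: %d reliable, %d with residual escape (BIC)",
                nrow(fits), nrow(reliable), sum(fits$residual_escape)))
message(sprintf("median silencing half-life: %.1f days (IQR %.1f-%.1f)",
                median(reliable$half_life_days),
                quantile(reliable$half_life_days, 0.25),
                quantile(reliable$half_life_days, 0.75)))

write_stage_tsv(fits, "results/decay_fits.tsv")
message("wrote results/decay_fits.tsv")
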