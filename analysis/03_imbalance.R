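#!/usr/bin/env Rscript
# Stage 3: differential allelic imbalance. Per Dox timepoint, a per-gene
# binomial GLM tests the treatment effect on the Xi read fraction (Wald
# test, Holm-adjusted within each contrast), and escapees with a
# significant >= 50% ratio reduction are called silenced.

library(xciescape)

sheet <- read_sample_sheet("results/sim/sample_sheet.tsv")
ratios <- read_stage_tsv("results/allelic_ratios.tsv", "ratios")
cond <- read_stage_tsv("results/condition_means.tsv", "ratios")
calls <- read_stage_tsv("results/escape_calls.tsv", "escape")
escapees <- calls$gene_id[calls$status == "escapee"]

timepoints <- sort(unique(sheet$dox_days[sheet$dox_days > 0 &
                                           sheet$washout_days == 0]))
all_out <- list()
for (t in timepoints) {
  contrast <- c("untreated", condition_label(t))
  tests <- fit_binomial_glm(ratios[ratios$gene_id %in% escapees, ],
                            sheet, contrast)
  tests$p_adjusted <- adjust_pvalues(tests$p_value, "holm")
  sil <- call_silencing(tests, cond)
  out <- merge(tests, sil[, c("gene_id", "reduction_fraction", "significant",
                              "silenced_by_dox")], by = "gene_id")
  message(sprintf("day %2d: %d/%d escapees silenced (significant >=50%% reduction)",
                  t, sum(out$silenced_by_dox), nrow(out)))
  all_out[[as.character(t)]] <- cbind(dox_days = t, out)
}
res <- do.call(rbind, all_out)
write_stage_tsv(res, "results/imbalance_silencing.tsv")
message("wrote results/imbalance_silencing.tsv")
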