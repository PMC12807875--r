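#!/usr/bin/env Rscript
# Stage 6: reversibility after Dox washout. For each induction duration
# with a washout arm, compares washout ratios with untreated ratios and
# classifies escapees as reversible / partially irreversible / irreversible.
# Category-wise recovery differences are tested pairwise (rank-sum, BH).

library(xciescape)

cond <- read_stage_tsv("results/condition_means.tsv", "ratios")
calls <- read_stage_tsv("results/escape_calls.tsv", "escape")
escapees <- calls$gene_id[calls$status == "escapee"]

rev <- classify_reversibility(escapees, cond)
for (d in sort(unique(rev$induction_days))) {
  tab <- table(rev$class[rev$induction_days == d])
  message(sprintf("Dox %2d d + washout: %s", d,
                  paste(names(tab), tab, collapse = ", ")))
}

# do categories differ in fold recovery?
rev$category <- calls$category[match(rev$gene_id, calls$gene_id)]
one_dur <- rev[rev$induction_days == max(rev$induction_days) &
                 is.finite(rev$fold_recovery), ]
if (length(unique(one_dur$category)) >= 2) {
  cmp <- compare_categories(one_dur$fold_recovery, one_dur$category)
  for (i in seq_len(nrow(cmp))) {
    message(sprintf("fold recovery %s vs %s: p_adj = %.3g",
                    cmp$group1[i], cmp$group2[i], cmp$p_adjusted[i]))
  }
}

write_stage_tsv(rev, "results/reversibility.tsv")
message("wrote results/reversibility.tsv")
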