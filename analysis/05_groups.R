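#!/usr/bin/env Rscript
# Stage 5: genomic organization of escapees. Partitions escapees into local
# gene groups (starts within 100 kb, chained) and asks whether neighbouring
# escapees have more similar silencing half-lives than random gene pairs.

library(xciescape)

ann_df <- read_stage_tsv("results/sim/gene_annotation.tsv", "simulate")
annotation <- xciescape:::validate_gene_annotation(ann_df)
calls <- read_stage_tsv("results/escape_calls.tsv", "escape")
fits <- read_stage_tsv("results/decay_fits.tsv", "kinetics")
escapees <- calls$gene_id[calls$status == "escapee"]

groups <- partition_gene_groups(escapees, annotation)
s <- attr(groups, "summary")
message(sprintf("%d gene groups: %d with >=3 members, %d singles/pairs (sizes %d-%d)",
                s$n_groups, s$n_groups_ge3, s$n_singles_or_pairs,
                s$size_range[1], s$size_range[2]))

nb <- neighbor_similarity_test(fits, annotation, n_permutations = 1000,
                               seed = 1)
if (nb$applicable) {
  message(sprintf(
    "neighbour half-life similarity: observed mean |dHL| = %.2f d vs null %.2f d, p = %.3g (%d pairs)",
    nb$observed_statistic, nb$null_mean, nb$p_value, nb$n_pairs))
} else {
  message("too few neighbour pairs with reliable fits for the permutation test")
}

write_stage_tsv(groups, "results/gene_groups.tsv")
message("wrote results/gene_groups.tsv")
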