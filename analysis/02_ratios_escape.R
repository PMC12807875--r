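#!/usr/bin/env Rscript
# Stage 2: allelic ratios (Xi fraction), low-expression filter, condition
# means, escape calling in the untreated state, and escape-category
# assignment against the cross-study matrix.

library(xciescape)

counts <- read_allelic_counts("results/sim/allelic_counts.tsv", "long_tsv")
sheet <- read_sample_sheet("results/sim/sample_sheet.tsv")
studies <- read_stage_tsv("results/sim/study_matrix.tsv", "simulate")

ratios <- compute_allelic_ratio(counts, sheet)
keep <- filter_low_expression(ratios)
low <- setdiff(unique(ratios$gene_id), keep)
message(sprintf("%d of %d genes pass the mean allelic count >= 10 filter",
                length(keep), length(unique(ratios$gene_id))))

cond <- aggregate_conditions(ratios, sheet)
calls <- call_escape(ratios, sheet, excluded_low_expression = low)
cats <- annotate_clone_specific(calls, classify_meta(studies))

message(sprintf("escape status: %s",
                paste(names(table(calls$status)), table(calls$status),
                      collapse = ", ")))
message(sprintf("escapee categories: %s",
                paste(names(table(cats$category[cats$status == "escapee"])),
                      table(cats$category[cats$status == "escapee"]),
                      collapse = ", ")))

# Xist induction level and its correlation with mean escape across samples
fc <- expression_fold_change(counts, sheet, "untreated")
esc <- calls$gene_id[calls$status == "escapee"]
esc_ratios <- ratios[ratios$gene_id %in% esc & ratios$defined, ]
mean_escape <- tapply(esc_ratios$ratio, esc_ratios$sample_id, mean)
xist_fc <- fc[fc$gene_id == "Xist", ]
xist <- xist_fc$fold_change[match(names(mean_escape), xist_fc$sample_id)]
corr <- correlate_escape_xist(as.numeric(mean_escape), xist)
message(sprintf("mean escape vs Xist level: Pearson R = %.2f (p = %.2g, n = %d)",
                corr$r, corr$p_value, corr$n))

dir.create("results", showWarnings = FALSE)
write_stage_tsv(ratios, "results/allelic_ratios.tsv")
write_stage_tsv(cond, "results/condition_means.tsv")
write_stage_tsv(merge(calls, cats[, c("gene_id", "category")], by = "gene_id"),
                "results/escape_calls.tsv")
message("wrote results/allelic_ratios.tsv, condition_means.tsv, escape_calls.tsv")
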