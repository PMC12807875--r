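#' Compute per-gene, per-sample allelic ratios (Xi fraction)
#'
#' The allelic ratio (d-score) of a gene in a sample is the fraction of
#' haplotype-assigned reads coming from the inactive X:
#' `r = Xi / (Xi + Xa)`. Which haplotype is the Xi is taken from the sample
#' sheet (`xi_haplotype`), so the same counts table can serve clones with
#' opposite skewing. Ratios with zero allelic coverage are undefined and
#' flagged (`defined = FALSE`), never silently zero.
#'
#' @param counts An allelic count table (see [read_allelic_counts()]).
#' @param sheet A sample sheet covering every sample in `counts`.
#' @return A `data.frame` with columns `gene_id`, `sample_id`, `xi_count`,
#'   `xa_count`, `total`, `ratio`, `defined`.
#' @export
compute_allelic_ratio <- function(counts, sheet) {
  missing_samples <- setdiff(unique(counts$sample_id), sheet$sample_id)
  if (length(missing_samples) > 0) {
    xe_integrity_error(sprintf("samples in counts but not in sample sheet: %s",
                               paste(missing_samples, collapse = ", ")))
  }
  xi_hap <- sheet$xi_haplotype[match(counts$sample_id, sheet$sample_id)]
  xi <- ifelse(xi_hap == "hap1", counts$count_hap1, counts$count_hap2)
  xa <- ifelse(xi_hap == "hap1", counts$count_hap2, counts$count_hap1)
  total <- xi + xa
  out <- data.frame(gene_id = counts$gene_id, sample_id = counts$sample_id,
                    xi_count = xi, xa_count = xa, total = total,
                    ratio = ifelse(total > 0, xi / total, NA_real_),
                    defined = total > 0, stringsAsFactors = FALSE)
  class(out) <- c("allelic_ratio", "data.frame")
  out
}

#' Filter lowly expressed genes by mean allelic coverage
#'
#' Genes whose mean allelic read count (summing both haplotypes) across the
#' analysis samples is below the threshold are excluded; the default of 10
#' matches the standard escape-calling filter. "Lower than ten" is strict:
#' a mean of exactly 10 is retained.
#'
#' @param ratios Output of [compute_allelic_ratio()].
#' @param min_mean_allelic_count Retention threshold on the per-gene mean of
#'   `xi + xa` over samples (default 10 reads).
#' @return Character vector of retained gene ids, in first-appearance order,
#'   with attribute `excluded`: a `data.frame` of dropped genes and reasons.
#' @export
filter_low_expression <- function(ratios, min_mean_allelic_count = 10) {
  if (nrow(ratios) == 0) {
    warning("empty ratio table; no genes to filter")
    out <- character(0)
    attr(out, "excluded") <- data.frame(gene_id = character(0),
                                        reason = character(0),
                                        mean_allelic_count = numeric(0))
    return(out)
  }
  genes <- unique(ratios$gene_id)
  means <- vapply(split(ratios$total, ratios$gene_id)[genes], mean, 0)
  keep <- genes[means >= min_mean_allelic_count]
  dropped <- genes[means < min_mean_allelic_count]
  attr(keep, "excluded") <- data.frame(
    gene_id = dropped, reason = rep("low_expression", length(dropped)),
    mean_allelic_count = unname(means[dropped]), stringsAsFactors = FALSE)
  keep
}

#' Average allelic ratios per condition
#'
#' Replicate ratios are averaged per (gene, condition) as unweighted means
#' of the defined per-replicate ratios (not pooled counts); samples with
#' undefined ratios do not contribute. Conditions with no defined ratio for
#' a gene emit no row.
#'
#' @param ratios Output of [compute_allelic_ratio()].
#' @param sheet The sample sheet (supplies condition labels and design
#'   columns).
#' @return A `data.frame` with `gene_id`, `condition_label`, `dox_days`,
#'   `washout_days`, `auxin`, `mean_ratio`, `n_replicates`,
#'   `mean_allelic_count`.
#' @export
aggregate_conditions <- function(ratios, sheet) {
  idx <- match(ratios$sample_id, sheet$sample_id)
  if (anyNA(idx)) {
    xe_integrity_error("ratio table contains samples absent from the sample sheet")
  }
  df <- ratios[ratios$defined, , drop = FALSE]
  idx <- idx[ratios$defined]
  df$condition_label <- sheet$condition_label[idx]
  key <- interaction(df$gene_id, df$condition_label, drop = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(gene_id = g$gene_id[1L], condition_label = g$condition_label[1L],
               mean_ratio = mean(g$ratio), n_replicates = nrow(g),
               mean_allelic_count = mean(g$total), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  cidx <- match(agg$condition_label, sheet$condition_label)
  agg$dox_days <- sheet$dox_days[cidx]
  agg$washout_days <- sheet$washout_days[cidx]
  agg$auxin <- sheet$auxin[cidx]
  agg <- agg[order(agg$gene_id, agg$dox_days, agg$washout_days), ,
             drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("condition_ratio_matrix", "data.frame")
  agg
}

#' Library-size-normalized expression and fold change
#'
#' CPM uses the total haplotype-assigned counts of each sample as library
#' size by default (`library_sizes` overrides, e.g. with totals from the
#' unsplit alignment). Fold change is relative to the mean CPM of the
#' reference condition, the usual way induction levels (e.g. of Xist) are
#' reported.
#'
#' @param counts An allelic count table.
#' @param sheet The sample sheet.
#' @param reference_condition Condition label of the reference (e.g.
#'   `"untreated"`).
#' @param library_sizes Optional named numeric vector of per-sample library
#'   sizes.
#' @return A `data.frame` with `gene_id`, `sample_id`, `cpm`, `fold_change`.
#' @export
expression_fold_change <- function(counts, sheet, reference_condition = "untreated",
                                   library_sizes = NULL) {
  if (!reference_condition %in% sheet$condition_label) {
    xe_config_error(sprintf("reference condition '%s' absent from sample sheet",
                            reference_condition))
  }
  total <- counts$count_hap1 + counts$count_hap2
  if (is.null(library_sizes)) {
    library_sizes <- tapply(total, counts$sample_id, sum)
  } else if (is.null(names(library_sizes)) ||
             !all(unique(counts$sample_id) %in% names(library_sizes))) {
    xe_config_error("library_sizes must be named by sample_id and cover all samples")
  }
  cpm <- 1e6 * total / as.numeric(library_sizes[counts$sample_id])
  ref_samples <- sheet$sample_id[sheet$condition_label == reference_condition]
  is_ref <- counts$sample_id %in% ref_samples
  ref_mean <- tapply(cpm[is_ref], counts$gene_id[is_ref], mean)
  out <- data.frame(gene_id = counts$gene_id, sample_id = counts$sample_id,
                    cpm = cpm,
                    fold_change = cpm / as.numeric(ref_mean[counts$gene_id]),
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_level", "data.frame")
  out
}
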