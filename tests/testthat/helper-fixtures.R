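# Small in-code fixtures shared across test files.

make_sheet <- function(dox_days = c(0, 0, 21, 21), washout_days = 0,
                       auxin = FALSE, xi_haplotype = "hap1") {
  n <- length(dox_days)
  df <- data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    dox_days = dox_days,
    washout_days = rep_len(washout_days, n),
    auxin = rep_len(auxin, n),
    replicate = stats::ave(seq_len(n), dox_days, rep_len(washout_days, n),
                           FUN = seq_along),
    xi_haplotype = rep_len(xi_haplotype, n))
  xciescape:::validate_sample_sheet(df)
}

make_counts <- function(gene_id, sample_id, xi, xa, chromosome = "chrX") {
  xciescape:::validate_allelic_counts(data.frame(
    gene_id = gene_id, sample_id = sample_id, count_hap1 = xi,
    count_hap2 = xa, chromosome = chromosome, stringsAsFactors = FALSE))
}

# Ratios table straight from xi/xa vectors under a hap1-Xi sheet.
make_ratios <- function(gene_id, sample_id, xi, xa) {
  total <- xi + xa
  df <- data.frame(gene_id = gene_id, sample_id = sample_id, xi_count = xi,
                   xa_count = xa, total = total,
                   ratio = ifelse(total > 0, xi / total, NA_real_),
                   defined = total > 0, stringsAsFactors = FALSE)
  class(df) <- c("allelic_ratio", "data.frame")
  df
}

make_annotation <- function(gene_id, start, chromosome = "chrX",
                            width = 5000L) {
  xciescape:::validate_gene_annotation(data.frame(
    gene_id = gene_id, chromosome = rep_len(chromosome, length(gene_id)),
    start = as.integer(start), end = as.integer(start + width),
    strand = "+", stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Replicate-level binomial observations of a decay trajectory.
simulate_trajectory <- function(r0, k, b, depth, n_reps = 3,
                                time_grid = c(0, 3, 7, 14, 21)) {
  t <- rep(time_grid, each = n_reps)
  true_r <- (r0 - b) * exp(-k * t) + b
  n <- rep_len(depth, length(t))
  list(t = t, ratio = stats::rbinom(length(t), n, true_r) / n)
}
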