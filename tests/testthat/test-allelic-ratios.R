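test_that("allelic ratio is Xi/(Xi+Xa) with the sheet-declared Xi haplotype", {
  sheet <- make_sheet(dox_days = c(0, 0))
  counts <- make_counts(rep(c("g1", "g2", "g3"), each = 2),
                        rep(c("s1", "s2"), 3),
                        xi = c(30L, 30L, 0L, 0L, 5L, 5L),
                        xa = c(70L, 70L, 0L, 0L, 5L, 5L))
  r <- compute_allelic_ratio(counts, sheet)
  expect_equal(r$ratio[r$gene_id == "g1"], c(0.3, 0.3))
  expect_true(all(is.na(r$ratio[r$gene_id == "g2"])))
  expect_false(any(r$defined[r$gene_id == "g2"]))
  expect_equal(r$ratio[r$gene_id == "g3"], c(0.5, 0.5))

  # hap2-Xi clone swaps the roles of the count columns
  sheet2 <- make_sheet(dox_days = c(0, 0), xi_haplotype = "hap2")
  r2 <- compute_allelic_ratio(counts, sheet2)
  expect_equal(r2$ratio[r2$gene_id == "g1"], c(0.7, 0.7))

  orphan <- make_counts("g1", "s99", 1L, 1L)
  expect_error(compute_allelic_ratio(orphan, sheet),
               class = "xe_integrity_error")
})

test_that("low-expression filter keeps genes with mean allelic count >= 10", {
  r <- make_ratios(rep(c("gA", "gB"), c(3, 2)),
                   c("s1", "s2", "s3", "s1", "s2"),
                   xi = c(4L, 5L, 6L, 2L, 3L), xa = c(4L, 5L, 6L, 2L, 3L))
  # gA sums {8,10,12} mean 10 (boundary retained); gB sums {4,6} mean 5
  keep <- filter_low_expression(r)
  expect_equal(keep, "gA", ignore_attr = TRUE)
  excluded <- attr(keep, "excluded")
  expect_equal(excluded$gene_id, "gB")
  expect_equal(excluded$reason, "low_expression")

  all_kept <- filter_low_expression(r, min_mean_allelic_count = 0)
  expect_setequal(as.character(all_kept), c("gA", "gB"))

  expect_warning(out <- filter_low_expression(r[0, ]), regexp = "empty")
  expect_length(out, 0L)
})

test_that("condition aggregation averages defined replicate ratios unweighted", {
  sheet <- make_sheet(dox_days = c(0, 0, 0))
  r <- make_ratios(rep(c("g1", "g2", "g3"), each = 3),
                   rep(c("s1", "s2", "s3"), 3),
                   xi = c(2L, 4L, 0L,  0L, 4L, 0L,  1L, 1L, 1L),
                   xa = c(8L, 6L, 0L,  0L, 6L, 0L,  3L, 3L, 3L))
  cm <- aggregate_conditions(r, sheet)
  expect_equal(cm$mean_ratio[cm$gene_id == "g1"], 0.3)  # mean of 0.2, 0.4
  expect_equal(cm$n_replicates[cm$gene_id == "g1"], 2L) # s3 undefined
  expect_equal(cm$mean_ratio[cm$gene_id == "g2"], 0.4)
  expect_equal(cm$n_replicates[cm$gene_id == "g2"], 1L)
  expect_equal(cm$mean_ratio[cm$gene_id == "g3"], 0.25) # idempotent on equals
})

test_that("CPM and fold change follow the library-size normalization", {
  sheet <- make_sheet(dox_days = c(0, 21))
  # library sizes: s1 = 1e6 in total, gene g1 contributes 100
  counts <- make_counts(rep(c("g1", "filler"), each = 2),
                        rep(c("s1", "s2"), 2),
                        xi = c(60L, 120L, 499950L, 499900L),
                        xa = c(40L, 80L, 499950L, 499900L))
  fc <- expression_fold_change(counts, sheet, "untreated")
  expect_equal(fc$cpm[fc$gene_id == "g1" & fc$sample_id == "s1"], 100)
  # reference sample equals the reference mean -> fold change 1
  expect_equal(fc$fold_change[fc$gene_id == "g1" & fc$sample_id == "s1"], 1)
  # doubled counts at fixed library size -> doubled fold change
  expect_equal(fc$fold_change[fc$gene_id == "g1" & fc$sample_id == "s2"], 2)
  expect_error(expression_fold_change(counts, sheet, "dox99d"),
               class = "xe_config_error")
})

test_that("ratios and CPM are invariant to sample order and count scaling", {
  set.seed(42)
  sheet <- make_sheet(dox_days = c(0, 0, 21, 21))
  genes <- sprintf("g%02d", 1:8)
  counts <- make_counts(rep(genes, each = 4), rep(sheet$sample_id, 8),
                        xi = rbinom(32, 100, 0.3) + 1L,
                        xa = rbinom(32, 100, 0.7) + 1L)
  r <- compute_allelic_ratio(counts, sheet)
  expect_true(all(r$ratio >= 0 & r$ratio <= 1))
  expect_equal(r$xi_count + r$xa_count, counts$count_hap1 + counts$count_hap2)

  perm <- counts[sample(nrow(counts)), , drop = FALSE]
  cm1 <- aggregate_conditions(r, sheet)
  cm2 <- aggregate_conditions(compute_allelic_ratio(perm, sheet), sheet)
  expect_equal(cm1, cm2)

  # scaling one sample's counts by c > 0 changes neither ratios nor cpm
  scaled <- counts
  idx <- scaled$sample_id == "s1"
  scaled$count_hap1[idx] <- scaled$count_hap1[idx] * 3L
  scaled$count_hap2[idx] <- scaled$count_hap2[idx] * 3L
  rs <- compute_allelic_ratio(scaled, sheet)
  expect_equal(rs$ratio[idx], r$ratio[idx])
  fc1 <- expression_fold_change(counts, sheet, "untreated")
  fc2 <- expression_fold_change(scaled, sheet, "untreated")
  expect_equal(fc1$cpm[idx], fc2$cpm[idx])
})
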