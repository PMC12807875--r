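esc_fixture <- function(ratios_by_gene) {
  # three untreated replicates per gene with exact target ratios
  genes <- names(ratios_by_gene)
  n_rep <- length(ratios_by_gene[[1]])
  sheet <- make_sheet(dox_days = rep(0, n_rep))
  denom <- 1000L
  xi <- unlist(lapply(ratios_by_gene, function(r) as.integer(round(r * denom))))
  r <- make_ratios(rep(genes, each = n_rep),
                   rep(sheet$sample_id[seq_len(n_rep)], length(genes)),
                   xi = xi, xa = denom - xi)
  list(ratios = r, sheet = sheet)
}

test_that("escape calling applies thresholds, rules and precedence", {
  fx <- esc_fixture(list(
    esc = c(0.15, 0.12, 0.20),     # all replicates > 0.1 -> escapee
    mixed = c(0.15, 0.08, 0.15),   # fails all-replicates, passes fraction
    high = c(0.85, 0.85, 0.85),    # > 0.8 -> excluded
    Xist = c(0.95, 0.95, 0.95),    # excluded regardless of ratio
    low = c(0.30, 0.30, 0.30),     # excluded by the expression filter
    sil = c(0.05, 0.02, 0.08)))
  calls <- call_escape(fx$ratios, fx$sheet,
                       excluded_low_expression = "low")
  status <- setNames(calls$status, calls$gene_id)
  expect_equal(status[["esc"]], "escapee")
  expect_equal(status[["mixed"]], "silenced")
  expect_equal(status[["high"]], "excluded_high_ratio")
  expect_equal(status[["Xist"]], "excluded_xist")
  expect_equal(status[["low"]], "excluded_low_expression")
  expect_equal(status[["sil"]], "silenced")
  expect_equal(unname(calls$basis_ratio[calls$gene_id == "esc"]),
               mean(c(0.15, 0.12, 0.20)), tolerance = 1e-3)

  frac <- call_escape(fx$ratios, fx$sheet, rule = "fraction",
                      fraction_threshold = 0.5,
                      excluded_low_expression = "low")
  expect_equal(frac$status[frac$gene_id == "mixed"], "escapee")
})

test_that("every informative gene gets exactly one status, deterministically", {
  set.seed(11)
  genes <- sprintf("g%02d", 1:30)
  sheet <- make_sheet(dox_days = c(0, 0, 0))
  r <- make_ratios(rep(genes, each = 3), rep(sheet$sample_id, 30),
                   xi = rbinom(90, 200, runif(90, 0.01, 0.95)),
                   xa = 0L)
  r$xa_count <- 200L - r$xi_count
  r$total <- 200L
  r$ratio <- r$xi_count / 200
  c1 <- call_escape(r, sheet)
  c2 <- call_escape(r, sheet)
  expect_identical(c1, c2)
  expect_setequal(c1$gene_id, genes)
  expect_equal(anyDuplicated(c1$gene_id), 0L)

  # raising the escape threshold never increases the escapee count
  thresholds <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  n_escapees <- vapply(thresholds, function(th) {
    sum(call_escape(r, sheet, ratio_threshold = th)$status == "escapee")
  }, 0L)
  expect_true(all(diff(n_escapees) <= 0))
})

test_that("meta-classification follows the detected/escaping study rules", {
  mk <- function(gene, n_det, n_esc, n_studies = 6) {
    call <- rep("not_detected", n_studies)
    if (n_det > 0) call[seq_len(n_det)] <- "silenced"
    if (n_esc > 0) call[seq_len(n_esc)] <- "escaping"
    data.frame(gene_id = gene, study_id = sprintf("st%d", seq_len(n_studies)),
               call = call)
  }
  m <- rbind(mk("gA", 4, 3),   # 0.75 > 0.5, detected >= 3 -> constitutive
             mk("gB", 2, 1),   # detected < 3 -> facultative
             mk("gC", 5, 0),   # escaping nowhere -> silenced
             mk("gD", 4, 2))   # exactly 50% -> facultative (needs > 50%)
  cats <- classify_meta(m)
  cat_of <- setNames(cats$category, cats$gene_id)
  expect_equal(cat_of[["gA"]], "constitutive")
  expect_equal(cat_of[["gB"]], "facultative")
  expect_equal(cat_of[["gC"]], "silenced")
  expect_equal(cat_of[["gD"]], "facultative")

  dup <- rbind(mk("gA", 1, 0), mk("gA", 1, 0))
  expect_error(classify_meta(dup), class = "xe_integrity_error")
})

test_that("local escapees unknown to the literature become clone-specific", {
  calls <- data.frame(
    gene_id = c("novel", "known", "off"),
    status = c("escapee", "escapee", "silenced"),
    basis_ratio = c(0.3, 0.3, 0.02))
  cats <- data.frame(gene_id = c("known", "off"),
                     category = c("facultative", "silenced"))
  out <- annotate_clone_specific(calls, cats)
  cat_of <- setNames(out$category, out$gene_id)
  expect_equal(cat_of[["novel"]], "clone_specific")   # absent from matrix
  expect_equal(cat_of[["known"]], "facultative")      # literature wins
  expect_equal(cat_of[["off"]], "silenced")           # non-escapee untouched

  # locally escaping but 'silenced' in every study is also clone-specific
  calls2 <- data.frame(gene_id = "g", status = "escapee", basis_ratio = 0.2)
  cats2 <- data.frame(gene_id = "g", category = "silenced")
  expect_equal(annotate_clone_specific(calls2, cats2)$category,
               "clone_specific")
})
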