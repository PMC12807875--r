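#' Read a haplotype-resolved allelic count table
#'
#' Reads gene x sample read counts split by parental haplotype, as produced
#' downstream of allele-split alignment (e.g. SNPsplit + featureCounts).
#' Two dialects are accepted:
#' \describe{
#'   \item{`long_tsv`}{columns `gene_id`, `sample_id`, `count_hap1`,
#'     `count_hap2` and optionally `chromosome`; one row per gene x sample.}
#'   \item{`wide_tsv`}{a `gene_id` column (optionally `chromosome`) plus one
#'     pair of columns `<sample>_hap1` / `<sample>_hap2` per sample.}
#' }
#' Lines starting with `#` are skipped. Counts must be non-negative
#' integers; haplotype-unassigned reads are expected to have been dropped
#' upstream and never enter the table.
#'
#' @param path Path to a tab-separated file.
#' @param format One of `"long_tsv"`, `"wide_tsv"`.
#' @return A `data.frame` with columns `gene_id`, `sample_id`, `count_hap1`,
#'   `count_hap2`, `chromosome` (NA when absent), in file gene order.
#' @export
read_allelic_counts <- function(path, format = c("long_tsv", "wide_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) xe_format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (format == "long_tsv") {
    tbl <- counts_from_long(df)
  } else {
    tbl <- counts_from_wide(df)
  }
  validate_allelic_counts(tbl)
}

counts_from_long <- function(df) {
  required <- c("gene_id", "sample_id", "count_hap1", "count_hap2")
  for (col in required) {
    if (!col %in% names(df)) {
      xe_format_error(sprintf("allelic count table is missing column '%s'", col))
    }
  }
  if (!"chromosome" %in% names(df)) df$chromosome <- NA_character_
  df[, c("gene_id", "sample_id", "count_hap1", "count_hap2", "chromosome")]
}

counts_from_wide <- function(df) {
  if (!"gene_id" %in% names(df)) {
    xe_format_error("allelic count table is missing column 'gene_id'")
  }
  chrom <- if ("chromosome" %in% names(df)) df$chromosome else NA_character_
  value_cols <- setdiff(names(df), c("gene_id", "chromosome"))
  hap <- regmatches(value_cols, regexec("^(.*)_(hap[12])$", value_cols))
  bad <- value_cols[vapply(hap, length, 1L) == 0L]
  if (length(bad) > 0) {
    xe_format_error(sprintf(
      "wide count columns must be named <sample>_hap1/<sample>_hap2; offending: %s",
      paste(bad, collapse = ", ")))
  }
  samples <- unique(vapply(hap, `[`, "", 2L))
  for (s in samples) {
    for (h in c("hap1", "hap2")) {
      if (!paste0(s, "_", h) %in% value_cols) {
        xe_format_error(sprintf("missing column '%s_%s' to pair sample '%s'", s, h, s))
      }
    }
  }
  long <- do.call(rbind, lapply(samples, function(s) {
    data.frame(gene_id = df$gene_id, sample_id = s,
               count_hap1 = df[[paste0(s, "_hap1")]],
               count_hap2 = df[[paste0(s, "_hap2")]],
               chromosome = chrom, stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

validate_allelic_counts <- function(tbl) {
  for (col in c("count_hap1", "count_hap2")) {
    x <- tbl[[col]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      xe_integrity_error(sprintf("column '%s' contains non-numeric or missing counts", col))
    }
    if (any(x < 0) || any(x != round(x))) {
      xe_integrity_error(sprintf("column '%s' contains negative or non-integer counts", col))
    }
    tbl[[col]] <- as.integer(round(x))
  }
  key <- paste(tbl$gene_id, tbl$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tbl[duplicated(key), , drop = FALSE][1L, ]
    xe_integrity_error(sprintf("duplicate (gene, sample) pair: (%s, %s)",
                               dup$gene_id, dup$sample_id))
  }
  tbl$gene_id <- as.character(tbl$gene_id)
  tbl$sample_id <- as.character(tbl$sample_id)
  class(tbl) <- c("allelic_count_table", "data.frame")
  tbl
}

#' Write an allelic count table
#'
#' @param tbl Table from [read_allelic_counts()] or [simulate_dataset()].
#' @param path Output TSV path.
#' @export
write_allelic_counts <- function(tbl, path) {
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Derive a condition label from treatment metadata
#'
#' Labels are a deterministic function of the design columns so that
#' grouping can never drift from the metadata: e.g. `untreated`,
#' `dox7d`, `dox14d_wash7d`, `dox7d_auxin`.
#'
#' @param dox_days Days of doxycycline (Xist induction); 0 = untreated.
#' @param washout_days Days of Dox washout after induction.
#' @param auxin Logical, auxin-inducible degron active.
#' @return Character vector of labels.
#' @export
condition_label <- function(dox_days, washout_days = 0, auxin = FALSE) {
  n <- max(length(dox_days), length(washout_days), length(auxin))
  dox_days <- rep_len(dox_days, n)
  washout_days <- rep_len(washout_days, n)
  auxin <- rep_len(auxin, n)
  vapply(seq_len(n), function(i) {
    parts <- character(0)
    if (dox_days[i] > 0) parts <- c(parts, sprintf("dox%gd", dox_days[i]))
    if (washout_days[i] > 0) parts <- c(parts, sprintf("wash%gd", washout_days[i]))
    if (isTRUE(auxin[i])) parts <- c(parts, "auxin")
    if (length(parts) == 0) "untreated" else paste(parts, collapse = "_")
  }, "")
}

#' Read and validate a sample sheet
#'
#' Required columns: `sample_id`, `dox_days`, `washout_days`, `auxin`,
#' `replicate`, `xi_haplotype` (one of `hap1`/`hap2`, the haplotype carried
#' by the inactive X in this clone). A derived `condition_label` column is
#' appended (see [condition_label()]).
#'
#' @param path Path to a TSV file.
#' @return A validated `data.frame` of per-sample metadata.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) xe_format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  required <- c("sample_id", "dox_days", "washout_days", "auxin", "replicate",
                "xi_haplotype")
  for (col in required) {
    if (!col %in% names(df)) {
      xe_format_error(sprintf("sample sheet is missing column '%s'", col))
    }
  }
  if (anyDuplicated(df$sample_id)) {
    xe_integrity_error(sprintf("duplicate sample_id: %s",
                               df$sample_id[duplicated(df$sample_id)][1L]))
  }
  if (!all(df$xi_haplotype %in% c("hap1", "hap2"))) {
    xe_format_error(sprintf(
      "xi_haplotype must be 'hap1' or 'hap2'; got: %s",
      paste(unique(setdiff(df$xi_haplotype, c("hap1", "hap2"))), collapse = ", ")))
  }
  if (any(df$dox_days < 0) || any(df$washout_days < 0)) {
    xe_integrity_error("dox_days and washout_days must be non-negative")
  }
  df$auxin <- as.logical(df$auxin)
  if (anyNA(df$auxin)) xe_format_error("auxin column must be logical (TRUE/FALSE)")
  df$sample_id <- as.character(df$sample_id)
  df$condition_label <- condition_label(df$dox_days, df$washout_days, df$auxin)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname read_sample_sheet
#' @param sheet A sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- as.data.frame(sheet)
  out$condition_label <- NULL  # derived, never persisted
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
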