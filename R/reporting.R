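#' Assemble a machine-readable run summary
#'
#' Deterministic tallies over the pipeline's stage outputs: escape status
#' and category counts, silencing calls, decay-model selection, gene-group
#' summary and reversibility class counts per induction duration, together
#' with the thresholds and seed used. Every count is a direct recount of
#' the stage table it summarizes.
#'
#' @param escape_calls Output of [call_escape()] (optional).
#' @param categories Output of [annotate_clone_specific()] /
#'   [classify_meta()] (optional).
#' @param silencing Output of [call_silencing()] (optional).
#' @param fits Output of [fit_gene_kinetics()] (optional).
#' @param groups Output of [partition_gene_groups()] (optional).
#' @param reversibility Output of [classify_reversibility()] (optional).
#' @param thresholds Named list of thresholds used in the run.
#' @param seed Seed used for randomized stages.
#' @return Nested list of class `run_summary`.
#' @export
summarize_run <- function(escape_calls = NULL, categories = NULL,
                          silencing = NULL, fits = NULL, groups = NULL,
                          reversibility = NULL, thresholds = list(),
                          seed = NULL) {
  tally <- function(x) as.list(table(x))
  out <- list(thresholds = thresholds, seed = seed)
  if (!is.null(escape_calls)) {
    out$escape_status <- tally(escape_calls$status)
    out$n_escapees <- sum(escape_calls$status == "escapee")
  }
  if (!is.null(categories)) out$escape_category <- tally(categories$category)
  if (!is.null(silencing)) {
    out$silencing <- list(
      n_tested = nrow(silencing),
      n_silenced = sum(silencing$silenced_by_dox),
      n_significant = sum(silencing$significant))
  }
  if (!is.null(fits)) {
    out$kinetics <- list(
      selected_model = tally(fits$selected_model),
      n_residual_escape = sum(fits$residual_escape),
      median_half_life_days = stats::median(
        fits$half_life_days[fits$selected_model != "unreliable"], na.rm = TRUE))
  }
  if (!is.null(groups)) out$gene_groups <- attr(groups, "summary")
  if (!is.null(reversibility)) {
    out$reversibility <- lapply(split(reversibility$class,
                                      reversibility$induction_days),
                                function(x) as.list(table(x)))
  }
  class(out) <- "run_summary"
  out
}

#' @rdname summarize_run
#' @param summary A `run_summary`.
#' @param path Output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Gene x condition allelic-ratio matrix for heat maps
#'
#' Reshapes condition means into a matrix with genes in rows (ordered by
#' genomic start when an annotation is given, mirroring a chromosome-order
#' heat map) and conditions in columns (ordered by induction then washout
#' duration).
#'
#' @param cond_matrix Output of [aggregate_conditions()].
#' @param annotation Optional gene annotation for genomic row order.
#' @param genes Optional subset/order of genes to include.
#' @return Numeric matrix of mean allelic ratios (NA where a gene has no
#'   defined mean in a condition).
#' @export
ratio_matrix <- function(cond_matrix, annotation = NULL, genes = NULL) {
  if (is.null(genes)) genes <- unique(cond_matrix$gene_id)
  if (!is.null(annotation)) {
    st <- annotation$start[match(genes, annotation$gene_id)]
    genes <- genes[order(st)]
  }
  conds <- unique(cond_matrix[, c("condition_label", "dox_days", "washout_days")])
  conds <- conds[order(conds$washout_days > 0, conds$dox_days,
                       conds$washout_days), , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(conds),
              dimnames = list(genes, conds$condition_label))
  idx <- cbind(match(cond_matrix$gene_id, genes),
               match(cond_matrix$condition_label, conds$condition_label))
  ok <- !is.na(idx[, 1L]) & !is.na(idx[, 2L])
  m[idx[ok, , drop = FALSE]] <- cond_matrix$mean_ratio[ok]
  m
}

#' Read a stage output table, failing with the stage name
#'
#' @param path TSV path written by an earlier pipeline stage.
#' @param stage Human-readable stage name used in the error message.
#' @return `data.frame`.
#' @export
read_stage_tsv <- function(path, stage) {
  if (!file.exists(path)) {
    xe_config_error(sprintf("missing output of stage '%s': %s", stage, path))
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a stage output table
#'
#' @param df Table to write.
#' @param path Output TSV path.
#' @export
write_stage_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
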