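#' Fold recovery of escape after washout
#'
#' The ratio of the allelic ratio after washout to the allelic ratio in
#' untreated samples. Undefined (NA) when the untreated ratio is 0.
#'
#' @param untreated_ratio,washout_ratio Non-negative allelic ratios
#'   (vectorized).
#' @return Numeric vector of fold recoveries.
#' @export
compute_fold_recovery <- function(untreated_ratio, washout_ratio) {
  if (any(untreated_ratio < 0, na.rm = TRUE) ||
      any(washout_ratio < 0, na.rm = TRUE)) {
    xe_value_error("allelic ratios must be non-negative")
  }
  ifelse(!is.na(untreated_ratio) & untreated_ratio > 0,
         washout_ratio / untreated_ratio, NA_real_)
}

#' Classify silencing reversibility after Dox washout
#'
#' Per gene and induction duration, compares the mean allelic ratio after
#' washout with the untreated mean. A gene is *reversible* when it reaches
#' at least 50% of untreated escape (`fold_recovery >= 0.5`) and an
#' allelic ratio > 0.1 after washout; *partially irreversible* when it
#' reaches 10-50% of untreated escape (inclusive at 10%) with washout
#' ratio > 0.1; *irreversible* otherwise. Genes with untreated ratio 0 are
#' `undefined`. Both legend conditions must hold, so a washout ratio
#' <= 0.1 forces irreversible regardless of fold recovery.
#'
#' @param genes Gene ids to classify (typically the escapee set).
#' @param cond_matrix Condition means from [aggregate_conditions()]
#'   (must contain the untreated and washout conditions).
#' @param untreated_condition Label of the untreated condition.
#' @param reversible_min Fold-recovery threshold for full reversibility.
#' @param partial_min Fold-recovery threshold for partial irreversibility.
#' @param ratio_floor Washout allelic ratio that must be exceeded.
#' @return `data.frame` with `gene_id`, `induction_days`, `washout_days`,
#'   `untreated_ratio`, `washout_ratio`, `fold_recovery`, `class`;
#'   attribute `summary` tabulates classes per induction duration.
#' @export
classify_reversibility <- function(genes, cond_matrix,
                                   untreated_condition = "untreated",
                                   reversible_min = 0.5, partial_min = 0.1,
                                   ratio_floor = 0.1) {
  untr <- cond_matrix[cond_matrix$condition_label == untreated_condition, ,
                      drop = FALSE]
  wash <- cond_matrix[cond_matrix$washout_days > 0, , drop = FALSE]
  if (nrow(wash) == 0) xe_config_error("no washout conditions in the ratio matrix")
  rows <- lapply(genes, function(g) {
    u <- untr$mean_ratio[untr$gene_id == g]
    if (length(u) != 1) u <- NA_real_
    w <- wash[wash$gene_id == g, , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    fr <- compute_fold_recovery(rep(u, nrow(w)), w$mean_ratio)
    cls <- vapply(seq_len(nrow(w)), function(i) {
      if (is.na(fr[i])) "undefined"
      else if (fr[i] >= reversible_min && w$mean_ratio[i] > ratio_floor) "reversible"
      else if (fr[i] >= partial_min && w$mean_ratio[i] > ratio_floor) "partially_irreversible"
      else "irreversible"
    }, "")
    data.frame(gene_id = g, induction_days = w$dox_days,
               washout_days = w$washout_days, untreated_ratio = u,
               washout_ratio = w$mean_ratio, fold_recovery = fr,
               class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) xe_config_error("no gene has both untreated and washout means")
  rownames(out) <- NULL
  attr(out, "summary") <- lapply(split(out$class, out$induction_days), table)
  class(out) <- c("reversibility_call", "data.frame")
  out
}
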