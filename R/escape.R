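#' Call escape status from untreated allelic ratios
#'
#' An X-linked gene escapes X inactivation when it keeps expression from the
#' Xi. A gene is called an escapee when its untreated allelic ratio exceeds
#' `ratio_threshold` (default 0.1) either in all untreated replicates
#' (`rule = "all_replicates"`, the clone analysis) or in at least
#' `fraction_threshold` of them (`rule = "fraction"`, the population/embryo
#' variant). Genes with mean untreated ratio above `high_ratio_threshold`
#' (default 0.8) are excluded as likely strain-specific expression or
#' mapping artefacts, and Xist itself — the cause of XCI, expressed from
#' the Xi — is never called an escapee.
#'
#' Status precedence: `excluded_xist` > `excluded_high_ratio` >
#' `excluded_low_expression` > `escapee`/`silenced`; genes without any
#' defined untreated ratio are `not_informative`.
#'
#' @param ratios Per-sample ratios from [compute_allelic_ratio()].
#' @param sheet Sample sheet.
#' @param untreated_condition Condition label of the untreated reference.
#' @param rule `"all_replicates"` or `"fraction"`.
#' @param fraction_threshold Minimum fraction of replicates above
#'   `ratio_threshold` under `rule = "fraction"`.
#' @param ratio_threshold Escape threshold on the allelic ratio (strict `>`).
#' @param high_ratio_threshold Exclusion threshold on the mean ratio
#'   (strict `>`).
#' @param xist_gene Gene id of Xist in this annotation.
#' @param excluded_low_expression Gene ids failing the coverage filter
#'   (see [filter_low_expression()]).
#' @return A `data.frame` with `gene_id`, `status`, `basis_ratio` (mean
#'   untreated ratio).
#' @export
call_escape <- function(ratios, sheet, untreated_condition = "untreated",
                        rule = c("all_replicates", "fraction"),
                        fraction_threshold = 0.5, ratio_threshold = 0.1,
                        high_ratio_threshold = 0.8, xist_gene = "Xist",
                        excluded_low_expression = character()) {
  rule <- match.arg(rule)
  if (!untreated_condition %in% sheet$condition_label) {
    xe_config_error(sprintf("untreated condition '%s' absent from sample sheet",
                            untreated_condition))
  }
  untr_samples <- sheet$sample_id[sheet$condition_label == untreated_condition]
  ur <- ratios[ratios$sample_id %in% untr_samples, , drop = FALSE]
  genes <- unique(ratios$gene_id)
  per_gene <- split(ur, factor(ur$gene_id, levels = genes))
  calls <- lapply(genes, function(g) {
    r <- per_gene[[g]]
    def <- r$ratio[r$defined]
    basis <- if (length(def) > 0) mean(def) else NA_real_
    status <- if (g %in% xist_gene) {
      "excluded_xist"
    } else if (!is.na(basis) && basis > high_ratio_threshold) {
      "excluded_high_ratio"
    } else if (g %in% excluded_low_expression) {
      "excluded_low_expression"
    } else if (length(def) == 0) {
      "not_informative"
    } else {
      escaping <- switch(rule,
        all_replicates = all(def > ratio_threshold),
        fraction = mean(def > ratio_threshold) >= fraction_threshold)
      if (escaping) "escapee" else "silenced"
    }
    data.frame(gene_id = g, status = status, basis_ratio = basis,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("escape_call", "data.frame")
  out
}

#' Classify escapees from a cross-study matrix
#'
#' Meta-classification over published escape calls: a gene is a
#' *constitutive* escapee when it is detected in at least
#' `min_studies_detected` studies and escapes in more than
#' `constitutive_fraction` of the studies that detect it; *facultative*
#' when it escapes in at least one study but misses the constitutive rule
#' (escaping in <=50% of studies, or detected in fewer than
#' `min_studies_detected`); *silenced* when detected but escaping nowhere.
#' A tie at exactly 50% escaping is facultative.
#'
#' @param study_matrix `data.frame` with `gene_id`, `study_id`, `call` in
#'   `{escaping, silenced, not_detected}`.
#' @param min_studies_detected Minimum detecting studies for the
#'   constitutive rule.
#' @param constitutive_fraction Escaping fraction that must be exceeded.
#' @return `data.frame` with `gene_id`, `category`, `n_detected`,
#'   `n_escaping`.
#' @export
classify_meta <- function(study_matrix, min_studies_detected = 3,
                          constitutive_fraction = 0.5) {
  if (nrow(study_matrix) == 0) xe_value_error("empty study matrix")
  ok <- study_matrix$call %in% c("escaping", "silenced", "not_detected")
  if (!all(ok)) {
    xe_format_error(sprintf("unknown study call value: %s",
                            paste(unique(study_matrix$call[!ok]), collapse = ", ")))
  }
  key <- paste(study_matrix$gene_id, study_matrix$study_id, sep = "\r")
  if (anyDuplicated(key)) {
    xe_integrity_error("duplicate (gene, study) pair in study matrix")
  }
  per_gene <- split(study_matrix$call, study_matrix$gene_id)
  out <- do.call(rbind, lapply(names(per_gene), function(g) {
    calls <- per_gene[[g]]
    n_det <- sum(calls != "not_detected")
    n_esc <- sum(calls == "escaping")
    category <- if (n_det >= min_studies_detected &&
                    n_esc / n_det > constitutive_fraction) {
      "constitutive"
    } else if (n_esc >= 1) {
      "facultative"
    } else if (n_det >= 1) {
      "silenced"
    } else {
      "unclassified"
    }
    data.frame(gene_id = g, category = category, n_detected = n_det,
               n_escaping = n_esc, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("escape_category", "data.frame")
  out
}

#' Mark clone-specific escapees
#'
#' Genes escaping in the local dataset but with zero escape calls in the
#' literature matrix (meta category `silenced` or `unclassified`/absent)
#' are relabelled `clone_specific`; all other categories are kept.
#'
#' @param calls Local escape calls from [call_escape()].
#' @param categories Meta categories from [classify_meta()].
#' @return `data.frame` with `gene_id`, `category` for every gene in
#'   `calls`.
#' @export
annotate_clone_specific <- function(calls, categories) {
  meta <- categories$category[match(calls$gene_id, categories$gene_id)]
  meta[is.na(meta)] <- "unclassified"
  local_escapee <- calls$status == "escapee"
  category <- ifelse(local_escapee & meta %in% c("silenced", "unclassified"),
                     "clone_specific", meta)
  out <- data.frame(gene_id = calls$gene_id, status = calls$status,
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("escape_category", "data.frame")
  out
}
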