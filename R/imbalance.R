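#' Per-gene binomial GLM test of differential allelic imbalance
#'
#' For each gene the number of Xi reads is modelled as binomial over the
#' total allelic reads with a logit-linear treatment effect,
#' `(xi, total) ~ 1 + treatment`, and the treatment coefficient (log-odds
#' difference between conditions) is tested with a two-sided Wald test.
#' Observations are replicate-level (xi, total) pairs by default;
#' `pooled = TRUE` sums counts per condition first. Boundary data sets
#' (a condition entirely at 0 or at 100% Xi) put the MLE at infinity and
#' are flagged `estimable = FALSE` with an undefined p value; no
#' overdispersion correction is applied (plain binomial likelihood).
#'
#' @param ratios Per-sample ratios from [compute_allelic_ratio()].
#' @param sheet Sample sheet.
#' @param contrast Length-2 character vector `c(control, treated)` of
#'   condition labels.
#' @param pooled Pool replicate counts per condition before fitting.
#' @return `data.frame` with one row per gene: `beta_treatment`,
#'   `std_error`, `wald_statistic`, `p_value`, `estimable`, plus the
#'   contrast labels.
#' @export
fit_binomial_glm <- function(ratios, sheet, contrast, pooled = FALSE) {
  if (length(contrast) != 2) xe_config_error("contrast must name two conditions")
  for (cond in contrast) {
    if (!cond %in% sheet$condition_label) {
      xe_config_error(sprintf("contrast condition '%s' absent from sample sheet", cond))
    }
  }
  cond <- sheet$condition_label[match(ratios$sample_id, sheet$sample_id)]
  keep <- cond %in% contrast & ratios$defined
  df <- ratios[keep, , drop = FALSE]
  df$treatment <- factor(cond[keep], levels = contrast)
  genes <- unique(ratios$gene_id)
  per_gene <- split(df, factor(df$gene_id, levels = genes))
  rows <- lapply(genes, function(g) {
    d <- per_gene[[g]]
    res <- data.frame(gene_id = g, condition_control = contrast[1L],
                      condition_treated = contrast[2L],
                      beta_treatment = NA_real_, std_error = NA_real_,
                      wald_statistic = NA_real_, p_value = NA_real_,
                      estimable = FALSE, stringsAsFactors = FALSE)
    if (nrow(d) == 0 || any(tabulate(d$treatment, nbins = 2L) == 0L)) {
      return(res)  # a condition has no informative replicate
    }
    if (pooled) {
      xi <- tapply(d$xi_count, d$treatment, sum)
      xa <- tapply(d$xa_count, d$treatment, sum)
      d <- data.frame(xi_count = as.numeric(xi), xa_count = as.numeric(xa),
                      treatment = factor(contrast, levels = contrast))
    }
    # boundary: all-success or all-failure within a group -> infinite MLE
    grp_xi <- tapply(d$xi_count, d$treatment, sum)
    grp_tot <- tapply(d$xi_count + d$xa_count, d$treatment, sum)
    boundary <- any(grp_xi == 0) || any(grp_xi == grp_tot)
    fit <- tryCatch(
      suppressWarnings(stats::glm(cbind(xi_count, xa_count) ~ treatment,
                                  family = stats::binomial(), data = d,
                                  control = stats::glm.control(
                                    epsilon = 1e-12, maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit)) return(res)
    cf <- stats::coef(summary(fit))
    if (nrow(cf) < 2) return(res)
    res$beta_treatment <- cf[2L, 1L]
    res$std_error <- cf[2L, 2L]
    res$wald_statistic <- cf[2L, 1L] / cf[2L, 2L]
    if (!boundary && fit$converged) {
      res$estimable <- TRUE
      res$p_value <- 2 * stats::pnorm(-abs(res$wald_statistic))
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("imbalance_test", "data.frame")
  out
}

#' Multiple-testing adjustment (Holm or Benjamini-Hochberg)
#'
#' Standard step-down Holm or step-up BH with monotonicity enforcement and
#' clipping at 1. Missing values are propagated and excluded from the
#' family size m.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NA/NaN allowed).
#' @param method `"holm"` or `"benjamini_hochberg"`.
#' @return Adjusted p values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (!is.numeric(p)) xe_value_error("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) xe_value_error("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = switch(method, holm = "holm",
                                                    benjamini_hochberg = "BH"))
  out
}

#' Call Xist-induced silencing of escapees
#'
#' A gene is silenced by the treatment when the allelic-imbalance test is
#' significant after adjustment and the allelic ratio drops by at least
#' `min_reduction` (default 50%) relative to the control condition:
#' `reduction = 1 - treated_mean / control_mean`.
#'
#' @param tests Output of [fit_binomial_glm()] with a `p_adjusted` column
#'   (add one via [adjust_pvalues()]).
#' @param cond_matrix Condition means from [aggregate_conditions()].
#' @param alpha Significance level on adjusted p values.
#' @param min_reduction Required fractional reduction of the ratio.
#' @return `data.frame` with `gene_id`, `reduction_fraction`, `significant`,
#'   `silenced_by_dox`, `reduction_defined`.
#' @export
call_silencing <- function(tests, cond_matrix, alpha = 0.05, min_reduction = 0.5) {
  if (!"p_adjusted" %in% names(tests)) {
    xe_config_error("tests must carry a p_adjusted column; run adjust_pvalues first")
  }
  ctrl <- tests$condition_control[1L]
  trt <- tests$condition_treated[1L]
  get_mean <- function(gene, cond) {
    m <- cond_matrix$mean_ratio[cond_matrix$gene_id == gene &
                                cond_matrix$condition_label == cond]
    if (length(m) == 1) m else NA_real_
  }
  rows <- lapply(seq_len(nrow(tests)), function(i) {
    g <- tests$gene_id[i]
    cm <- get_mean(g, ctrl)
    tm <- get_mean(g, trt)
    defined <- !is.na(cm) && !is.na(tm) && cm > 0
    red <- if (defined) 1 - tm / cm else NA_real_
    sig <- isTRUE(tests$estimable[i]) && !is.na(tests$p_adjusted[i]) &&
      tests$p_adjusted[i] < alpha
    data.frame(gene_id = g, control_mean = cm, treated_mean = tm,
               reduction_fraction = red, significant = sig,
               silenced_by_dox = sig && defined && red >= min_reduction,
               reduction_defined = defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("silencing_call", "data.frame")
  out
}

#' Pairwise Wilcoxon comparisons across groups
#'
#' Rank-sum tests between all pairs of groups (signed-rank when
#' `paired = TRUE`; values are then matched by position within group), with
#' Benjamini-Hochberg adjustment across the family of comparisons.
#'
#' @param values Numeric vector of per-gene values (e.g. fold recovery).
#' @param group Grouping factor/character of the same length.
#' @param paired Use the paired signed-rank test.
#' @return `data.frame` with `group1`, `group2`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_categories <- function(values, group, paired = FALSE) {
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) < 2) xe_value_error("need at least two groups to compare")
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    x <- values[group == pairs[1L, j]]
    y <- values[group == pairs[2L, j]]
    if (paired && length(x) != length(y)) {
      xe_value_error("paired comparison requires equal group sizes")
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
    # fully tied data degenerate the normal approximation; no evidence of
    # a shift means p = 1
    p <- if (is.nan(wt$p.value)) 1 else wt$p.value
    data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
               statistic = unname(wt$statistic), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_value, "benjamini_hochberg")
  rownames(out) <- NULL
  out
}

#' Correlate mean escape with Xist induction level
#'
#' Pearson correlation between the per-sample mean allelic ratio over
#' informative genes and the per-sample Xist expression level, with the
#' usual t-test p value and the least-squares line.
#'
#' @param mean_escape Per-sample mean allelic ratio.
#' @param xist_level Per-sample Xist level (e.g. CPM fold change).
#' @return List with `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
correlate_escape_xist <- function(mean_escape, xist_level) {
  if (length(mean_escape) != length(xist_level)) {
    xe_value_error("vectors must have equal length")
  }
  if (length(mean_escape) < 3) xe_value_error("need at least 3 samples")
  if (stats::var(mean_escape) == 0 || stats::var(xist_level) == 0) {
    xe_value_error("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(xist_level, mean_escape, method = "pearson")
  fit <- stats::lm(mean_escape ~ xist_level)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), n = length(mean_escape))
}
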