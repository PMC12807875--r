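#' Fit an exponential-decay silencing trajectory
#'
#' Models the allelic ratio over days of Xist induction as
#' `r(t) = a * exp(-k * t) + b`, where `k` is the decay constant (per day),
#' `a` scales the decay and `b` is an asymptotic offset quantifying
#' residual escape after prolonged induction. The nested
#' `model = "no_offset"` variant fixes `b = 0` (full silencing). Fitting is
#' bounded nonlinear least squares (`nls`, port algorithm) with a
#' multi-start grid, since single-start `nls` is sensitive to
#' initialization: k in {0.05, 0.2, 0.5, 1.5}, b in {0, min ratio, 0.1}
#' (offset model only), a initialized as r(0) - b. Bounds: k in
#' (1e-4, 10] per day, b in [0, 1], a in [-1, 1].
#'
#' R-squared is `1 - RSS/TSS` with TSS about the observation mean — the
#' same TSS for both models, so their R-squared values are comparable.
#'
#' @param t Days of induction per observation (replicate-level).
#' @param ratio Observed allelic ratios in `[0, 1]`.
#' @param model `"offset"` (free `b`) or `"no_offset"` (`b = 0`).
#' @return List with `model`, `a`, `k`, `b`, `rss`, `r_squared`, `n_obs`,
#'   `converged`, and `reason` when no fit was possible.
#' @export
fit_decay <- function(t, ratio, model = c("offset", "no_offset")) {
  model <- match.arg(model)
  keep <- !is.na(ratio) & !is.na(t)
  t <- t[keep]; ratio <- ratio[keep]
  if (length(unique(t)) < 3) {
    xe_insufficient_data_error("need >= 3 distinct timepoints to fit a decay")
  }
  n <- length(ratio)
  tss <- sum((ratio - mean(ratio))^2)
  base <- list(model = model, a = NA_real_, k = NA_real_, b = NA_real_,
               rss = NA_real_, r_squared = NA_real_, n_obs = n,
               converged = FALSE, reason = NA_character_)
  if (tss == 0) {
    base$reason <- "zero_variance"
    return(base)
  }
  r0 <- mean(ratio[t == min(t)])
  k_starts <- c(0.05, 0.2, 0.5, 1.5)
  b_starts <- if (model == "offset") {
    unique(pmin(pmax(c(0, min(ratio), 0.1), 0), 1))
  } else 0
  best <- NULL
  dat <- data.frame(t = t, ratio = ratio)
  for (k0 in k_starts) {
    for (b0 in b_starts) {
      a0 <- min(max(r0 - b0, -1), 1)
      fit <- tryCatch(suppressWarnings(
        if (model == "offset") {
          stats::nls(ratio ~ a * exp(-k * t) + b, data = dat,
                     start = list(a = a0, k = k0, b = b0),
                     lower = c(a = -1, k = 1e-4, b = 0),
                     upper = c(a = 1, k = 10, b = 1),
                     algorithm = "port",
                     control = stats::nls.control(maxiter = 200))
        } else {
          stats::nls(ratio ~ a * exp(-k * t), data = dat,
                     start = list(a = a0, k = k0),
                     lower = c(a = -1, k = 1e-4), upper = c(a = 1, k = 10),
                     algorithm = "port",
                     control = stats::nls.control(maxiter = 200))
        }), error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        cf <- stats::coef(fit)
        best <- list(a = unname(cf["a"]), k = unname(cf["k"]),
                     b = if (model == "offset") unname(cf["b"]) else 0,
                     rss = rss)
      }
    }
  }
  if (is.null(best)) {
    base$reason <- "fit_failure"
    return(base)
  }
  base[c("a", "k", "b", "rss")] <- best[c("a", "k", "b", "rss")]
  base$r_squared <- 1 - best$rss / tss
  base$converged <- TRUE
  base
}

#' Select between offset and no-offset decay models by BIC
#'
#' Genes where both fits have R-squared < `min_r_squared` (default 0.3) are
#' labelled `unreliable` and excluded from kinetic interpretation. For the
#' rest, the Gaussian least-squares BIC `n*log(RSS/n) + p_eff*log(n)` is
#' compared, with `p_eff` counting the free curve parameters plus one for
#' the error variance; the lower BIC wins and a tie goes to the simpler
#' no-offset model. Selection of the offset model is the evidence for
#' residual escape; `b_above_0.1` additionally flags fitted offsets above
#' the escape threshold.
#'
#' @param fit_offset,fit_no_offset Results of [fit_decay()].
#' @param gene_id Optional gene id carried into the result.
#' @param min_r_squared Reliability threshold applied to both fits.
#' @return One-row `data.frame` (a decay-fit record): parameters of the
#'   selected model, both R-squared and BIC values, `selected_model`,
#'   `half_life_days`, `residual_escape`, `b_above_0.1`.
#' @export
select_model <- function(fit_offset, fit_no_offset, gene_id = NA_character_,
                         min_r_squared = 0.3) {
  n <- max(fit_offset$n_obs, fit_no_offset$n_obs)
  bic <- function(fit, n_par) {
    if (!fit$converged) return(NA_real_)
    fit$n_obs * log(fit$rss / fit$n_obs) + (n_par + 1) * log(fit$n_obs)
  }
  bic_off <- bic(fit_offset, 3L)
  bic_no <- bic(fit_no_offset, 2L)
  r2_off <- if (fit_offset$converged) fit_offset$r_squared else -Inf
  r2_no <- if (fit_no_offset$converged) fit_no_offset$r_squared else -Inf
  selected <- if (r2_off < min_r_squared && r2_no < min_r_squared) {
    "unreliable"
  } else if (!fit_offset$converged && !fit_no_offset$converged) {
    "unreliable"
  } else if (!fit_offset$converged) {
    "no_offset"
  } else if (!fit_no_offset$converged) {
    "offset"
  } else if (bic_off < bic_no - 1e-9) {
    "offset"
  } else {
    "no_offset"  # tie goes to the simpler model
  }
  sel_fit <- switch(selected, offset = fit_offset, no_offset = fit_no_offset,
                    unreliable = NULL)
  out <- data.frame(
    gene_id = gene_id,
    a = if (is.null(sel_fit)) NA_real_ else sel_fit$a,
    k = if (is.null(sel_fit)) NA_real_ else sel_fit$k,
    b = if (is.null(sel_fit)) NA_real_ else sel_fit$b,
    r2_offset = fit_offset$r_squared, r2_no_offset = fit_no_offset$r_squared,
    bic_offset = bic_off, bic_no_offset = bic_no,
    selected_model = selected,
    half_life_days = if (is.null(sel_fit)) NA_real_ else half_life(sel_fit$k),
    residual_escape = selected == "offset",
    stringsAsFactors = FALSE)
  out[["b_above_0.1"]] <- selected == "offset" && !is.na(out$b) && out$b > 0.1
  class(out) <- c("decay_fit", "data.frame")
  out
}

#' Silencing half-life from the decay constant
#'
#' `t_1/2 = -ln(0.5) / k = ln(2) / k`, in days when `k` is per day.
#'
#' @param k Decay constant, must be > 0.
#' @return Half-life in the reciprocal units of `k`.
#' @export
half_life <- function(k) {
  if (any(!is.na(k) & k <= 0)) xe_value_error("half-life requires k > 0")
  log(2) / k
}

#' Fit decay kinetics for a set of genes
#'
#' Convenience driver: builds per-gene trajectories from replicate-level
#' ratios over the Dox time course (washout and auxin samples are
#' excluded — the trajectory describes the induction course only), fits
#' both nested models and selects by BIC.
#'
#' @param ratios Per-sample ratios from [compute_allelic_ratio()].
#' @param sheet Sample sheet.
#' @param genes Gene ids to fit (default: all genes in `ratios`).
#' @param use_condition_means Fit on condition means instead of
#'   replicate-level observations.
#' @param min_r_squared Passed to [select_model()].
#' @return `data.frame` with one decay-fit row per gene.
#' @export
fit_gene_kinetics <- function(ratios, sheet, genes = NULL,
                              use_condition_means = FALSE,
                              min_r_squared = 0.3) {
  if (is.null(genes)) genes <- unique(ratios$gene_id)
  keep_samples <- sheet$sample_id[sheet$washout_days == 0 & !sheet$auxin]
  r <- ratios[ratios$sample_id %in% keep_samples & ratios$defined, ,
              drop = FALSE]
  r$t <- sheet$dox_days[match(r$sample_id, sheet$sample_id)]
  if (use_condition_means) {
    key <- interaction(r$gene_id, r$t, drop = TRUE)
    r <- do.call(rbind, lapply(split(r, key), function(g) {
      data.frame(gene_id = g$gene_id[1L], t = g$t[1L], ratio = mean(g$ratio))
    }))
  }
  per_gene <- split(r, factor(r$gene_id, levels = genes))
  rows <- lapply(genes, function(g) {
    d <- per_gene[[g]]
    if (length(unique(d$t)) < 3) {
      out <- select_model(list(converged = FALSE, n_obs = nrow(d),
                               r_squared = NA_real_),
                          list(converged = FALSE, n_obs = nrow(d),
                               r_squared = NA_real_), gene_id = g)
      return(out)
    }
    select_model(fit_decay(d$t, d$ratio, "offset"),
                 fit_decay(d$t, d$ratio, "no_offset"),
                 gene_id = g, min_r_squared = min_r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test for shared kinetics of neighbouring genes
#'
#' Tests whether genes lying close together on the chromosome (gene starts
#' within `window` bp) have more similar silencing half-lives than expected
#' by chance. The observed statistic is the mean absolute half-life
#' difference over all neighbour pairs; the null distribution permutes the
#' half-lives over the gene positions. One-sided p (smaller = more similar)
#' with +1 smoothing: `p = (1 + #{null <= observed}) / (n_permutations + 1)`.
#'
#' @param fits Decay fits from [fit_gene_kinetics()]; only rows with a
#'   reliable model and finite half-life are used.
#' @param annotation Gene annotation providing start coordinates.
#' @param window Neighbour distance threshold in bp (start-to-start,
#'   inclusive).
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed (required: the null is resampled).
#' @return List with `observed_statistic`, `null_mean`, `null_quantiles`,
#'   `p_value`, `n_pairs`, `n_genes`, `n_permutations`, `applicable`.
#' @export
neighbor_similarity_test <- function(fits, annotation, window = 1e5,
                                     n_permutations = 1000, seed) {
  if (missing(seed)) xe_config_error("neighbor_similarity_test requires a seed")
  ok <- fits$selected_model != "unreliable" & is.finite(fits$half_life_days)
  hl <- fits$half_life_days[ok]
  genes <- fits$gene_id[ok]
  idx <- match(genes, annotation$gene_id)
  keep <- !is.na(idx)
  hl <- hl[keep]; idx <- idx[keep]
  start <- annotation$start[idx]
  chrom <- annotation$chromosome[idx]
  n <- length(hl)
  na_result <- list(observed_statistic = NA_real_, null_mean = NA_real_,
                    null_quantiles = NULL, p_value = NA_real_, n_pairs = 0L,
                    n_genes = n, n_permutations = n_permutations,
                    applicable = FALSE)
  if (n < 3) return(na_result)
  pair_stat <- function(values) {
    total <- 0; m <- 0L
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (chrom[i] == chrom[j] && abs(start[i] - start[j]) <= window) {
          total <- total + abs(values[i] - values[j])
          m <- m + 1L
        }
      }
    }
    c(total = total, m = m)
  }
  obs <- pair_stat(hl)
  if (obs["m"] < 2) return(na_result)
  observed <- obs["total"] / obs["m"]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    s <- pair_stat(sample(hl))
    s["total"] / s["m"]
  }, 0)
  list(observed_statistic = unname(observed), null_mean = mean(null),
       null_quantiles = stats::quantile(null, c(0.025, 0.5, 0.975)),
       p_value = (1 + sum(null <= observed)) / (n_permutations + 1),
       n_pairs = unname(as.integer(obs["m"])), n_genes = n,
       n_permutations = n_permutations, applicable = TRUE)
}
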