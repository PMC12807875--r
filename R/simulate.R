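#' Configuration for the synthetic allelic-count generator
#'
#' Defines a simulated clone with skewed X inactivation observed over an
#' inducible Xist time course: per-gene true allelic ratios follow
#' `r(t) = (r0 - b) * exp(-k * t) + b` over the Dox days of `time_grid`,
#' reads are binomially sampled around per-gene sequencing depths, a
#' washout arm recovers a class-dependent fraction of untreated escape,
#' escapee clusters are laid out to satisfy the 100-kb chaining rule, and
#' a cross-study matrix is generated consistent with each gene's category.
#'
#' Default study conditions mirror an NPC clone time course: five Dox
#' timepoints (days 0, 3, 7, 14, 21), three biological replicates, washout
#' arms of 7 days after 7, 14 and 21 days of induction. Depths are
#' negative-binomially distributed across genes to mimic expression
#' heterogeneity. Escapee untreated ratios are drawn at or above 0.2 and
#' recovery fractions are kept clear of the 0.1 washout-ratio boundary so
#' that every gene's truth label is unambiguous under the classification
#' rules.
#'
#' @param n_genes Number of X-linked genes beside Xist.
#' @param category_proportions Named fractions over
#'   `constitutive`, `facultative`, `clone_specific`, `silenced`
#'   (must sum to 1).
#' @param time_grid Dox treatment durations in days (must include 0).
#' @param n_replicates Biological replicates per condition.
#' @param washout_induction_days Induction durations that get a washout arm.
#' @param washout_days Washout duration in days.
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of
#'   per-gene allelic read depth.
#' @param decay_ranges Per-category ranges for (r0, k, b); see defaults.
#' @param reversibility_proportions Named fractions over `reversible`,
#'   `partially_irreversible`, `irreversible` for non-constitutive escapees.
#' @param n_studies Number of simulated literature studies.
#' @param n_clusters,genes_per_cluster,cluster_spacing_bp,between_cluster_gap_bp
#'   Genomic layout: escapee clusters whose member starts are
#'   `cluster_spacing_bp` apart (within the 100-kb rule) separated by
#'   `between_cluster_gap_bp`.
#' @param cluster_k_jitter Log-scale SD of within-cluster decay constants
#'   around the cluster's shared k.
#' @param seed Integer seed; the generator is fully reproducible under it.
#' @return A validated config list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 120,
                              category_proportions = c(constitutive = 0.10,
                                                       facultative = 0.35,
                                                       clone_specific = 0.15,
                                                       silenced = 0.40),
                              time_grid = c(0, 3, 7, 14, 21),
                              n_replicates = 3,
                              washout_induction_days = c(7, 14, 21),
                              washout_days = 7,
                              depth_mean = 200, depth_dispersion = 2,
                              decay_ranges = list(
                                constitutive = list(r0 = c(0.3, 0.6),
                                                    k = c(0.08, 0.5),
                                                    b = c(0.15, 0.3)),
                                facultative = list(r0 = c(0.2, 0.55),
                                                   k = c(0.08, 0.8),
                                                   b = c(0, 0)),
                                clone_specific = list(r0 = c(0.2, 0.5),
                                                      k = c(0.08, 0.8),
                                                      b = c(0, 0)),
                                silenced = list(r0 = c(0, 0.08),
                                                k = c(NA, NA), b = c(NA, NA))),
                              reversibility_proportions = c(
                                reversible = 0.4,
                                partially_irreversible = 0.3,
                                irreversible = 0.3),
                              n_studies = 10,
                              n_clusters = 5, genes_per_cluster = 4,
                              cluster_spacing_bp = 30000,
                              between_cluster_gap_bp = 500000,
                              cluster_k_jitter = 0.15,
                              seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(category_proportions) - 1) > 1e-8) {
    xe_config_error("category_proportions must sum to 1")
  }
  if (abs(sum(reversibility_proportions) - 1) > 1e-8) {
    xe_config_error("reversibility_proportions must sum to 1")
  }
  if (!0 %in% time_grid) xe_config_error("time_grid must include day 0 (untreated)")
  if (n_clusters * genes_per_cluster >
      n_genes * sum(category_proportions[c("constitutive", "facultative",
                                           "clone_specific")])) {
    xe_config_error("not enough escapee genes for the requested cluster layout")
  }
  if (cluster_spacing_bp > 1e5) {
    xe_config_error("cluster_spacing_bp must satisfy the 100-kb chaining rule")
  }
  class(cfg) <- "simulation_config"
  cfg
}

runif_range <- function(n, range) stats::runif(n, range[1L], range[2L])

#' Simulate a haplotype-resolved allelic count dataset
#'
#' Generates an allelic count table, sample sheet, gene annotation,
#' cross-study escape matrix and a truth table under the configured study
#' design. For each gene and sample the total allelic reads are Poisson
#' draws around a negative-binomially distributed per-gene depth and the
#' Xi reads are `Binomial(total, r_true)` where `r_true` follows the
#' exponential decay (Dox arm) or the class-dependent recovered ratio
#' (washout arm). Truth reversibility labels are derived by applying the
#' classification rule to the noise-free ratios, so labels are always
#' self-consistent. An `Xist` gene is included (allelic ratio 0.95,
#' expression induced ~15-fold under Dox, reverting after washout).
#'
#' @param config A [simulation_config()].
#' @return List of class `xci_simulation` with elements `counts`, `sheet`,
#'   `annotation`, `study_matrix`, `truth` (per-gene parameters and
#'   labels), `truth_ratios` (true per-condition ratios) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    xe_config_error("config must come from simulation_config()")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_genes
  gene_ids <- sprintf("gene%03d", seq_len(n))

  ## --- categories -----------------------------------------------------
  props <- config$category_proportions
  counts_per_cat <- floor(props * n)
  short <- n - sum(counts_per_cat)
  if (short > 0) {
    extra <- order(props * n - counts_per_cat, decreasing = TRUE)[seq_len(short)]
    counts_per_cat[extra] <- counts_per_cat[extra] + 1L
  }
  category <- sample(rep(names(props), counts_per_cat))
  escapee <- category != "silenced"

  ## --- decay parameters ----------------------------------------------
  r0 <- k <- b <- rep(NA_real_, n)
  for (cat in names(config$decay_ranges)) {
    i <- which(category == cat)
    rg <- config$decay_ranges[[cat]]
    r0[i] <- runif_range(length(i), rg$r0)
    if (cat != "silenced") {
      k[i] <- runif_range(length(i), rg$k)
      b[i] <- runif_range(length(i), rg$b)
    }
  }
  b[category == "silenced"] <- r0[category == "silenced"]  # flat trajectory

  ## --- genomic layout: clustered escapees share kinetics --------------
  esc_idx <- which(escapee)
  n_clustered <- config$n_clusters * config$genes_per_cluster
  clustered <- sample(esc_idx, n_clustered)
  cluster_of <- rep(NA_integer_, n)
  cluster_of[clustered] <- rep(seq_len(config$n_clusters),
                               each = config$genes_per_cluster)
  for (cl in seq_len(config$n_clusters)) {
    members <- which(cluster_of == cl)
    k_base <- stats::runif(1, 0.1, 0.6)
    k[members] <- pmin(pmax(
      k_base * exp(stats::rnorm(length(members), 0, config$cluster_k_jitter)),
      0.02), 2)
  }
  start <- rep(NA_real_, n)
  pos <- 1e6
  for (cl in seq_len(config$n_clusters)) {
    members <- which(cluster_of == cl)
    start[members] <- pos + (seq_along(members) - 1) * config$cluster_spacing_bp
    pos <- max(start[members]) + config$between_cluster_gap_bp
  }
  solo <- which(is.na(start))
  for (i in solo) {
    start[i] <- pos
    pos <- pos + config$between_cluster_gap_bp
  }
  xist_start <- pos

  ## --- reversibility truth --------------------------------------------
  rev_class_drawn <- rep(NA_character_, n)
  recovery <- rep(NA_real_, n)
  rev_class_drawn[category == "constitutive"] <- "reversible"
  other_esc <- which(escapee & category != "constitutive")
  draw <- sample(names(config$reversibility_proportions), length(other_esc),
                 replace = TRUE, prob = config$reversibility_proportions)
  # partial irreversibility needs the true washout ratio clear of the 0.1
  # floor; genes too lowly escaping for that get a coin flip instead
  ineligible <- draw == "partially_irreversible" & r0[other_esc] < 0.3
  draw[ineligible] <- sample(c("reversible", "irreversible"),
                             sum(ineligible), replace = TRUE)
  rev_class_drawn[other_esc] <- draw
  for (i in which(escapee)) {
    recovery[i] <- switch(rev_class_drawn[i],
      reversible = stats::runif(1, 0.65, 0.95),
      partially_irreversible = stats::runif(1, max(0.35, 0.13 / r0[i]), 0.45),
      irreversible = stats::runif(1, 0, 0.05))
  }

  ## --- sample sheet ----------------------------------------------------
  reps <- seq_len(config$n_replicates)
  dox_rows <- expand.grid(replicate = reps, dox_days = config$time_grid)
  wash_rows <- expand.grid(replicate = reps,
                           dox_days = config$washout_induction_days)
  sheet <- rbind(
    data.frame(dox_days = dox_rows$dox_days, washout_days = 0,
               replicate = dox_rows$replicate),
    data.frame(dox_days = wash_rows$dox_days,
               washout_days = config$washout_days,
               replicate = wash_rows$replicate))
  sheet$sample_id <- ifelse(
    sheet$washout_days > 0,
    sprintf("d%gw%g_r%d", sheet$dox_days, sheet$washout_days, sheet$replicate),
    sprintf("d%g_r%d", sheet$dox_days, sheet$replicate))
  sheet$auxin <- FALSE
  sheet$xi_haplotype <- "hap1"
  sheet <- validate_sample_sheet(sheet)

  ## --- true per-condition ratios ---------------------------------------
  conditions <- unique(sheet[, c("condition_label", "dox_days", "washout_days")])
  true_ratio <- function(i, dox, wash) {
    if (!escapee[i]) return(r0[i])
    if (wash > 0) return(max(recovery[i] * r0[i], b[i]))
    (r0[i] - b[i]) * exp(-k[i] * dox) + b[i]
  }
  truth_ratios <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(gene_id = gene_ids[i],
               condition_label = conditions$condition_label,
               true_ratio = vapply(seq_len(nrow(conditions)), function(j) {
                 true_ratio(i, conditions$dox_days[j], conditions$washout_days[j])
               }, 0), stringsAsFactors = FALSE)
  }))

  washout_true <- vapply(seq_len(n), function(i) {
    if (!escapee[i]) return(NA_real_)
    max(recovery[i] * r0[i], b[i])
  }, 0)
  fold_true <- ifelse(escapee & r0 > 0, washout_true / r0, NA_real_)
  rev_class_true <- ifelse(!escapee, NA_character_,
    ifelse(fold_true >= 0.5 & washout_true > 0.1, "reversible",
    ifelse(fold_true >= 0.1 & washout_true > 0.1, "partially_irreversible",
           "irreversible")))

  ## --- counts -----------------------------------------------------------
  base_depth <- pmax(stats::rnbinom(n, size = config$depth_dispersion,
                                    mu = config$depth_mean), 20)
  sample_truth <- merge(truth_ratios, sheet[, c("sample_id", "condition_label")],
                        by = "condition_label")
  sample_truth <- sample_truth[order(match(sample_truth$gene_id, gene_ids),
                                     match(sample_truth$sample_id,
                                           sheet$sample_id)), , drop = FALSE]
  depth <- base_depth[match(sample_truth$gene_id, gene_ids)]
  total <- pmax(stats::rpois(nrow(sample_truth), depth), 1)
  xi <- stats::rbinom(nrow(sample_truth), total, sample_truth$true_ratio)
  counts <- data.frame(gene_id = sample_truth$gene_id,
                       sample_id = sample_truth$sample_id,
                       count_hap1 = xi, count_hap2 = total - xi,
                       chromosome = "chrX", stringsAsFactors = FALSE)

  # Xist: expressed from the Xi, induced under Dox, reverting after washout
  xist_fold <- ifelse(sheet$dox_days > 0 & sheet$washout_days == 0, 15, 1)
  xist_total <- pmax(stats::rpois(nrow(sheet), 800 * xist_fold), 1)
  xist_xi <- stats::rbinom(nrow(sheet), xist_total, 0.95)
  counts <- rbind(counts, data.frame(
    gene_id = "Xist", sample_id = sheet$sample_id, count_hap1 = xist_xi,
    count_hap2 = xist_total - xist_xi, chromosome = "chrX",
    stringsAsFactors = FALSE))
  counts <- validate_allelic_counts(counts)

  annotation <- validate_gene_annotation(data.frame(
    gene_id = c(gene_ids, "Xist"), chromosome = "chrX",
    start = as.integer(c(start, xist_start)),
    end = as.integer(c(start, xist_start) + 5000L),
    strand = "+", stringsAsFactors = FALSE))

  study_matrix <- simulate_study_matrix(gene_ids, category, config$n_studies)

  truth <- data.frame(gene_id = gene_ids, category = category, r0 = r0,
                      k = k, b = b, cluster = cluster_of,
                      start = as.integer(start),
                      base_depth = base_depth,
                      recovery_fraction = recovery,
                      washout_true_ratio = washout_true,
                      reversibility_class = rev_class_true,
                      stringsAsFactors = FALSE)

  out <- list(counts = counts, sheet = sheet, annotation = annotation,
              study_matrix = study_matrix, truth = truth,
              truth_ratios = truth_ratios, config = config)
  class(out) <- "xci_simulation"
  out
}

# Study calls consistent with each gene's category under the meta rules:
# constitutive genes are detected in >= 3 studies and escape in > 50% of
# them; facultative in >= 1 but a minority; clone-specific and silenced
# genes escape in none (clone-specific are mostly undetected).
simulate_study_matrix <- function(gene_ids, category, n_studies) {
  studies <- sprintf("study%02d", seq_len(n_studies))
  rows <- lapply(seq_along(gene_ids), function(i) {
    calls <- rep("not_detected", n_studies)
    cat <- category[i]
    if (cat == "constitutive") {
      n_det <- sample(max(3, n_studies - 4):n_studies, 1)
      frac <- stats::runif(1, 0.6, 0.95)
      n_esc <- max(ceiling(frac * n_det), floor(n_det / 2) + 1)
    } else if (cat == "facultative") {
      if (stats::runif(1) < 0.3) {
        n_det <- sample(1:2, 1); n_esc <- sample(seq_len(n_det), 1)
      } else {
        n_det <- sample(3:n_studies, 1)
        n_esc <- sample(seq_len(max(1, floor((n_det - 1) / 2))), 1)
      }
    } else if (cat == "clone_specific") {
      n_det <- sample(0:2, 1); n_esc <- 0
    } else {
      n_det <- sample(3:n_studies, 1); n_esc <- 0
    }
    if (n_det > 0) {
      det <- sample(n_studies, n_det)
      calls[det] <- "silenced"
      if (n_esc > 0) calls[det[seq_len(n_esc)]] <- "escaping"
    }
    data.frame(gene_id = gene_ids[i], study_id = studies, call = calls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mix two allelic count tables at a defined fraction
#'
#' Emulates cell-mixture experiments (e.g. defined fractions of treated
#' cells spiked into an untreated population): per gene and haplotype the
#' expected count is `(1 - f) * a + f * b`, realized by stochastic rounding
#' (floor plus a Bernoulli draw on the fractional part) so that `f = 0`
#' and `f = 1` return the pure tables exactly.
#'
#' @param pure_a,pure_b Allelic count tables over the same (gene, sample)
#'   keys.
#' @param fraction_b Mixing fraction of `pure_b` in `[0, 1]`.
#' @param seed Optional integer seed for the stochastic rounding.
#' @return An allelic count table.
#' @export
simulate_mixture <- function(pure_a, pure_b, fraction_b, seed = NULL) {
  if (fraction_b < 0 || fraction_b > 1) {
    xe_value_error("fraction_b must lie in [0, 1]")
  }
  key_a <- paste(pure_a$gene_id, pure_a$sample_id, sep = "\r")
  key_b <- paste(pure_b$gene_id, pure_b$sample_id, sep = "\r")
  if (!setequal(key_a, key_b)) {
    xe_integrity_error("mixture inputs must share the same (gene, sample) set")
  }
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  b_idx <- match(key_a, key_b)
  out <- pure_a
  for (col in c("count_hap1", "count_hap2")) {
    expected <- (1 - fraction_b) * pure_a[[col]] +
      fraction_b * pure_b[[col]][b_idx]
    lo <- floor(expected)
    out[[col]] <- as.integer(lo + stats::rbinom(length(expected), 1,
                                                expected - lo))
  }
  validate_allelic_counts(as.data.frame(out))
}

#' Write all tables of a simulated dataset
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_allelic_counts(sim$counts, file.path(dir, "allelic_counts.tsv"))
  write_sample_sheet(sim$sheet, file.path(dir, "sample_sheet.tsv"))
  write_gene_annotation(sim$annotation, file.path(dir, "gene_annotation.tsv"))
  utils::write.table(sim$study_matrix, file.path(dir, "study_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth_ratios, file.path(dir, "truth_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
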