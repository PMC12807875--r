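#' Partition genes into local gene groups by start-position chaining
#'
#' Iterates over genes sorted by start coordinate (stable sort; distance is
#' start-to-start, strand-agnostic, using the left-most coordinate) and
#' chains consecutive genes into one group while each step is within
#' `window` bp (inclusive), splitting whenever it is not. Singletons are
#' emitted as their own groups. A change of chromosome always splits.
#'
#' @param genes Gene ids to partition (e.g. the escapee set).
#' @param annotation Gene annotation with `gene_id`, `chromosome`, `start`.
#' @param window Chaining distance in bp (default 100 kb).
#' @return `data.frame` with `group_id`, `gene_id`, `chromosome`, `start`,
#'   `group_size`, ordered by position; attribute `summary` holds
#'   `n_groups`, `n_groups_ge3`, `n_singles_or_pairs` and the size range,
#'   and attribute `skipped` any unannotated gene ids.
#' @export
partition_gene_groups <- function(genes, annotation, window = 1e5) {
  idx <- match(genes, annotation$gene_id)
  skipped <- genes[is.na(idx)]
  if (length(skipped) > 0) {
    warning(sprintf("skipping %d unannotated gene(s): %s", length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  }
  genes <- genes[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  df <- data.frame(gene_id = genes, chromosome = annotation$chromosome[idx],
                   start = annotation$start[idx], stringsAsFactors = FALSE)
  ord <- order(df$chromosome, df$start)  # stable: ties keep input order
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  if (n == 0) {
    out <- data.frame(group_id = integer(0), gene_id = character(0),
                      chromosome = character(0), start = integer(0),
                      group_size = integer(0))
  } else {
    new_group <- c(TRUE, diff(df$start) > window |
                     df$chromosome[-1] != df$chromosome[-n])
    df$group_id <- cumsum(new_group)
    size <- table(df$group_id)
    df$group_size <- as.integer(size[as.character(df$group_id)])
    out <- df[, c("group_id", "gene_id", "chromosome", "start", "group_size")]
  }
  rownames(out) <- NULL
  sizes <- if (nrow(out)) tapply(out$group_size, out$group_id, `[`, 1L) else integer(0)
  attr(out, "summary") <- list(
    n_groups = length(sizes),
    n_groups_ge3 = sum(sizes >= 3),
    n_singles_or_pairs = sum(sizes <= 2),
    size_range = if (length(sizes)) range(sizes) else c(NA_integer_, NA_integer_))
  attr(out, "skipped") <- skipped
  class(out) <- c("gene_groups", "data.frame")
  out
}
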