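#' Read gene annotation from GTF or BED
#'
#' Internal coordinates are 1-based closed (the GTF convention). BED input
#' (0-based half-open) is converted at the boundary, so a BED `chromStart`
#' of 99 becomes `start` 100. For GTF, `type == "gene"` records are used
#' when present; otherwise the span of all records sharing a `gene_id` is
#' taken. Strand `*`/`.` is reported as `"unknown"`.
#'
#' @param path Path to the annotation file.
#' @param format One of `"gtf"`, `"bed"`.
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`; one row per gene.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) xe_format_error(sprintf("file not found: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) {
      xe_format_error(sprintf("failed to parse %s file '%s': %s",
                              toupper(format), path, conditionMessage(e)))
    })
  df <- as.data.frame(gr)
  if (format == "gtf") {
    if (!"gene_id" %in% names(df)) {
      xe_format_error("GTF attributes do not contain gene_id")
    }
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", , drop = FALSE]
    } else {
      # collapse transcript/exon records to the per-gene span
      df <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
        g$start <- min(g$start); g$end <- max(g$end); g[1L, , drop = FALSE]
      }))
    }
    gene_id <- df$gene_id
  } else {
    if (!"name" %in% names(df) || anyNA(df$name)) {
      xe_format_error("BED input requires a name field holding the gene id")
    }
    gene_id <- df$name
  }
  ann <- data.frame(
    gene_id = as.character(gene_id),
    chromosome = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = ifelse(as.character(df$strand) %in% c("+", "-"),
                    as.character(df$strand), "unknown"),
    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  validate_gene_annotation(ann)
}

validate_gene_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) {
    xe_integrity_error(sprintf("duplicate gene_id in annotation: %s",
                               ann$gene_id[duplicated(ann$gene_id)][1L]))
  }
  if (any(ann$start > ann$end)) xe_integrity_error("annotation has start > end")
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' @rdname read_gene_annotation
#' @param ann A gene annotation table.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
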