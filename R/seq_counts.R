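#' Sequence-level count matrix
#'
#' Container pairing an integer count matrix (rows = unique small-RNA
#' sequences, columns = samples) with its sequence annotation. Row names of
#' the matrix are generated gene IDs (`<canonical gene>-<k>`, see
#' [make_gene_ids()]); the annotation table maps each gene ID back to its
#' exact sequence, canonical gene and biotype.
#'
#' @param counts integer matrix, genes x samples, with unique row names
#'   (gene IDs) and column names (sample IDs).
#' @param annotation data.frame with columns `gene_id`, `sequence`,
#'   `canonical_gene`, `biotype`, one row per matrix row (matched by
#'   `gene_id`).
#' @return An object of class `seq_counts`: a list with elements `counts`
#'   and `annotation`.
#' @export
seq_counts <- function(counts, annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique row names (gene IDs)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  need <- c("gene_id", "sequence", "canonical_gene", "biotype")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (!all(annotation$biotype %in% BIOTYPES))
    stop("unknown biotype label(s): ",
         paste(setdiff(unique(annotation$biotype), BIOTYPES), collapse = ", "))
  annotation <- annotation[match(rownames(counts), annotation$gene_id),
                           need, drop = FALSE]
  if (anyNA(annotation$gene_id))
    stop("annotation is missing entries for some count rows")
  rownames(annotation) <- NULL
  structure(list(counts = counts, annotation = annotation),
            class = "seq_counts")
}

#' @export
print.seq_counts <- function(x, ...) {
  cat(sprintf("seq_counts: %d sequences x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(factor(x$annotation$biotype, levels = BIOTYPES))
  cat("  biotypes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  median column sum: %s\n",
              format(stats::median(colSums(x$counts)), big.mark = ",")))
  invisible(x)
}

# Accept either a seq_counts object or a bare matrix.
count_matrix <- function(x) {
  if (inherits(x, "seq_counts")) x$counts else as.matrix(x)
}

annotation_of <- function(x) {
  if (inherits(x, "seq_counts")) x$annotation else NULL
}

#' Generate per-isoform gene IDs from a count matrix
#'
#' Unique sequences sharing a canonical gene are distinguished by
#' concatenating a 1-based index to the gene name (`miR-21-1`, `miR-21-2`,
#' ...), indexed in order of decreasing total read count across samples,
#' ties broken by lexicographic sequence order. The numbering is therefore a
#' deterministic function of the matrix alone.
#'
#' @param total_counts numeric vector of per-sequence total counts.
#' @param sequences character vector of the sequences (parallel).
#' @param canonical_genes character vector of canonical gene names (parallel).
#' @return character vector of unique gene IDs, parallel to the inputs.
#' @export
make_gene_ids <- function(total_counts, sequences, canonical_genes) {
  stopifnot(length(total_counts) == length(sequences),
            length(sequences) == length(canonical_genes))
  ids <- character(length(sequences))
  for (g in unique(canonical_genes)) {
    i <- which(canonical_genes == g)
    ord <- i[order(-total_counts[i], sequences[i])]
    ids[ord] <- paste0(g, "-", seq_along(ord))
  }
  ids
}

# Assemble a seq_counts from a raw matrix keyed by sequence plus reference
# annotation, generating gene IDs and ordering rows by canonical gene then
# isoform index. Shared by the simulator and the read-processing pipeline so
# both produce byte-identical objects for identical count content.
build_seq_counts <- function(counts_by_seq, sequences, reference) {
  m <- match(sequences, reference$sequence)
  if (anyNA(m)) stop("sequence absent from reference")
  canon <- reference$canonical_gene[m]
  bio <- reference$biotype[m]
  ids <- make_gene_ids(rowSums(counts_by_seq), sequences, canon)
  ord <- order(canon, ids_index(ids))
  counts <- counts_by_seq[ord, , drop = FALSE]
  rownames(counts) <- ids[ord]
  ann <- data.frame(gene_id = ids[ord], sequence = sequences[ord],
                    canonical_gene = canon[ord], biotype = bio[ord],
                    stringsAsFactors = FALSE)
  seq_counts(counts, ann)
}

ids_index <- function(ids) {
  as.integer(sub(".*-", "", ids))
}

#' Read and write the pipeline's tab-separated formats
#'
#' Plain-text interchange: a counts TSV (first column `gene_id`, remaining
#' columns one per sample), a lookup/reference TSV (`gene_id`, `sequence`,
#' `canonical_gene`, `biotype` — or without `gene_id` for an annotated
#' reference), and a metadata TSV (one row per sample).
#'
#' @param x object to write ([seq_counts], reference or metadata data.frame).
#' @param path file path.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_counts_tsv <- function(x, path) {
  x <- if (inherits(x, "seq_counts")) x else stop("expected a seq_counts")
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lookup_path <- sub("(\\.tsv)?$", ".lookup.tsv", path)
  write.table(x$annotation, lookup_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts = path, lookup = lookup_path))
}

#' @rdname tsv_io
#' @param lookup_path path to the lookup TSV written alongside the counts.
#' @export
read_counts_tsv <- function(path, lookup_path = sub("(\\.tsv)?$", ".lookup.tsv", path)) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  ann <- read.delim(lookup_path, stringsAsFactors = FALSE)
  seq_counts(counts, ann)
}

#' @rdname tsv_io
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_table_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
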