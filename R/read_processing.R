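#' Trim adapters and random bases from small-RNA reads
#'
#' Locates the 3' adapter (earliest exact occurrence; with
#' `max_mismatch > 0` the earliest occurrence within that mismatch budget;
#' a partial adapter prefix of at least `min_partial` nt at the read end is
#' also accepted), removes it and everything 3' of it, then strips
#' `n_random` bases from each end of the remaining insert. Inserts shorter
#' than `min_len` after trimming are discarded, as are reads with no
#' adapter occurrence and inserts containing N (exact-match annotation
#' cannot place them).
#'
#' @param reads character vector of raw reads over A/C/G/T/N.
#' @param adapter 3' adapter sequence.
#' @param n_random random bases flanking the insert on each side (4 for
#'   NEXTFLEX-style libraries).
#' @param min_len minimum insert length kept after trimming.
#' @param max_mismatch mismatches tolerated in the adapter match.
#' @param min_partial minimum adapter-prefix length accepted at the read end.
#' @return data.frame with columns `insert` (NA when discarded) and
#'   `reason` (`"ok"`, `"no_adapter"`, `"too_short"`, `"has_N"`).
#' @export
trim_reads <- function(reads, adapter, n_random = 4L, min_len = 15L,
                       max_mismatch = 0L, min_partial = 8L) {
  if (grepl("[^ACGT]", adapter)) stop("adapter must contain only A/C/G/T")
  n <- length(reads)
  if (max_mismatch == 0L) {
    pos <- regexpr(adapter, reads, fixed = TRUE)
    pos <- ifelse(pos > 0L, as.integer(pos), NA_integer_)
  } else {
    hits <- Biostrings::vmatchPattern(adapter, Biostrings::DNAStringSet(reads),
                                      max.mismatch = max_mismatch)
    pos <- vapply(Biostrings::startIndex(hits), function(s)
      if (length(s)) min(s) else NA_integer_, integer(1))
  }
  # Partial adapter prefix at the very end of the read (adapter runs off).
  alen <- nchar(adapter)
  rlen <- nchar(reads)
  for (k in seq(alen - 1L, by = -1L,
                length.out = max(0L, alen - min_partial))) {
    miss <- is.na(pos)
    if (!any(miss)) break
    pref <- substr(adapter, 1L, k)
    tail_match <- miss & rlen >= k &
      substr(reads, rlen - k + 1L, rlen) == pref
    pos[tail_match] <- rlen[tail_match] - k + 1L
  }
  insert <- rep(NA_character_, n)
  reason <- rep("no_adapter", n)
  found <- !is.na(pos)
  head_len <- pos[found] - 1L
  ins <- substr(reads[found], n_random + 1L, head_len - n_random)
  ok_len <- nchar(ins) >= min_len & head_len >= 2L * n_random
  has_n <- grepl("N", ins, fixed = TRUE)
  reason[found] <- ifelse(!ok_len, "too_short",
                          ifelse(has_n, "has_N", "ok"))
  keep <- which(found)[ok_len & !has_n]
  insert[keep] <- ins[ok_len & !has_n]
  data.frame(insert = insert, reason = reason, stringsAsFactors = FALSE)
}

#' @rdname trim_reads
#' @param read a single raw read.
#' @return `trim_read()`: the trimmed insert, or `NA` with attribute
#'   `reason` when discarded.
#' @export
trim_read <- function(read, adapter, n_random = 4L, min_len = 15L,
                      max_mismatch = 0L) {
  r <- trim_reads(read, adapter, n_random, min_len, max_mismatch)
  structure(r$insert, reason = r$reason)
}

#' Resolve multi-annotation biotype conflicts by priority
#'
#' Multi-mapping is common for short reads; when a sequence carries several
#' candidate biotype annotations, the highest-priority one wins, in the
#' order miRNA > YRNA > tRNA > piRNA > protein_coding > other.
#'
#' @param biotypes character vector (a nonempty set of candidate biotypes).
#' @return the single winning biotype.
#' @export
assign_biotype_priority <- function(biotypes) {
  if (length(biotypes) == 0) stop("empty biotype set")
  bad <- setdiff(biotypes, BIOTYPES)
  if (length(bad)) stop("unknown biotype label(s): ", paste(bad, collapse = ", "))
  BIOTYPES[min(match(biotypes, BIOTYPES))]
}

#' Collapse trimmed reads into an annotated sequence-level count matrix
#'
#' Identical inserts are collapsed into one row per distinct sequence;
#' isoforms differing by even a single nucleotide stay separate rows.
#' Sequences are annotated by exact match against the reference; per-isoform
#' gene IDs are generated with [make_gene_ids()]. Inserts absent from the
#' reference are tallied per sample as unannotated and excluded from the
#' matrix.
#'
#' @param trimmed named list, sample id -> character vector of trimmed
#'   inserts (discarded reads already removed).
#' @param reference annotated reference (columns `sequence`,
#'   `canonical_gene`, `biotype`).
#' @return list with `counts` (a [seq_counts]), `lookup` (the gene-ID
#'   lookup table), and `unannotated` (named per-sample tallies).
#' @export
collapse_and_annotate <- function(trimmed, reference) {
  if (is.null(reference) || nrow(reference) == 0) stop("empty reference")
  stopifnot(is.list(trimmed), !is.null(names(trimmed)))
  n_ref <- nrow(reference)
  counts <- matrix(0L, n_ref, length(trimmed),
                   dimnames = list(NULL, names(trimmed)))
  unann <- setNames(integer(length(trimmed)), names(trimmed))
  for (j in seq_along(trimmed)) {
    idx <- match(trimmed[[j]], reference$sequence)
    unann[j] <- sum(is.na(idx))
    tab <- tabulate(idx[!is.na(idx)], nbins = n_ref)
    counts[, j] <- as.integer(tab)
  }
  obs <- rowSums(counts) > 0L
  sc <- build_seq_counts(counts[obs, , drop = FALSE],
                         reference$sequence[obs], reference)
  list(counts = sc, lookup = sc$annotation, unannotated = unann)
}

#' Drop samples with insufficient annotated reads
#'
#' A sample is kept only when strictly more than `min_mapped` reads map to
#' an annotated transcriptomic feature (column sum of the annotated matrix).
#'
#' @param x a [seq_counts] or count matrix.
#' @param min_mapped threshold; default one million mapped reads.
#' @return list with `kept` (same class as `x`) and `excluded`
#'   (character vector of dropped sample IDs).
#' @export
qc_filter_samples <- function(x, min_mapped = 1e6) {
  m <- count_matrix(x)
  keep <- colSums(m) > min_mapped
  if (!any(keep)) warning("all samples fall below the mapped-read threshold")
  kept <- if (inherits(x, "seq_counts")) {
    seq_counts(m[, keep, drop = FALSE], x$annotation)
  } else m[, keep, drop = FALSE]
  list(kept = kept, excluded = colnames(m)[!keep])
}

#' Per-sample biotype composition and transcript diversity
#'
#' @param x a [seq_counts].
#' @return list with `fractions` (biotype x sample matrix of read
#'   fractions, columns summing to 1) and `diversity` (biotype x sample
#'   counts of detected (count > 0) unique sequences).
#' @export
biotype_composition <- function(x) {
  stopifnot(inherits(x, "seq_counts"))
  m <- x$counts
  if (ncol(m) == 0 || nrow(m) == 0) stop("empty count matrix")
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero-count sample(s): ",
                          paste(colnames(m)[tot == 0], collapse = ", "))
  bio <- factor(x$annotation$biotype, levels = BIOTYPES)
  agg <- rowsum(m, bio)
  frac <- sweep(agg, 2, tot, "/")
  div <- rowsum((m > 0) + 0L, bio)
  full <- function(a) {
    out <- matrix(0, length(BIOTYPES), ncol(m),
                  dimnames = list(BIOTYPES, colnames(m)))
    out[rownames(a), ] <- a
    out
  }
  list(fractions = full(frac), diversity = full(div))
}

#' Count small-RNA reads from FASTQ files
#'
#' The full read-processing pipeline: read FASTQ, trim adapter and random
#' bases, collapse exact sequences, annotate against the reference, apply
#' the mapped-read sample QC. Per-sample tallies of retained, discarded
#' (by reason) and unannotated reads are reported.
#'
#' @param fastq_files named character vector of FASTQ paths (names = sample
#'   IDs; unnamed paths use the file stem).
#' @param reference annotated reference table.
#' @param adapter 3' adapter sequence.
#' @inheritParams trim_reads
#' @param min_mapped sample QC threshold on annotated reads (strictly
#'   greater than).
#' @return list with `counts` ([seq_counts] of QC-passing samples),
#'   `lookup`, `qc` (per-sample data.frame of read tallies) and
#'   `excluded_samples`.
#' @export
count_smallrna <- function(fastq_files, reference, adapter, n_random = 4L,
                           min_len = 15L, max_mismatch = 0L,
                           min_mapped = 1e6) {
  if (is.null(names(fastq_files)))
    names(fastq_files) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(fastq_files))
  trimmed <- vector("list", length(fastq_files))
  names(trimmed) <- names(fastq_files)
  qc <- data.frame(sample_id = names(fastq_files), total = 0L, retained = 0L,
                   no_adapter = 0L, too_short = 0L, has_N = 0L,
                   unannotated = 0L, stringsAsFactors = FALSE)
  for (j in seq_along(fastq_files)) {
    if (file.size(fastq_files[j]) == 0) {
      trimmed[[j]] <- character(0)
      next
    }
    reads <- as.character(Biostrings::readDNAStringSet(fastq_files[j],
                                                       format = "fastq"))
    tr <- trim_reads(reads, adapter, n_random, min_len, max_mismatch)
    qc$total[j] <- length(reads)
    qc$retained[j] <- sum(tr$reason == "ok")
    qc$no_adapter[j] <- sum(tr$reason == "no_adapter")
    qc$too_short[j] <- sum(tr$reason == "too_short")
    qc$has_N[j] <- sum(tr$reason == "has_N")
    trimmed[[j]] <- tr$insert[tr$reason == "ok"]
  }
  coll <- collapse_and_annotate(trimmed, reference)
  qc$unannotated <- coll$unannotated[qc$sample_id]
  filt <- qc_filter_samples(coll$counts, min_mapped)
  list(counts = filt$kept, lookup = coll$lookup, qc = qc,
       excluded_samples = filt$excluded)
}
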