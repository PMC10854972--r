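#' Median-of-ratios size factors
#'
#' Per-sample size factor s_j = median over reference genes of
#' count_gj / (geometric mean of gene g across samples). Only genes with a
#' nonzero count in every sample enter the reference, as the geometric mean
#' is otherwise zero.
#'
#' @param x a [seq_counts] or count matrix (genes x samples).
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(x) {
  m <- count_matrix(x)
  ref <- rowSums(m == 0) == 0
  if (!any(ref))
    stop("no gene has nonzero counts in every sample; ",
         "filter low-coverage samples or genes first")
  sub <- m[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, median)
  setNames(sf, colnames(m))
}

#' Divide counts by their size factors
#'
#' @param x a [seq_counts] or count matrix.
#' @param sf size factors; computed with [size_factors()] if omitted.
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(x, sf = size_factors(x)) {
  m <- count_matrix(x)
  stopifnot(length(sf) == ncol(m), all(sf > 0))
  sweep(m, 2, sf, "/")
}

#' Expression filter for a two-group comparison
#'
#' Keeps genes with a value strictly greater than `min_count` in at least
#' `min_frac` of the samples under comparison. Applied to raw counts before
#' differential expression and to normalized counts for the
#' coefficient-of-variation analysis.
#'
#' @param x a [seq_counts] or (possibly normalized) matrix, already
#'   subset to the samples being compared.
#' @param min_count strict lower threshold.
#' @param min_frac minimum fraction of samples exceeding it.
#' @return named logical vector, TRUE for kept genes.
#' @export
filter_expressed <- function(x, min_count = 10, min_frac = 0.5) {
  m <- count_matrix(x)
  if (ncol(m) == 0) stop("empty comparison: no samples")
  setNames(rowMeans(m > min_count) >= min_frac, rownames(m))
}
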