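#' Benjamini-Hochberg adjustment with explicit NA handling
#'
#' Step-up false-discovery-rate adjustment. NA entries (untested genes) are
#' passed through unchanged and excluded from the denominator.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Negative-binomial Wald test for differential expression
#'
#' A deliberately simple sequence-level NB test: median-of-ratios size
#' factors, per-gene method-of-moments dispersion shared between the two
#' groups, and a Wald test on the log2 fold change of the normalized group
#' means. There is no dispersion shrinkage, LFC shrinkage or independent
#' filtering, so results are close to, but not numerically identical with,
#' heavier NB machinery.
#'
#' Per gene, with normalized counts y: group means m1, m2; pooled
#' within-group variance s2 (n1 + n2 - 2 denominator); dispersion
#' phi = max(1e-8, (s2 - mbar) / mbar^2) where mbar is the overall mean;
#' Var(mk) ~ (mk + phi mk^2) / nk; the Wald statistic is
#' log2(m2/m1) / SE(log2FC) against a standard normal, two-sided. Genes
#' with all-zero counts are reported with NA and excluded from the BH
#' denominator; if one group mean is zero a 0.5 pseudocount enters the
#' ratio (sign is preserved).
#'
#' @param x a [seq_counts] or count matrix (raw counts), columns covering
#'   exactly the samples under comparison.
#' @param group factor/character of length ncol with exactly two levels;
#'   the log2 fold change is second level vs first (reference) level.
#' @param min_count,min_frac expression filter (on raw counts) applied
#'   before testing; set `filter = FALSE` to test all genes.
#' @param filter apply the expression filter.
#' @param sf size factors; computed from `x` if omitted.
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `base_mean`, `log2FC`, `lfcSE`, `stat`, `p`, `padj`, `filter_kept`
#'   (one row per input gene; untested genes carry NA statistics).
#' @export
nb_wald_de <- function(x, group, min_count = 10, min_frac = 0.5,
                       filter = TRUE, sf = NULL) {
  m <- count_matrix(x)
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("exactly two groups required, got: ",
         paste(levels(group), collapse = ", "))
  if (length(group) != ncol(m))
    stop("group length must match the number of samples")
  if (any(table(group) < 2)) stop("each group needs at least 2 samples")
  if (is.null(sf)) sf <- size_factors(m)
  y <- normalize_counts(m, sf)
  kept <- if (filter) filter_expressed(m, min_count, min_frac)
          else setNames(rep(TRUE, nrow(m)), rownames(m))
  i1 <- group == levels(group)[1]
  i2 <- group == levels(group)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  mbar <- rowMeans(y)
  ss <- rowSums((y[, i1, drop = FALSE] - m1)^2) +
        rowSums((y[, i2, drop = FALSE] - m2)^2)
  s2 <- ss / (n1 + n2 - 2)
  phi <- pmax(1e-8, (s2 - mbar) / pmax(mbar, 1e-12)^2)

  testable <- kept & mbar > 0
  pseudo <- ifelse(m1 == 0 | m2 == 0, 0.5, 0)
  lfc <- log2((m2 + pseudo) / (m1 + pseudo))
  v1 <- (m1 + phi * m1^2) / n1
  v2 <- (m2 + phi * m2^2) / n2
  se_ln <- sqrt(v1 / pmax(m1, pseudo)^2 + v2 / pmax(m2, pseudo)^2)
  se <- se_ln / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(stat))
  p[lfc == 0] <- 1
  lfc[!testable] <- NA_real_
  se[!testable] <- NA_real_
  stat[!testable] <- NA_real_
  p[!testable] <- NA_real_
  res <- data.frame(gene_id = rownames(m), base_mean = mbar, log2FC = lfc,
                    lfcSE = se, stat = stat, p = p, padj = bh_adjust(p),
                    filter_kept = unname(testable),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "comparison") <- paste(levels(group)[2], "vs", levels(group)[1])
  attr(res, "groups") <- levels(group)
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, alpha = 0.05, ...) {
  tested <- sum(x$filter_kept)
  cat(sprintf("Differential expression: %s\n", attr(x, "comparison")))
  cat(sprintf("  %d genes, %d tested, %d with p < %g, %d with padj < %g\n",
              nrow(x), tested, sum(x$p < alpha, na.rm = TRUE), alpha,
              sum(x$padj < alpha, na.rm = TRUE), alpha))
  invisible(x)
}

#' Genes significant at an unadjusted threshold
#'
#' @param de a `de_result`.
#' @param alpha unadjusted p threshold (strict).
#' @param adjusted use BH-adjusted p instead.
#' @return character vector of gene IDs.
#' @export
significant_genes <- function(de, alpha = 0.05, adjusted = FALSE) {
  p <- if (adjusted) de$padj else de$p
  de$gene_id[!is.na(p) & p < alpha]
}
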