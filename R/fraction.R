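#' Per-gene coefficient of variation comparison between plasma fractions
#'
#' Computes the per-gene %CV (100 * sd / mean) of normalized expression in
#' the EV-enriched and the EV-depleted fraction, restricted to genes passing
#' the expression filter (normalized value > `min_count` in at least
#' `min_frac` of samples) within both fractions, and compares the two %CV
#' distributions with a two-sided Welch t-test.
#'
#' @param norm_ev,norm_depleted normalized expression matrices
#'   (genes x samples) on a shared gene space (matched row names).
#' @param min_count,min_frac joint expression filter, applied per fraction.
#' @return object of class `cv_result`: list with `cv` (data.frame
#'   `gene_id`, `cv_ev`, `cv_depleted`), fraction medians, and the Welch
#'   test (`statistic`, `p`).
#' @export
percent_cv_comparison <- function(norm_ev, norm_depleted,
                                  min_count = 10, min_frac = 0.5) {
  if (!identical(rownames(norm_ev), rownames(norm_depleted)))
    stop("the two matrices must share the same genes (row names)")
  keep <- filter_expressed(norm_ev, min_count, min_frac) &
          filter_expressed(norm_depleted, min_count, min_frac)
  if (sum(keep) < 2)
    stop("fewer than 2 genes pass the expression filter in both fractions")
  cv <- function(m) 100 * apply(m, 1, sd) / rowMeans(m)
  cv_ev <- cv(norm_ev[keep, , drop = FALSE])
  cv_dep <- cv(norm_depleted[keep, , drop = FALSE])
  wt <- t.test(cv_dep, cv_ev, alternative = "two.sided", var.equal = FALSE)
  structure(list(
    cv = data.frame(gene_id = rownames(norm_ev)[keep], cv_ev = cv_ev,
                    cv_depleted = cv_dep, row.names = NULL,
                    stringsAsFactors = FALSE),
    median_ev = median(cv_ev), median_depleted = median(cv_dep),
    statistic = unname(wt$statistic), p = wt$p.value),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%%CV comparison over %d genes\n", nrow(x$cv)))
  cat(sprintf("  median %%CV: EV %.1f, depleted %.1f; Welch t = %.2f, p = %.3g\n",
              x$median_ev, x$median_depleted, x$statistic, x$p))
  invisible(x)
}

#' Detection overlap between the EV and EV-depleted fractions
#'
#' A sequence counts as detected in a fraction when it has a nonzero count
#' in at least one of that fraction's samples. The detected sets are
#' partitioned into EV-only, depleted-only and shared, overall and per
#' biotype, and the most abundant transcripts per fraction are listed.
#'
#' @param ev,depleted count matrices or [seq_counts] on a shared gene space.
#' @param annotation annotation data.frame with `gene_id` and `biotype`;
#'   taken from `ev` when it is a [seq_counts].
#' @param top_n how many top transcripts (by total reads) to report.
#' @return list with `overall` (named counts both/ev_only/depleted_only),
#'   `by_biotype` (matrix), `top_ev`, `top_depleted`.
#' @export
detection_overlap <- function(ev, depleted, annotation = annotation_of(ev),
                              top_n = 10) {
  m_ev <- count_matrix(ev)
  m_dep <- count_matrix(depleted)
  if (!identical(rownames(m_ev), rownames(m_dep)))
    stop("the two matrices must share the same genes (row names)")
  d_ev <- rowSums(m_ev > 0) > 0
  d_dep <- rowSums(m_dep > 0) > 0
  part <- factor(ifelse(d_ev & d_dep, "both",
                 ifelse(d_ev, "ev_only",
                 ifelse(d_dep, "depleted_only", "neither"))),
                 levels = c("both", "ev_only", "depleted_only", "neither"))
  overall <- table(part)[c("both", "ev_only", "depleted_only")]
  by_bio <- NULL
  if (!is.null(annotation)) {
    bio <- factor(annotation$biotype[match(rownames(m_ev),
                                           annotation$gene_id)],
                  levels = BIOTYPES)
    by_bio <- table(bio, part)[, c("both", "ev_only", "depleted_only")]
  }
  top <- function(m) head(rownames(m)[order(-rowSums(m))], top_n)
  list(overall = overall, by_biotype = by_bio,
       top_ev = top(m_ev), top_depleted = top(m_dep))
}

#' Concordance of two differential-expression signatures
#'
#' Compares two DE results computed against a shared reference group:
#' genes significant (unadjusted p < alpha) in only one, the other, or both
#' comparisons, and within the shared set how many agree in fold-change
#' direction. Zero log2 fold changes count as concordant only when both
#' are zero.
#'
#' @param de_a,de_b `de_result` objects.
#' @param alpha unadjusted significance threshold.
#' @return object of class `concordance_summary`: list with `a_only`,
#'   `b_only`, `shared` (gene IDs), `n_concordant`, `n_discordant`,
#'   `pct_concordant`.
#' @export
concordance_overlap <- function(de_a, de_b, alpha = 0.05) {
  sig_a <- significant_genes(de_a, alpha)
  sig_b <- significant_genes(de_b, alpha)
  shared <- intersect(sig_a, sig_b)
  sa <- sign(de_a$log2FC[match(shared, de_a$gene_id)])
  sb <- sign(de_b$log2FC[match(shared, de_b$gene_id)])
  conc <- sa == sb
  structure(list(a_only = setdiff(sig_a, shared),
                 b_only = setdiff(sig_b, shared),
                 shared = shared,
                 n_concordant = sum(conc),
                 n_discordant = sum(!conc),
                 pct_concordant = if (length(shared))
                   100 * mean(conc) else NA_real_),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("DE overlap: %d A-only, %d B-only, %d shared (%s%% concordant)\n",
              length(x$a_only), length(x$b_only), length(x$shared),
              if (is.na(x$pct_concordant)) "-" else
                format(x$pct_concordant, digits = 3)))
  invisible(x)
}
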