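#' Top differentially expressed genes by adjusted p or fold-change magnitude
#'
#' @param de a `de_result`.
#' @param by ranking criterion: `"padj"` (ascending adjusted p) or
#'   `"lfc"` (descending |log2FC|). Ties break on the other criterion,
#'   then on gene ID.
#' @param n how many genes (all tested genes, with a warning, if fewer).
#' @return character vector of gene IDs.
#' @export
select_top10 <- function(de, by = c("padj", "lfc"), n = 10L) {
  by <- match.arg(by)
  tested <- de[!is.na(de$p), , drop = FALSE]
  ord <- if (by == "padj") {
    order(tested$padj, -abs(tested$log2FC), tested$gene_id)
  } else {
    order(-abs(tested$log2FC), tested$padj, tested$gene_id)
  }
  if (nrow(tested) < n)
    warning("only ", nrow(tested), " tested genes available; returning all")
  tested$gene_id[ord][seq_len(min(n, nrow(tested)))]
}

#' Logistic-regression benchmark over repeated random splits
#'
#' Fits an unpenalized binomial GLM on the supplied feature matrix
#' (typically the normalized counts of the top-10 DE genes) over
#' `n_repeats` random 80/20 training/test splits, recording held-out
#' accuracy at the 0.5 cutoff and ROC AUC. Splits with a single-class
#' training part are redrawn; fits that fail to converge (e.g. perfect
#' separation) are kept but counted.
#'
#' @param X samples x features numeric matrix or data.frame.
#' @param y 0/1 labels or two-level factor.
#' @param n_repeats number of random splits.
#' @param test_frac held-out fraction.
#' @param seed RNG seed.
#' @return object of class `lrm_result`: gene list, full-data
#'   coefficients, mean/sd accuracy and AUC, per-repeat table, number of
#'   non-converged fits.
#' @export
fit_evaluate_lrm <- function(X, y, n_repeats = 100L, test_frac = 0.2,
                             seed = 1L) {
  X <- as.data.frame(X)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    stopifnot(nlevels(y) == 2)
    lev <- levels(y)
    y <- as.integer(y == lev[2])
  } else lev <- c("0", "1")
  stopifnot(length(unique(y)) == 2, nrow(X) == length(y))
  set.seed(seed)
  dat <- cbind(.y = y, X)
  acc <- auc <- numeric(n_repeats)
  n_flagged <- 0L
  for (it in seq_len(n_repeats)) {
    test <- draw_split(nrow(X), y, test_frac)
    fit <- suppressWarnings(glm(.y ~ ., family = binomial(),
                                data = dat[-test, , drop = FALSE]))
    if (!fit$converged) n_flagged <- n_flagged + 1L
    prob <- suppressWarnings(
      predict(fit, newdata = dat[test, , drop = FALSE], type = "response"))
    acc[it] <- mean((prob > 0.5) == y[test])
    auc[it] <- roc_auc(y[test], prob)
  }
  full <- suppressWarnings(glm(.y ~ ., family = binomial(), data = dat))
  structure(list(genes = colnames(X), levels = lev,
                 coefficients = coef(full),
                 mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 mean_auc = mean(auc, na.rm = TRUE),
                 sd_auc = sd(auc, na.rm = TRUE),
                 n_repeats = n_repeats, n_not_converged = n_flagged,
                 per_repeat = data.frame(repeat_id = seq_len(n_repeats),
                                         accuracy = acc, auc = auc)),
            class = "lrm_result")
}

#' @export
print.lrm_result <- function(x, ...) {
  cat(sprintf("Logistic-regression model on %d genes (%s vs %s)\n",
              length(x$genes), x$levels[1], x$levels[2]))
  cat(sprintf("  accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f over %d repeats\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_auc, x$sd_auc,
              x$n_repeats))
  if (x$n_not_converged)
    cat(sprintf("  %d fit(s) did not converge (possible separation)\n",
                x$n_not_converged))
  invisible(x)
}

#' Per-gene linear regression of expression on time to conversion
#'
#' For converter samples, regresses normalized expression on the time axis
#' x = -years_to_conversion (so x = -4 means the diagnosis came 4 years
#' after the blood draw and x rises toward 0 as conversion approaches).
#' Genes with R^2 >= `r2_min` and a two-sided slope-t-test p < `alpha`
#' are flagged as significantly tracking disease progression.
#'
#' @param expr normalized expression matrix (genes x converter samples).
#' @param years_to_conversion positive years from draw to the later
#'   diagnosis, one per column of `expr`.
#' @param r2_min,alpha flagging thresholds.
#' @return data.frame of class `conversion_trend`: `gene_id`, `slope`
#'   (normalized counts per year), `intercept`, `r_squared`, `p`,
#'   `flagged`.
#' @export
time_to_conversion_regression <- function(expr, years_to_conversion,
                                          r2_min = 0.66, alpha = 0.05) {
  expr <- as.matrix(expr)
  yrs <- years_to_conversion
  if (length(yrs) != ncol(expr))
    stop("one years_to_conversion value per expression column required")
  if (any(yrs <= 0)) stop("years_to_conversion must be positive for converters")
  n <- length(yrs)
  if (n < 3) stop("regression needs at least 3 converter samples")
  x <- -yrs
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(expr %*% xc) / sxx
  intercept <- rowMeans(expr) - slope * mean(x)
  fitted <- outer(slope, x) + intercept
  rss <- rowSums((expr - fitted)^2)
  tss <- rowSums((expr - rowMeans(expr))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  res <- data.frame(gene_id = rownames(expr), slope = slope,
                    intercept = intercept, r_squared = r2, p = p,
                    flagged = r2 >= r2_min & !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("conversion_trend", "data.frame")
  attr(res, "n_converters") <- n
  res
}

#' @export
print.conversion_trend <- function(x, ...) {
  cat(sprintf("Time-to-conversion regression over %d genes (%d converters)\n",
              nrow(x), attr(x, "n_converters")))
  cat(sprintf("  %d gene(s) flagged (R^2 and p thresholds)\n", sum(x$flagged)))
  invisible(x)
}
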