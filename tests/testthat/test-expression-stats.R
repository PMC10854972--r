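test_that("size factors are 1 for identical columns and scale with depth", {
  m <- matrix(rep(c(5L, 10L, 20L), 4), ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4), tolerance = 1e-12)

  m2 <- cbind(A = c(5L, 10L, 20L), B = c(10L, 20L, 40L))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2, tolerance = 1e-12)

  mz <- matrix(c(0L, 1L, 1L, 0L), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(mz), "nonzero")
})

test_that("size factors equal the brute-force median-of-ratios oracle", {
  set.seed(101)
  for (i in 1:20) {
    m <- random_count_matrix(50, 10)
    expect_equal(unname(size_factors(m)), unname(oracle_size_factors(m)),
                 tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  # an odd reference size makes the ratio-scale and log-scale medians
  # coincide, so the agreement is exact
  m <- random_count_matrix(81, 8)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA entries pass through and leave the denominator
  p <- c(0.01, NA, 0.02)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.02))
})

test_that("BH equals the brute-force oracle and is monotone", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_false(is.unsorted(adj[order(p)]))
  }
})

test_that("the expression filter uses a strict threshold", {
  m <- rbind(g1 = c(11, 11, 0, 0), g2 = rep(10, 4), g3 = rep(50, 4))
  colnames(m) <- paste0("s", 1:4)
  keep <- filter_expressed(m, min_count = 10, min_frac = 0.5)
  expect_true(keep[["g1"]])    # > 10 in exactly half the samples
  expect_false(keep[["g2"]])   # 10 everywhere fails the strict >
  expect_true(all(filter_expressed(m, 0, 0)))
})

test_that("the NB Wald test handles degenerate and constant genes", {
  m <- rbind(const = rep(20L, 8), zero = rep(0L, 8), other = rep(7L, 8))
  colnames(m) <- paste0("s", 1:8)
  grp <- factor(rep(c("a", "b"), each = 4))
  de <- nb_wald_de(m, grp, filter = FALSE)
  expect_equal(de$log2FC[de$gene_id == "const"], 0)
  expect_equal(de$p[de$gene_id == "const"], 1)
  expect_true(is.na(de$p[de$gene_id == "zero"]))

  m2 <- rbind(up = c(5L, 8L, 6L, 7L, 40L, 45L, 50L, 38L),
              flat = rep(20L, 8))
  colnames(m2) <- paste0("s", 1:8)
  de2 <- nb_wald_de(m2, grp, filter = FALSE,
                    sf = setNames(rep(1, 8), colnames(m2)))
  expect_gt(de2$log2FC[de2$gene_id == "up"], 0)
  expect_lt(de2$p[de2$gene_id == "up"], 0.05)
  # padj never below p among tested genes
  tested <- !is.na(de2$p)
  expect_true(all(de2$padj[tested] >= de2$p[tested] - 1e-12))
})

test_that("log2FC sign equals the sign of the normalized group-mean difference", {
  set.seed(33)
  m <- random_count_matrix(100, 12, lambda = 40)
  grp <- factor(rep(c("a", "b"), each = 6))
  de <- nb_wald_de(m, grp, filter = FALSE)
  y <- normalize_counts(m)
  diffm <- rowMeans(y[, 7:12]) - rowMeans(y[, 1:6])
  expect_equal(unname(sign(de$log2FC)), unname(sign(diffm)))
})

test_that("%CV arithmetic is exact on constructed genes", {
  ev <- rbind(flat = rep(20, 6), g = c(11, 22, 33, 11, 22, 33))
  dep <- ev * c(1, 1)
  colnames(ev) <- colnames(dep) <- paste0("s", 1:6)
  res <- percent_cv_comparison(ev, dep, min_count = 10, min_frac = 0.5)
  expect_equal(res$cv$cv_ev[res$cv$gene_id == "flat"], 0)
  v <- c(1, 2, 3) * 11
  expect_equal(res$cv$cv_ev[res$cv$gene_id == "g"],
               100 * sd(c(v, v)) / mean(c(v, v)))
  # the Welch test agrees with the textbook formula
  set.seed(8)
  ev2 <- matrix(runif(600, 20, 200), 100,
                dimnames = list(paste0("g", 1:100), paste0("e", 1:6)))
  dep2 <- matrix(runif(600, 20, 200), 100,
                 dimnames = list(paste0("g", 1:100), paste0("d", 1:6)))
  res2 <- percent_cv_comparison(ev2, dep2)
  o <- oracle_welch(res2$cv$cv_depleted, res2$cv$cv_ev)
  expect_equal(res2$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(res2$p, o$p, tolerance = 1e-10)
  expect_error(percent_cv_comparison(ev[1, , drop = FALSE] * 0,
                                     dep[1, , drop = FALSE] * 0), "fewer than 2")
})

test_that("detection overlap partitions detected sequences exhaustively", {
  m1 <- rbind(a = c(1, 0), b = c(2, 3), c = c(0, 0))
  m2 <- rbind(a = c(0, 0), b = c(1, 0), c = c(4, 0))
  colnames(m1) <- c("e1", "e2"); colnames(m2) <- c("d1", "d2")
  ov <- detection_overlap(m1, m2)
  expect_equal(as.numeric(ov$overall), c(1, 1, 1)) # both, ev, dep
  ov_same <- detection_overlap(m1, m1)
  expect_equal(as.numeric(ov_same$overall[c("ev_only", "depleted_only")]),
               c(0, 0))
  disj_a <- rbind(a = 1, b = 0); disj_b <- rbind(a = 0, b = 1)
  colnames(disj_a) <- colnames(disj_b) <- "s"
  expect_equal(as.numeric(detection_overlap(disj_a, disj_b)$overall[["both"]]),
               0)
})

test_that("planted depleted-fraction dropout shows up as EV-only detections", {
  d <- tiny_design(seed = 41, n_per_group = c(control = 10),
                   n_genes_per_biotype = c(miRNA = 1000),
                   isomir_family_sizes = 1, isomir_family_probs = 1,
                   library_size_mean = 2e5,
                   depleted_prob = 1, depleted_dropout_rate = 0.3)
  sim <- simulate_cohort(d)
  md <- sim$metadata
  ev <- sim$counts$counts[, md$sample_id[md$fraction == "EV"]]
  dep <- sim$counts$counts[, md$sample_id[md$fraction == "depleted"]]
  ov <- detection_overlap(ev, dep)
  ev_detected <- sum(ov$overall[c("both", "ev_only")])
  expect_lt(abs(ov$overall[["ev_only"]] / ev_detected - 0.3), 0.05)
})

test_that("concordance counts match exhaustive enumeration on toy DE tables", {
  mk_de <- function(p, lfc) {
    d <- data.frame(gene_id = paste0("g", seq_along(p)), base_mean = 10,
                    log2FC = lfc, lfcSE = 1, stat = 0, p = p,
                    padj = bh_adjust(p), filter_kept = TRUE,
                    stringsAsFactors = FALSE)
    class(d) <- c("de_result", "data.frame")
    d
  }
  a <- mk_de(c(0.01, 0.02, 0.2, 0.03, 0.04), c(1, -1, 1, 2, 0))
  b <- mk_de(c(0.04, 0.01, 0.01, 0.2, 0.01), c(1, 1, -2, 2, 0))
  res <- concordance_overlap(a, b, alpha = 0.05)
  # shared significant: g1, g2, g5; concordant: g1 (+/+), g5 (0/0)
  expect_setequal(res$shared, c("g1", "g2", "g5"))
  expect_equal(res$n_concordant, 2)
  expect_equal(res$n_discordant, 1)
  expect_equal(res$a_only, "g4")
  expect_equal(res$b_only, "g3")
  same <- concordance_overlap(a, a)
  expect_equal(same$pct_concordant, 100)
  expect_equal(res$n_concordant + res$n_discordant, length(res$shared))
})

test_that("null NB-Wald p-values are approximately uniform", {
  set.seed(99)
  ngen <- 2000; n <- 40
  base <- rlnorm(ngen, log(100), 1)
  mu <- outer(base, rlnorm(n, 0, 0.25))
  m <- matrix(rnbinom(ngen * n, mu = mu, size = 1 / 0.2), ngen,
              dimnames = list(paste0("g", 1:ngen), paste0("s", 1:n)))
  de <- nb_wald_de(m, factor(rep(c("a", "b"), each = 20)))
  ks <- suppressWarnings(ks.test(de$p[!is.na(de$p)], "punif"))
  expect_gt(ks$p.value, 0.01)
})
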