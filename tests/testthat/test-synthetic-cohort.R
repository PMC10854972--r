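test_that("reference generation respects family structure, counts and determinism", {
  d1 <- cohort_design(n_per_group = c(control = 2),
                      n_genes_per_biotype = c(miRNA = 1),
                      isomir_family_sizes = 3, isomir_family_probs = 1,
                      seed = 11)
  ref <- simulate_reference(d1)
  expect_equal(nrow(ref), 3)
  expect_equal(unique(ref$canonical_gene), "miR-1")
  expect_equal(anyDuplicated(ref$sequence), 0L)
  expect_true(all(nchar(ref$sequence) >= 15 & nchar(ref$sequence) <= 45))

  expect_identical(simulate_reference(d1), simulate_reference(d1))

  d2 <- cohort_design(n_per_group = c(control = 2),
                      n_genes_per_biotype = setNames(rep(50, 6),
                                                     evsmallrna:::BIOTYPES),
                      isomir_family_sizes = 1, isomir_family_probs = 1,
                      seed = 3)
  expect_equal(nrow(simulate_reference(d2)), 300)
})

test_that("unplanted group contrasts are centred at zero and planted effects are recovered", {
  d <- tiny_design(seed = 5,
                   n_per_group = c(control = 20, AD = 20),
                   n_genes_per_biotype = c(miRNA = 500, YRNA = 250,
                                           tRNA = 250),
                   isomir_family_sizes = 1, isomir_family_probs = 1,
                   library_size_mean = 1e5)
  sim <- simulate_cohort(d)
  grp <- sim$metadata$group
  y <- normalize_counts(sim$counts)
  lr <- log2((rowMeans(y[, grp == "AD"]) + 0.5) /
             (rowMeans(y[, grp == "control"]) + 0.5))
  expect_lt(abs(mean(lr)), 0.1)

  d2 <- tiny_design(seed = 5,
                    n_per_group = c(control = 20, AD = 20),
                    n_genes_per_biotype = c(miRNA = 500, YRNA = 250,
                                            tRNA = 250),
                    isomir_family_sizes = 1, isomir_family_probs = 1,
                    library_size_mean = 1e5,
                    planted_effects = list(list(genes = paste0("miR-", 1:20),
                                                group = "AD", log2FC = 2)))
  sim2 <- simulate_cohort(d2)
  y2 <- normalize_counts(sim2$counts)
  planted <- rownames(sim2$counts$counts)[sim2$truth$lfc[, "AD"] != 0]
  lr2 <- log2((rowMeans(y2[planted, sim2$metadata$group == "AD"]) + 0.5) /
              (rowMeans(y2[planted, sim2$metadata$group == "control"]) + 0.5))
  expect_lt(abs(mean(lr2) - 2), 0.3)
})

test_that("planted log2FC converges to the target with larger groups", {
  d <- tiny_design(seed = 9,
                   n_per_group = c(control = 50, AD = 50),
                   n_genes_per_biotype = c(miRNA = 300),
                   isomir_family_sizes = 1, isomir_family_probs = 1,
                   library_size_mean = 1e5,
                   planted_effects = list(list(genes = paste0("miR-", 1:15),
                                               group = "AD", log2FC = 1.5)))
  sim <- simulate_cohort(d)
  y <- normalize_counts(sim$counts)
  planted <- rownames(sim$counts$counts)[sim$truth$lfc[, "AD"] != 0]
  lr <- log2((rowMeans(y[planted, sim$metadata$group == "AD"]) + 0.5) /
             (rowMeans(y[planted, sim$metadata$group == "control"]) + 0.5))
  expect_lt(abs(mean(lr) - 1.5), 0.2)
})

test_that("zero converter effect scale leaves converters indistinguishable from controls", {
  d <- tiny_design(seed = 21,
                   n_per_group = c(control = 20, AD = 20, C_to_AD = 10),
                   n_genes_per_biotype = c(miRNA = 500),
                   isomir_family_sizes = 1, isomir_family_probs = 1,
                   library_size_mean = 1e5,
                   converter_effect_scale = 0,
                   planted_effects = list(list(genes = paste0("miR-", 1:25),
                                               group = "AD", log2FC = 2)))
  sim <- simulate_cohort(d)
  y <- normalize_counts(sim$counts)
  grp <- sim$metadata$group
  ks <- suppressWarnings(
    ks.test(rowMeans(y[, grp == "C_to_AD"]), rowMeans(y[, grp == "control"])))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort simulation is deterministic and metadata satisfies its invariants", {
  d <- tiny_design(seed = 13, n_per_group = c(control = 8, MCI = 6, AD = 6,
                                              C_to_AD = 4, C_to_MCI = 3,
                                              MCI_to_AD = 3),
                   depleted_prob = 0.5)
  s1 <- simulate_cohort(d)
  s2 <- simulate_cohort(d)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$metadata, s2$metadata)

  md <- s1$metadata
  expect_true(all(md$years_to_conversion[md$converts_to == "none"] == 0))
  expect_true(all(md$years_to_conversion[md$converts_to != "none"] > 0))
  expect_true(all(md$MMSE >= 0 & md$MMSE <= 30))
  expect_true(all(md$DRS >= 0 & md$DRS <= 144))
  expect_true(all(md$fraction %in% c("EV", "depleted")))
  # matched depleted rows mirror their EV subject
  dep <- md[md$fraction == "depleted", ]
  ev_match <- md[match(sub("_dep$", "", dep$sample_id), md$sample_id), ]
  expect_identical(dep$group, ev_match$group)
})

test_that("non-converter counts are invariant to the converter effect scale", {
  mk <- function(scale) {
    d <- tiny_design(seed = 31, n_per_group = c(control = 6, AD = 6,
                                                C_to_AD = 4),
                     n_genes_per_biotype = c(miRNA = 50),
                     converter_effect_scale = scale,
                     planted_effects = list(list(genes = "miR-1",
                                                 group = "AD", log2FC = 2)))
    simulate_cohort(d)
  }
  s0 <- mk(0); s1 <- mk(1)
  non_conv <- s0$metadata$sample_id[s0$metadata$group %in% c("control", "AD")]
  common <- intersect(rownames(s0$counts$counts), rownames(s1$counts$counts))
  expect_identical(s0$counts$counts[common, non_conv],
                   s1$counts$counts[common, non_conv])
})

test_that("simulated reads round-trip and empty columns give empty FASTQ", {
  ref <- data.frame(sequence = c("ACGTACGTACGTACGTAC", "TTTTCCCCGGGGAAAATT"),
                    canonical_gene = c("miR-9", "miR-9"),
                    biotype = "miRNA", stringsAsFactors = FALSE)
  counts <- build_tiny_counts(ref, S1 = c(5L, 2L), S2 = c(0L, 0L))
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  out <- withr::local_tempdir()
  fq <- simulate_reads(counts, adapter, out, n_random = 4, seed = 2)
  expect_equal(file.size(fq[["S2"]]), 0)
  res <- count_smallrna(fq, ref, adapter, min_mapped = 0)
  # the empty sample has no annotated reads and is dropped by the QC rule
  expect_identical(res$counts$counts, counts$counts[, "S1", drop = FALSE])
  expect_identical(res$counts$annotation, counts$annotation)
})

test_that("design validation rejects invalid settings", {
  expect_error(cohort_design(n_per_group = c(bogus = 3)), "unknown group")
  expect_error(cohort_design(converter_effect_scale = -0.1), "\\[0, 1\\]")
  expect_error(cohort_design(n_per_group = c(control = 0)), "positive")
  expect_error(simulate_reads(simulate_cohort(tiny_design())$counts,
                              "ADAPTER", tempdir()), "A/C/G/T")
})
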