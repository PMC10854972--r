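test_that("feature preselection applies a strict unadjusted-p threshold", {
  d <- data.frame(gene_id = c("a", "b", "c"), base_mean = 1,
                  log2FC = 1, lfcSE = 1, stat = 1,
                  p = c(0.01, 0.049, 0.05), padj = c(0.03, 0.07, 0.07),
                  filter_kept = TRUE, stringsAsFactors = FALSE)
  class(d) <- c("de_result", "data.frame")
  expect_equal(preselect_features(d), c("a", "b"))
  d$p <- rep(0.5, 3)
  expect_error(preselect_features(d), "no features")
})

test_that("penalty tuning reaches perfect accuracy on separated clusters", {
  gc <- gaussian_clusters(n_per_class = 16, n_feat = 20, shift = 4, seed = 2)
  tuned <- tune_lambda(gc$X, gc$y, alpha = 0.5, n_iter = 25, seed = 7)
  expect_equal(tuned$best_accuracy, 1)
  expect_gt(tuned$lambda, 0)
  # a single iteration is deterministic under the seed
  t1 <- tune_lambda(gc$X, gc$y, n_iter = 1, seed = 3)
  t2 <- tune_lambda(gc$X, gc$y, n_iter = 1, seed = 3)
  expect_identical(t1, t2)
})

test_that("shuffled labels bring tuning accuracy down to chance", {
  gc <- gaussian_clusters(n_per_class = 16, n_feat = 20, shift = 4, seed = 2)
  set.seed(11)
  yperm <- sample(gc$y)
  tuned <- tune_lambda(gc$X, yperm, n_iter = 20, seed = 7)
  expect_lt(mean(tuned$accuracies), 0.75)
})

test_that("feature selection recovers planted features and respects the penalty limit", {
  gc <- gaussian_clusters(n_per_class = 20, n_feat = 100, shift = 4,
                          n_informative = 10, seed = 4)
  tuned <- tune_lambda(gc$X, gc$y, n_iter = 20, seed = 5)
  sel <- select_features(gc$X, gc$y, tuned$lambda, n_iter = 40, seed = 6)
  expect_gte(length(intersect(sel$features, paste0("f", 1:10))), 8)
  expect_true(all(sel$features %in% colnames(gc$X)))
  # an essentially infinite penalty shrinks everything away
  sel_inf <- suppressWarnings(
    select_features(gc$X, gc$y, lambda = 1e6, n_iter = 5, seed = 6))
  expect_lte(length(sel_inf$features), 1)
  # determinism
  sel2 <- select_features(gc$X, gc$y, tuned$lambda, n_iter = 40, seed = 6)
  expect_identical(sel$features, sel2$features)
})

test_that("performance estimation separates signal from permutation noise", {
  gc <- gaussian_clusters(n_per_class = 16, n_feat = 30, shift = 4,
                          n_informative = 5, seed = 9)
  perf <- estimate_performance(gc$X, gc$y, lambda = 0.05,
                               features = paste0("f", 1:5),
                               n_iter = 50, seed = 10)
  expect_gte(perf$mean_accuracy, 0.95)
  expect_gte(perf$mean_auc, 0.98)
  set.seed(12)
  perm <- estimate_performance(gc$X, sample(gc$y), lambda = 0.05,
                               features = paste0("f", 1:5),
                               n_iter = 50, seed = 10)
  expect_gt(perm$mean_accuracy, 0.3)
  expect_lt(perm$mean_accuracy, 0.7)
  expect_error(estimate_performance(gc$X, gc$y, 0.05, character(0)),
               "empty feature set")
})

test_that("the full three-loop classifier separates a planted two-group cohort", {
  sim <- simulate_cohort(separable_design(seed = 3))
  grp <- factor(sim$metadata$group, levels = c("control", "AD"))
  fit <- elnet_classify(sim$counts, grp, n_iter = 30, seed = 5)
  expect_s3_class(fit, "elnet_model")
  expect_gte(fit$performance$mean_accuracy, 0.9)
  expect_gte(fit$all_sample_accuracy, 0.95)
  expect_true(all(fit$features %in% fit$feature_pool))
  # probabilities live in [0,1] and are invariant to sample order
  p1 <- predict(fit, sim$counts)
  expect_true(all(p1 >= 0 & p1 <= 1))
  shuf <- sample(ncol(sim$counts$counts))
  p2 <- predict(fit, sim$counts$counts[, shuf])
  expect_equal(p2[names(p1)], p1)
  # same seed, same model
  fit2 <- elnet_classify(sim$counts, grp, n_iter = 30, seed = 5)
  expect_identical(fit$features, fit2$features)
  expect_equal(fit$lambda, fit2$lambda)
  expect_equal(fit$waterfall, fit2$waterfall)
})

test_that("prediction fails loudly when a model feature is missing", {
  sim <- simulate_cohort(separable_design(seed = 3))
  grp <- factor(sim$metadata$group, levels = c("control", "AD"))
  fit <- elnet_classify(sim$counts, grp, n_iter = 10, seed = 5)
  m <- sim$counts$counts
  drop_gene <- fit$features[1]
  expect_error(predict(fit, m[setdiff(rownames(m), drop_gene), ]),
               "absent")
})

test_that("a null-coefficient model gives probability one half everywhere", {
  stub <- structure(list(alpha = 0.5, lambda = 0.1,
                         features = character(0),
                         beta = setNames(numeric(0), character(0)), b0 = 0,
                         levels = c("normal", "PART"),
                         feature_pool = character(0),
                         center = numeric(0), scale = numeric(0),
                         ref_log_geomean = c(g1 = log(10))),
                    class = "elnet_model")
  m <- matrix(c(10L, 20L), 1, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(predict(stub, m)), c(0.5, 0.5))
  # the flagging cutoff is inclusive at exactly 0.5
  expect_equal(flag_suspected_part(stub, m, cutoff = 0.5), c("s1", "s2"))
  stub$b0 <- qlogis(0.49)
  expect_equal(flag_suspected_part(stub, m, cutoff = 0.5), character(0))
})

test_that("converter projection orders and assigns by probability", {
  sim <- simulate_cohort(separable_design(seed = 6,
                                          n_per_group = c(control = 12,
                                                          AD = 12,
                                                          C_to_AD = 6),
                                          converter_effect_scale = 1))
  md <- sim$metadata
  nc <- md$group %in% c("control", "AD")
  grp <- factor(md$group[nc], levels = c("control", "AD"))
  fit <- elnet_classify(sim$counts$counts[, md$sample_id[nc]], grp,
                        n_iter = 25, seed = 8)
  proj <- project_new_samples(fit,
                              sim$counts$counts[, md$sample_id[md$group == "C_to_AD"]])
  expect_equal(nrow(proj$projection), 6)
  expect_false(is.unsorted(proj$projection$probability))
  expect_equal(sum(proj$assigned), 6)
  # full-scale converters carry the full disease signature
  expect_gte(proj$assigned[["AD"]], 5)
})
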