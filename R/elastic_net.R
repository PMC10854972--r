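#' Pre-select classifier features from a DE result
#'
#' Sequences with unadjusted p < `alpha_p` between the two groups being
#' classified form the feature pool for the elastic net.
#'
#' @param de a `de_result` for the same two groups.
#' @param alpha_p strict unadjusted-p threshold.
#' @return character vector of gene IDs, in the DE table's (stable) order.
#' @export
preselect_features <- function(de, alpha_p = 0.05) {
  feats <- significant_genes(de, alpha_p)
  if (length(feats) == 0)
    stop("no features with unadjusted p < ", alpha_p,
         "; raise the threshold or revisit the comparison")
  feats
}

# 80/20 split with both classes required in the training part; single-class
# training draws are rejected and redrawn (bounded).
draw_split <- function(n, y, test_frac = 0.2, max_tries = 100L) {
  n_test <- max(1L, round(n * test_frac))
  for (i in seq_len(max_tries)) {
    test <- sample(n, n_test)
    if (length(unique(y[-test])) == 2L) return(test)
  }
  stop("could not draw a training split containing both classes")
}

glmnet_nfolds <- function(n_train) max(3L, min(10L, n_train))

# glmnet refuses single-column predictor matrices; pad with an all-zero
# dummy column whose coefficient is necessarily zero.
pad_x <- function(X) {
  if (ncol(X) >= 2L) return(X)
  cbind(X, `.dummy` = 0)
}

roc_auc <- function(y, prob) {
  if (length(unique(y)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(y, prob, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

#' Loop 1: tune the elastic-net penalty over repeated random splits
#'
#' For each of `n_iter` random 80/20 training/test splits, an internally
#' cross-validated elastic-net path is fit on the training part; the
#' accuracy-optimal penalty of that iteration (lambda.min) is scored by its
#' classification accuracy on the held-out 20% at a 0.5 probability cutoff.
#' The penalty of the single best-accuracy iteration is returned (ties: the
#' first iteration encountered).
#'
#' @param X samples x features numeric matrix (already normalized,
#'   log-transformed and standardized).
#' @param y 0/1 class labels.
#' @param alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param n_iter number of random splits.
#' @param test_frac held-out fraction per split.
#' @param seed RNG seed for the split and fold sequence.
#' @return list with `lambda`, `best_accuracy`, `best_iteration`,
#'   `accuracies` (per-iteration test accuracies).
#' @export
tune_lambda <- function(X, y, alpha = 0.5, n_iter = 1000L, test_frac = 0.2,
                        seed = 1L) {
  stopifnot(n_iter >= 1L, length(unique(y)) == 2L)
  set.seed(seed)
  Xp <- pad_x(X)
  acc <- numeric(n_iter)
  best <- -Inf; best_lambda <- NA_real_; best_it <- NA_integer_
  for (it in seq_len(n_iter)) {
    test <- draw_split(nrow(Xp), y, test_frac)
    cvfit <- cv.glmnet_retry(Xp[-test, , drop = FALSE], y[-test], alpha)
    prob <- predict(cvfit, Xp[test, , drop = FALSE], s = cvfit$lambda.min,
                    type = "response")
    acc[it] <- mean((prob > 0.5) == y[test])
    if (acc[it] > best) {
      best <- acc[it]; best_lambda <- cvfit$lambda.min; best_it <- it
    }
  }
  list(lambda = best_lambda, best_accuracy = best, best_iteration = best_it,
       accuracies = acc)
}

cv.glmnet_retry <- function(Xtr, ytr, alpha, tries = 5L) {
  nf <- glmnet_nfolds(length(ytr))
  for (i in seq_len(tries)) {
    fit <- tryCatch(
      suppressWarnings(glmnet::cv.glmnet(Xtr, ytr, family = "binomial",
                                         alpha = alpha, nfolds = nf,
                                         type.measure = "class")),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  stop("cross-validated elastic-net fit failed repeatedly ",
       "(groups too small?)")
}

#' Loop 2: select the feature set at a fixed penalty
#'
#' For each random 80/20 split an elastic net is fit on the training part
#' at the fixed penalty from [tune_lambda()]; the nonzero-coefficient
#' sequences of the single best test-accuracy iteration are the selected
#' feature set (ties: first).
#'
#' @inheritParams tune_lambda
#' @param lambda fixed penalty.
#' @return list with `features`, `beta` (named nonzero coefficients),
#'   `b0` (intercept), `accuracy` (best test accuracy), `training`
#'   (row indices of the best iteration's training samples),
#'   `accuracies`.
#' @export
select_features <- function(X, y, lambda, alpha = 0.5, n_iter = 1000L,
                            test_frac = 0.2, seed = 1L) {
  set.seed(seed)
  Xp <- pad_x(X)
  acc <- numeric(n_iter)
  best <- -Inf; best_fit <- NULL; best_train <- NULL
  for (it in seq_len(n_iter)) {
    test <- draw_split(nrow(Xp), y, test_frac)
    fit <- suppressWarnings(glmnet::glmnet(Xp[-test, , drop = FALSE],
                                           y[-test], family = "binomial",
                                           alpha = alpha))
    prob <- predict(fit, Xp[test, , drop = FALSE], s = lambda,
                    type = "response")
    acc[it] <- mean((prob > 0.5) == y[test])
    if (acc[it] > best) {
      best <- acc[it]; best_fit <- fit
      best_train <- setdiff(seq_len(nrow(Xp)), test)
    }
  }
  cf <- as.matrix(coef(best_fit, s = lambda))[, 1]
  beta <- cf[-1]
  beta <- beta[beta != 0 & names(beta) != ".dummy"]
  if (length(beta) == 0)
    warning("best model has no nonzero coefficients at this penalty")
  list(features = names(beta), beta = beta, b0 = unname(cf[1]),
       accuracy = best, training = best_train, accuracies = acc)
}

#' Loop 3: estimate performance at fixed penalty and feature set
#'
#' Repeated 80/20 splits, refitting the penalized model restricted to the
#' selected features on each training part, recording held-out accuracy
#' (0.5 cutoff) and the area under the empirical ROC curve. Iterations
#' whose test split contains a single class have no defined AUC and are
#' excluded from the AUC mean (their number is reported).
#'
#' @inheritParams select_features
#' @param features the selected feature set (column names of `X`).
#' @return object of class `model_performance`: list with `mean_accuracy`,
#'   `sd_accuracy`, `mean_auc`, `sd_auc`, `n_iterations`,
#'   `n_auc_undefined`, and the per-iteration vectors.
#' @export
estimate_performance <- function(X, y, lambda, features, alpha = 0.5,
                                 n_iter = 1000L, test_frac = 0.2, seed = 1L) {
  if (length(features) == 0) stop("empty feature set")
  set.seed(seed)
  Xf <- pad_x(X[, features, drop = FALSE])
  acc <- auc <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    test <- draw_split(nrow(Xf), y, test_frac)
    fit <- suppressWarnings(glmnet::glmnet(Xf[-test, , drop = FALSE],
                                           y[-test], family = "binomial",
                                           alpha = alpha))
    prob <- predict(fit, Xf[test, , drop = FALSE], s = lambda,
                    type = "response")[, 1]
    acc[it] <- mean((prob > 0.5) == y[test])
    auc[it] <- roc_auc(y[test], prob)
  }
  structure(list(mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 mean_auc = mean(auc, na.rm = TRUE),
                 sd_auc = sd(auc, na.rm = TRUE),
                 n_iterations = n_iter, n_auc_undefined = sum(is.na(auc)),
                 accuracies = acc, aucs = auc),
            class = "model_performance")
}

#' @export
print.model_performance <- function(x, ...) {
  cat(sprintf("accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f (%d iterations%s)\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_auc, x$sd_auc,
              x$n_iterations,
              if (x$n_auc_undefined)
                sprintf(", %d without AUC", x$n_auc_undefined) else ""))
  invisible(x)
}

#' Three-loop elastic-net classifier for two sample groups
#'
#' The full repeated-random-split procedure: (1) tune the penalty over
#' `n_iter` 80/20 splits of an internally cross-validated elastic net;
#' (2) at that fixed penalty, select the nonzero-coefficient sequences of
#' the best split's model; (3) at fixed penalty and feature set, estimate
#' mean +/- sd accuracy and AUC over another `n_iter` splits. The best
#' model from loop 2 is then applied to all samples to produce the
#' waterfall probability vector.
#'
#' Features are the DE sequences with unadjusted p < `alpha_p`; their
#' median-of-ratios normalized counts are log2(x+1)-transformed and
#' standardized per feature before the penalized fits (penalties are
#' scale-sensitive).
#'
#' @param x a [seq_counts] or raw count matrix, columns covering exactly
#'   the samples to classify.
#' @param group two-level factor; class 1 ("disease") is the second level.
#' @param de optional precomputed `de_result` for the same comparison;
#'   computed internally otherwise.
#' @param alpha elastic-net mixing parameter.
#' @param n_iter iterations per loop.
#' @param test_frac held-out fraction per split.
#' @param alpha_p feature-preselection threshold on unadjusted p.
#' @param min_count,min_frac expression-filter settings for the internal DE.
#' @param seed master seed; the three loops use derived sub-seeds.
#' @return object of class `elnet_model`; see [predict.elnet_model()],
#'   [project_new_samples()].
#' @export
elnet_classify <- function(x, group, de = NULL, alpha = 0.5, n_iter = 1000L,
                           test_frac = 0.2, alpha_p = 0.05,
                           min_count = 10, min_frac = 0.5, seed = 1L) {
  m <- count_matrix(x)
  group <- factor(group)
  stopifnot(nlevels(group) == 2, length(group) == ncol(m))
  sf <- size_factors(m)
  if (is.null(de))
    de <- nb_wald_de(m, group, min_count, min_frac, sf = sf)
  pool <- preselect_features(de, alpha_p)
  norm <- normalize_counts(m, sf)
  Xall <- t(log2(norm[pool, , drop = FALSE] + 1))
  center <- colMeans(Xall)
  scale_ <- apply(Xall, 2, sd)
  scale_[scale_ == 0] <- 1
  X <- scale(Xall, center = center, scale = scale_)
  y <- as.integer(group == levels(group)[2])

  tuned <- tune_lambda(X, y, alpha, n_iter, test_frac,
                       seed = substream_seed(seed, 11L))
  sel <- select_features(X, y, tuned$lambda, alpha, n_iter, test_frac,
                         seed = substream_seed(seed, 12L))
  perf <- if (length(sel$features)) {
    estimate_performance(X, y, tuned$lambda, sel$features, alpha, n_iter,
                         test_frac, seed = substream_seed(seed, 13L))
  } else NULL

  # Pseudo-reference for projecting samples the model has never seen:
  # median-of-ratios against the training cohort's gene-wise geometric means.
  ref_genes <- rowSums(m == 0) == 0
  log_geo <- rowMeans(log(m[ref_genes, , drop = FALSE]))

  obj <- structure(list(
    alpha = alpha, lambda = tuned$lambda,
    features = sel$features, beta = sel$beta, b0 = sel$b0,
    levels = levels(group), y = y,
    feature_pool = pool, center = center, scale = scale_,
    ref_log_geomean = log_geo,
    performance = perf,
    best_split_accuracy = sel$accuracy,
    tuning_best_accuracy = tuned$best_accuracy,
    training_samples = colnames(m)[sel$training],
    sample_ids = colnames(m),
    n_iter = n_iter, seed = seed,
    de = de), class = "elnet_model")
  prob <- predict(obj, m)
  wf <- data.frame(sample_id = colnames(m), group = as.character(group),
                   probability = prob, stringsAsFactors = FALSE)
  wf <- wf[order(wf$probability), , drop = FALSE]
  rownames(wf) <- NULL
  obj$waterfall <- wf
  obj$all_sample_accuracy <- mean((prob > 0.5) == y)
  obj
}

# Feature-space transform of a raw count matrix using the stored training
# normalization reference and standardization.
elnet_transform <- function(object, m) {
  need <- union(names(object$ref_log_geomean), object$feature_pool)
  missing <- setdiff(need, rownames(m))
  if (length(missing))
    stop("feature(s) absent from new data: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  ref <- object$ref_log_geomean
  sf <- apply(m[names(ref), , drop = FALSE], 2, function(cnt) {
    ok <- cnt > 0
    if (!any(ok)) stop("cannot normalize an all-zero sample")
    exp(median(log(cnt[ok]) - ref[ok]))
  })
  norm <- sweep(m[object$feature_pool, , drop = FALSE], 2, sf, "/")
  Xn <- t(log2(norm + 1))
  scale(Xn, center = object$center, scale = object$scale)
}

#' Predict class-1 probabilities from a fitted elastic-net model
#'
#' @param object an `elnet_model`.
#' @param newdata a [seq_counts] or raw count matrix (genes x samples)
#'   containing at least the model's feature genes; normalized against the
#'   training pseudo-reference.
#' @param type `"response"` for probabilities, `"class"` for labels at the
#'   0.5 cutoff.
#' @param ... unused.
#' @return named numeric (or character) vector, one entry per sample.
#' @export
predict.elnet_model <- function(object, newdata, type = c("response", "class"),
                                ...) {
  type <- match.arg(type)
  m <- count_matrix(newdata)
  Xs <- elnet_transform(object, m)
  eta <- if (length(object$features)) {
    object$b0 + as.vector(Xs[, object$features, drop = FALSE] %*% object$beta)
  } else rep(object$b0, ncol(m))
  prob <- setNames(plogis(eta), colnames(m))
  if (type == "class")
    setNames(object$levels[(prob > 0.5) + 1L], colnames(m))
  else prob
}

#' Project held-out (e.g. converter) samples onto a fitted model
#'
#' The model must have been trained without the projected samples; they are
#' normalized against the training pseudo-reference and assigned at the
#' 0.5 probability cutoff.
#'
#' @param model an `elnet_model`.
#' @param newdata counts for the new samples.
#' @return list with `projection` (data.frame `sample_id`, `probability`,
#'   `class`) and `assigned` (counts per class).
#' @export
project_new_samples <- function(model, newdata) {
  prob <- predict(model, newdata)
  cls <- model$levels[(prob > 0.5) + 1L]
  proj <- data.frame(sample_id = names(prob), probability = unname(prob),
                     class = cls, stringsAsFactors = FALSE)
  proj <- proj[order(proj$probability), , drop = FALSE]
  rownames(proj) <- NULL
  list(projection = proj,
       assigned = table(factor(cls, levels = model$levels)))
}

#' @export
print.elnet_model <- function(x, ...) {
  cat(sprintf("Elastic-net classifier: %s vs %s (alpha = %g, lambda = %.4g)\n",
              x$levels[1], x$levels[2], x$alpha, x$lambda))
  cat(sprintf("  %d features selected from a pool of %d DE sequences\n",
              length(x$features), length(x$feature_pool)))
  cat(sprintf("  best-split accuracy %.3f; all-sample accuracy %.3f\n",
              x$best_split_accuracy, x$all_sample_accuracy))
  if (!is.null(x$performance)) { cat("  held-out: "); print(x$performance) }
  invisible(x)
}

#' @export
summary.elnet_model <- function(object, ...) {
  print(object)
  if (length(object$beta)) {
    cat("  coefficients (standardized feature scale):\n")
    print(round(sort(object$beta), 4))
  }
  invisible(object)
}

#' @export
coef.elnet_model <- function(object, ...) {
  c("(Intercept)" = object$b0, object$beta)
}

#' Waterfall plot of per-sample model probabilities
#'
#' @param x an `elnet_model`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.elnet_model <- function(x, ...) {
  wf <- x$waterfall
  cols <- ifelse(wf$group == x$levels[2], "firebrick", "steelblue")
  graphics::barplot(wf$probability - 0.5, col = cols, border = NA,
                    names.arg = rep("", nrow(wf)), offset = 0.5,
                    ylim = c(0, 1),
                    ylab = sprintf("P(%s)", x$levels[2]),
                    main = "Model confidence by sample", ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::legend("topleft", fill = c("steelblue", "firebrick"),
                   legend = x$levels, bty = "n")
  invisible(x)
}
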