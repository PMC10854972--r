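#' Default run configuration
#'
#' Nested list of every pipeline threshold at its standard value, suitable
#' for editing or serializing to YAML. `comparisons` pairs are classified
#' and benchmarked; each converter group is projected onto the model whose
#' disease class matches its conversion target.
#'
#' @param seed master seed; each stage derives its own sub-seed.
#' @param outdir output directory (`NULL` = do not write files).
#' @return named list of class `run_config`.
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  structure(list(
    paths = list(counts = NULL, lookup = NULL, metadata = NULL,
                 outdir = outdir),
    design = list(),            # overrides for cohort_design()
    simulate_reads = FALSE,     # exercise FASTQ emission + re-counting
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    read = list(n_random = 4L, min_len = 15L, max_mismatch = 0L),
    qc = list(min_mapped = 1e6),
    de = list(min_count = 10, min_frac = 0.5, alpha = 0.05),
    elnet = list(alpha = 0.5, n_iter = 1000L, test_frac = 0.2,
                 alpha_p = 0.05),
    lrm = list(n_repeats = 100L, criterion = "padj"),
    trend = list(r2_min = 0.66, alpha = 0.05),
    curation = list(enabled = TRUE, part_cutoff = 0.5,
                    exclude_pathologies = c("FTD", "vascular")),
    comparisons = list(c("control", "AD"), c("control", "MCI"),
                       c("MCI", "AD")),
    seed = as.integer(seed)), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_in(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- merge_in(cfg, user)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Summarize differential-expression signatures by biotype
#'
#' Per comparison: how many sequences are significant at unadjusted
#' p < `alpha`, the percentage of the signature contributed by each
#' biotype, and the miRNA vs non-miRNA share.
#'
#' @param de_list named list of `de_result` objects.
#' @param annotation annotation with `gene_id` and `biotype`.
#' @param alpha unadjusted significance threshold.
#' @return data.frame, one row per comparison; percentage columns sum to
#'   100 (all zero, with `empty = TRUE`, for empty signatures).
#' @export
de_summary <- function(de_list, annotation, alpha = 0.05) {
  rows <- lapply(names(de_list), function(nm) {
    sig <- significant_genes(de_list[[nm]], alpha)
    bio <- factor(annotation$biotype[match(sig, annotation$gene_id)],
                  levels = BIOTYPES)
    pct <- if (length(sig)) 100 * as.vector(table(bio)) / length(sig)
           else rep(0, length(BIOTYPES))
    names(pct) <- paste0("pct_", BIOTYPES)
    c(list(comparison = nm, n_significant = length(sig)), as.list(pct),
      list(pct_miRNA_total = pct[["pct_miRNA"]],
           pct_non_miRNA = if (length(sig)) 100 - pct[["pct_miRNA"]] else 0,
           empty = length(sig) == 0))
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}

stage_msg <- function(quiet, ...) if (!quiet) message("[evsmallrna] ", ...)

#' Run the full workflow
#'
#' Orchestrates the pipeline in dependency order: obtain counts (load a
#' TSV, or simulate a cohort — optionally routing the simulated reads
#' through FASTQ emission and re-counting), sample QC, cohort curation
#' (PART model on confirmed controls, flagging, rule application),
#' per-comparison differential expression, elastic-net classification with
#' converter projection, the logistic-regression benchmark, the
#' time-to-conversion regression, and a biotype DE summary. Identical
#' config and seed give an identical report.
#'
#' @param config a `run_config` (see [default_config()],
#'   [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return a `run_report`: nested list of per-stage summaries plus the
#'   fitted objects (`$objects`). Written as JSON (without the objects) to
#'   `outdir` when configured.
#' @export
run_all <- function(config = default_config(), quiet = FALSE) {
  cfg <- config
  t0 <- proc.time()[["elapsed"]]
  report <- list(package_version = as.character(utils::packageVersion("evsmallrna")),
                 config = cfg[setdiff(names(cfg), "design")],
                 stages = list())
  objects <- list()

  ## ---- counts ----
  if (!is.null(cfg$paths$counts)) {
    stage_msg(quiet, "loading counts from ", cfg$paths$counts)
    counts <- read_counts_tsv(cfg$paths$counts,
                              cfg$paths$lookup %||%
                                sub("(\\.tsv)?$", ".lookup.tsv",
                                    cfg$paths$counts))
    metadata <- read_table_tsv(cfg$paths$metadata)
    truth <- NULL
    report$stages$input <- list(source = "files", skipped_read_processing = TRUE)
  } else {
    stage_msg(quiet, "simulating cohort")
    design <- do.call(cohort_design,
                      c(cfg$design, list(seed = substream_seed(cfg$seed, 1L))))
    sim <- simulate_cohort(design)
    counts <- sim$counts; metadata <- sim$metadata; truth <- sim$truth
    if (isTRUE(cfg$simulate_reads)) {
      stage_msg(quiet, "emitting FASTQ and re-counting")
      fq_dir <- file.path(cfg$paths$outdir %||% tempdir(), "fastq")
      fq <- simulate_reads(counts, cfg$adapter, fq_dir,
                           n_random = cfg$read$n_random,
                           seed = substream_seed(cfg$seed, 2L))
      cs <- count_smallrna(fq, sim$reference, cfg$adapter,
                           n_random = cfg$read$n_random,
                           min_len = cfg$read$min_len,
                           max_mismatch = cfg$read$max_mismatch,
                           min_mapped = 0)
      counts <- cs$counts
      report$stages$read_processing <-
        list(n_reads = sum(cs$qc$total), n_retained = sum(cs$qc$retained))
    }
    report$stages$input <- list(source = "simulation",
                                n_sequences = nrow(counts$counts),
                                n_samples = ncol(counts$counts))
  }

  ## ---- sample QC ----
  qc <- qc_filter_samples(counts, cfg$qc$min_mapped)
  counts <- qc$kept
  metadata <- metadata[metadata$sample_id %in% colnames(counts$counts), ,
                       drop = FALSE]
  report$stages$sample_qc <- list(min_mapped = cfg$qc$min_mapped,
                                  n_excluded = length(qc$excluded),
                                  excluded = qc$excluded)

  md_ev <- if ("fraction" %in% names(metadata))
    metadata[metadata$fraction == "EV", , drop = FALSE] else metadata
  ev_counts <- count_matrix(counts)[, md_ev$sample_id, drop = FALSE]

  ## ---- curation ----
  flagged <- character(0)
  if (isTRUE(cfg$curation$enabled)) {
    stage_msg(quiet, "curating cohort (PART model)")
    part_model <- tryCatch(
      build_part_model(ev_counts, md_ev, alpha = cfg$elnet$alpha,
                       n_iter = cfg$elnet$n_iter,
                       test_frac = cfg$elnet$test_frac,
                       alpha_p = cfg$elnet$alpha_p,
                       seed = substream_seed(cfg$seed, 3L)),
      error = function(e) e)
    if (inherits(part_model, "error")) {
      report$stages$curation <- list(part_model = "unavailable",
                                     note = conditionMessage(part_model))
    } else {
      unknown <- md_ev$sample_id[md_ev$dx_at_draw == "control" &
                                   md_ev$postmortem_dx == "unknown" &
                                   md_ev$converts_to == "none"]
      flagged <- flag_suspected_part(part_model,
                                     ev_counts[, unknown, drop = FALSE],
                                     cfg$curation$part_cutoff)
      objects$part_model <- part_model
      report$stages$curation <-
        list(part_model = list(n_features = length(part_model$features),
                               best_split_accuracy = part_model$best_split_accuracy,
                               all_sample_accuracy = part_model$all_sample_accuracy),
             n_flagged_suspected_part = length(flagged))
    }
  }
  groups <- apply_curation_rules(md_ev, flagged,
                                 cfg$curation$exclude_pathologies)
  objects$groups <- groups
  report$stages$curation$group_sizes <-
    as.list(table(factor(groups$final_group, levels = c(GROUPS, "excluded"))))
  report$stages$curation$exclusions_by_reason <-
    as.list(table(groups$exclusion_reason[groups$exclusion_reason != "none"]))

  grp_of <- setNames(groups$final_group, groups$sample_id)
  samples_in <- function(g) names(grp_of)[grp_of == g]

  ## ---- DE + classification per comparison ----
  target_of <- c(C_to_MCI = "MCI", C_to_AD = "AD", MCI_to_AD = "AD")
  origin_of <- c(C_to_MCI = "control", C_to_AD = "control", MCI_to_AD = "MCI")
  de_list <- list(); elnet_list <- list(); lrm_list <- list()
  projections <- list()
  for (cmp in cfg$comparisons) {
    nm <- paste(cmp[2], "vs", cmp[1])
    ids <- c(samples_in(cmp[1]), samples_in(cmp[2]))
    if (length(samples_in(cmp[1])) < 2 || length(samples_in(cmp[2])) < 2) {
      report$stages$comparisons[[nm]] <- list(skipped = "group too small")
      next
    }
    stage_msg(quiet, "comparison ", nm)
    sub <- ev_counts[, ids, drop = FALSE]
    grp <- factor(grp_of[ids], levels = cmp)
    de <- nb_wald_de(sub, grp, cfg$de$min_count, cfg$de$min_frac)
    de_list[[nm]] <- de
    cls <- tryCatch(
      elnet_classify(sub, grp, de = de, alpha = cfg$elnet$alpha,
                     n_iter = cfg$elnet$n_iter,
                     test_frac = cfg$elnet$test_frac,
                     alpha_p = cfg$elnet$alpha_p,
                     seed = substream_seed(cfg$seed, 10L)),
      error = function(e) e)
    cmp_report <- list(
      n_significant_p = length(significant_genes(de, cfg$de$alpha)),
      n_significant_padj = sum(de$padj < cfg$de$alpha, na.rm = TRUE))
    if (!inherits(cls, "error")) {
      elnet_list[[nm]] <- cls
      cmp_report$elnet <- list(
        n_features = length(cls$features), lambda = cls$lambda,
        mean_accuracy = cls$performance$mean_accuracy,
        sd_accuracy = cls$performance$sd_accuracy,
        mean_auc = cls$performance$mean_auc,
        sd_auc = cls$performance$sd_auc,
        all_sample_accuracy = cls$all_sample_accuracy)
      ## project converters whose origin/target match this comparison
      for (cg in names(target_of)) {
        if (origin_of[[cg]] == cmp[1] && target_of[[cg]] == cmp[2]) {
          conv_ids <- samples_in(cg)
          if (length(conv_ids)) {
            proj <- project_new_samples(cls, ev_counts[, conv_ids, drop = FALSE])
            projections[[cg]] <- proj
            cmp_report$converters[[cg]] <- list(
              n = length(conv_ids),
              n_assigned_disease = unname(proj$assigned[cmp[2]]),
              mean_probability = mean(proj$projection$probability))
          }
        }
      }
      ## logistic-regression benchmark on the top-10 genes
      top <- select_top10(de, by = cfg$lrm$criterion)
      Xn <- t(normalize_counts(sub)[top, , drop = FALSE])
      lrm <- fit_evaluate_lrm(Xn, grp, n_repeats = cfg$lrm$n_repeats,
                              seed = substream_seed(cfg$seed, 20L))
      lrm_list[[nm]] <- lrm
      cmp_report$lrm <- list(mean_accuracy = lrm$mean_accuracy,
                             sd_accuracy = lrm$sd_accuracy,
                             mean_auc = lrm$mean_auc, sd_auc = lrm$sd_auc)
    } else {
      cmp_report$elnet <- list(skipped = conditionMessage(cls))
    }
    report$stages$comparisons[[nm]] <- cmp_report
  }

  ## ---- time-to-conversion regression ----
  trend_list <- list()
  for (cg in names(target_of)) {
    ids <- samples_in(cg)
    md_c <- md_ev[match(ids, md_ev$sample_id), , drop = FALSE]
    ok <- md_c$years_to_conversion > 0
    if (sum(ok) >= 3) {
      norm_all <- normalize_counts(ev_counts)
      tr <- time_to_conversion_regression(norm_all[, ids[ok], drop = FALSE],
                                          md_c$years_to_conversion[ok],
                                          cfg$trend$r2_min, cfg$trend$alpha)
      trend_list[[cg]] <- tr
      report$stages$trend[[cg]] <- list(n_converters = sum(ok),
                                        n_flagged = sum(tr$flagged))
    }
  }

  ## ---- DE biotype summary ----
  if (length(de_list)) {
    dsum <- de_summary(de_list, counts$annotation, cfg$de$alpha)
    report$stages$de_summary <- dsum
  }

  report$elapsed_seconds <- round(proc.time()[["elapsed"]] - t0, 2)
  objects$counts <- counts; objects$metadata <- metadata
  objects$de <- de_list; objects$elnet <- elnet_list
  objects$lrm <- lrm_list; objects$trend <- trend_list
  objects$projections <- projections
  if (!is.null(truth)) objects$truth <- truth

  ## ---- outputs ----
  if (!is.null(cfg$paths$outdir)) {
    out <- cfg$paths$outdir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_counts_tsv(counts, file.path(out, "counts.tsv"))
    write_table_tsv(metadata, file.path(out, "metadata.tsv"))
    write_table_tsv(groups, file.path(out, "curated_groups.tsv"))
    for (nm in names(de_list))
      write_table_tsv(de_list[[nm]],
                      file.path(out, paste0("de_", gsub(" ", "_", nm), ".tsv")))
    for (nm in names(elnet_list)) {
      wf <- elnet_list[[nm]]$waterfall
      write_table_tsv(wf, file.path(out, paste0("waterfall_",
                                                gsub(" ", "_", nm), ".tsv")))
    }
    for (cg in names(trend_list))
      write_table_tsv(trend_list[[cg]],
                      file.path(out, paste0("trend_", cg, ".tsv")))
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  structure(c(report, list(objects = objects)), class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("evsmallrna run report (", x$elapsed_seconds, "s )\n", sep = "")
  for (nm in names(x$stages$comparisons)) {
    s <- x$stages$comparisons[[nm]]
    if (!is.null(s$skipped)) { cat("  ", nm, ": skipped\n"); next }
    cat(sprintf("  %s: %d DE (p), %d (padj)", nm,
                s$n_significant_p, s$n_significant_padj))
    if (!is.null(s$elnet$mean_accuracy))
      cat(sprintf("; ELNET acc %.2f, AUC %.2f", s$elnet$mean_accuracy,
                  s$elnet$mean_auc))
    if (!is.null(s$lrm))
      cat(sprintf("; LRM acc %.2f, AUC %.2f", s$lrm$mean_accuracy,
                  s$lrm$mean_auc))
    cat("\n")
  }
  for (cg in names(x$stages$trend))
    cat(sprintf("  trend %s: %d flagged gene(s)\n", cg,
                x$stages$trend[[cg]]$n_flagged))
  invisible(x)
}
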