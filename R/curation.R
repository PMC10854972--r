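#' Elastic-net model separating normal ageing from PART in confirmed controls
#'
#' Builds the full three-loop elastic-net classifier on clinically normal
#' controls whose autopsy confirmed either normal age-related pathology or
#' primary age-related tauopathy (PART). The resulting model is used to
#' screen controls without autopsy data for a PART-like plasma signature.
#'
#' @param x a [seq_counts] or count matrix covering (at least) the control
#'   samples.
#' @param metadata sample metadata with `sample_id`, `dx_at_draw`,
#'   `postmortem_dx` (and `fraction`, only EV samples are used if present).
#' @param ... passed to [elnet_classify()] (`alpha`, `n_iter`, `seed`, ...).
#' @return an `elnet_model` with levels `normal` (class 0) and `PART`
#'   (class 1).
#' @export
build_part_model <- function(x, metadata, ...) {
  m <- count_matrix(x)
  md <- metadata
  if ("fraction" %in% names(md)) md <- md[md$fraction == "EV", , drop = FALSE]
  md <- md[md$dx_at_draw == "control" &
             md$postmortem_dx %in% c("normal", "PART"), , drop = FALSE]
  tab <- table(factor(md$postmortem_dx, levels = c("normal", "PART")))
  if (any(tab < 2))
    stop("need at least 2 confirmed controls in each pathology class ",
         "(normal: ", tab[["normal"]], ", PART: ", tab[["PART"]], ")")
  sub <- m[, md$sample_id, drop = FALSE]
  grp <- factor(md$postmortem_dx, levels = c("normal", "PART"))
  elnet_classify(sub, grp, ...)
}

#' Flag controls whose plasma signature resembles PART
#'
#' Controls without autopsy data are projected onto the PART model; those
#' with PART-class probability at or above the cutoff ("50% or greater
#' confidence") are flagged for exclusion from the clean control group.
#'
#' @param model the [build_part_model()] fit.
#' @param x counts for the unknown-pathology controls (a [seq_counts] or
#'   matrix; an empty set of samples yields an empty flag list).
#' @param cutoff flagging threshold on the PART probability (inclusive).
#' @return character vector of flagged sample IDs.
#' @export
flag_suspected_part <- function(model, x, cutoff = 0.5) {
  m <- count_matrix(x)
  if (ncol(m) == 0) return(character(0))
  prob <- predict(model, m)
  names(prob)[prob >= cutoff]
}

#' Reconcile clinical diagnosis, pathology and conversion into final groups
#'
#' Applies the curation rules in a fixed order: (1) non-converter controls
#' with postmortem AD pathology are excluded; (2) controls with confirmed
#' PART are excluded from disease comparisons; (3) controls flagged by the
#' PART model are excluded; (4) clinically MCI samples with a postmortem or
#' subsequent DLB diagnosis are excluded; (5) non-converter MCI/AD samples
#' whose primary pathology is on the configurable exclusion list are
#' excluded; (6) converters are assigned to `C_to_MCI` / `C_to_AD` /
#' `MCI_to_AD`; (7) everyone else keeps the diagnosis at draw. Pathology
#' rules 1-3 apply to non-converters only: a control whose clinical course
#' progressed to the pathology's disease is concordant, not confounded.
#'
#' @param metadata data.frame with `sample_id`, `dx_at_draw`,
#'   `postmortem_dx`, `converts_to` (and optionally `fraction`; rules apply
#'   per sample regardless of fraction).
#' @param flagged sample IDs flagged by [flag_suspected_part()].
#' @param exclude_pathologies primary pathologies that disqualify
#'   non-converter MCI/AD samples.
#' @return data.frame of class `curated_groups`: `sample_id`,
#'   `final_group` (a group name or `"excluded"`), `exclusion_reason`
#'   (`pathology_AD_in_control`, `confirmed_PART`, `predicted_PART`,
#'   `DLB_in_MCI`, `other`, `none`).
#' @export
apply_curation_rules <- function(metadata, flagged = character(0),
                                 exclude_pathologies = c("FTD", "vascular")) {
  md <- metadata
  need <- c("sample_id", "dx_at_draw", "postmortem_dx", "converts_to")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  conv <- md$converts_to != "none"
  bad <- which(conv & !(paste(md$dx_at_draw, md$converts_to) %in%
                          c("control MCI", "control AD", "MCI AD")))
  if (length(bad))
    stop("contradictory conversion metadata for sample(s): ",
         paste(md$sample_id[bad], collapse = ", "))

  group <- md$dx_at_draw
  reason <- rep("none", nrow(md))
  excl <- function(i, why) {
    hit <- i & reason == "none"
    group[hit] <<- "excluded"
    reason[hit] <<- why
  }
  ctrl_nc <- md$dx_at_draw == "control" & !conv
  excl(ctrl_nc & md$postmortem_dx == "AD", "pathology_AD_in_control")
  excl(ctrl_nc & md$postmortem_dx == "PART", "confirmed_PART")
  excl(ctrl_nc & md$sample_id %in% flagged, "predicted_PART")
  excl(md$dx_at_draw == "MCI" & md$postmortem_dx == "DLB", "DLB_in_MCI")
  excl(md$dx_at_draw %in% c("MCI", "AD") & !conv &
         md$postmortem_dx %in% exclude_pathologies, "other")
  still <- group != "excluded"
  group[still & conv & md$dx_at_draw == "control" & md$converts_to == "MCI"] <-
    "C_to_MCI"
  group[still & conv & md$dx_at_draw == "control" & md$converts_to == "AD"] <-
    "C_to_AD"
  group[still & conv & md$dx_at_draw == "MCI"] <- "MCI_to_AD"

  out <- data.frame(sample_id = md$sample_id, final_group = group,
                    exclusion_reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("curated_groups", "data.frame")
  out
}

#' @export
print.curated_groups <- function(x, ...) {
  cat("Curated groups:\n")
  print(table(factor(x$final_group, levels = c(GROUPS, "excluded"))))
  ex <- x$exclusion_reason[x$exclusion_reason != "none"]
  if (length(ex)) {
    cat("Exclusions by reason:\n")
    print(table(ex))
  }
  invisible(x)
}

#' ApoE genotype by group cross-tabulation
#'
#' A descriptive contingency table of ApoE genotype against the final
#' analysis group (no inference).
#'
#' @param metadata sample metadata with `sample_id` and `apoe`.
#' @param groups a `curated_groups` table; when omitted, `dx_at_draw` is
#'   used as the grouping.
#' @return a contingency table, genotypes x groups.
#' @export
apoe_crosstab <- function(metadata, groups = NULL) {
  g <- if (is.null(groups)) metadata$dx_at_draw else
    groups$final_group[match(metadata$sample_id, groups$sample_id)]
  table(apoe = metadata$apoe, group = g)
}
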