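#' Design of a synthetic plasma EV small-RNA cohort
#'
#' Collects every knob of the synthetic data generator in one validated
#' object. Defaults emulate the structure of a memory-clinic plasma EV
#' cohort: control / MCI / AD groups plus three converter groups (controls
#' or MCI patients whose diagnosis progressed after the blood draw),
#' negative-binomial counts with log-normal abundance skew and library-size
#' variation, isomiR families, partially shared disease signatures, an
#' EV-depleted fraction with fewer detected sequences and inflated
#' per-gene variability, and a latent postmortem pathology label that only
#' imperfectly matches the clinical diagnosis.
#'
#' @param n_per_group named integer vector of samples per group; names from
#'   `control, MCI, AD, C_to_MCI, C_to_AD, MCI_to_AD`.
#' @param n_genes_per_biotype named integer vector of canonical genes per
#'   biotype (`miRNA, YRNA, tRNA, piRNA, protein_coding, other`).
#' @param isomir_family_sizes,isomir_family_probs possible isomiR family
#'   sizes (sequences per canonical gene) and their sampling probabilities.
#' @param library_size_mean expected total annotated reads per sample.
#' @param library_size_sdlog log-normal sd of the per-sample library factor.
#' @param abundance_sdlog log-normal sd of per-sequence baseline abundance
#'   (larger = a few dominant transcripts, as in plasma).
#' @param phi negative-binomial dispersion (Var = mu + phi * mu^2); scalar
#'   or per-sequence vector.
#' @param planted_effects list of effects, each a list with elements
#'   `genes` (canonical gene names or sequence row indices), `group`
#'   (a clinical group, or `"PART"` for a pathology-driven effect in
#'   controls with PART at autopsy), and `log2FC`.
#' @param converter_effect_scale fraction in \[0, 1\] of the full disease
#'   effect expressed in converter samples (0 = indistinguishable from their
#'   group at draw, 1 = full future-disease signature).
#' @param trend_genes optional data.frame with columns `gene` (canonical
#'   name or row index) and `slope` (normalized counts per year): in
#'   converter samples the expected normalized expression changes linearly
#'   along the time axis x = -years_to_conversion.
#' @param depleted_prob probability that a subject also contributes an
#'   EV-depleted fraction sample.
#' @param depleted_cv_inflation multiplicative inflation (> 1) of the
#'   per-gene coefficient of variation in the depleted fraction.
#' @param depleted_dropout_rate fraction of sequences absent (zero counts)
#'   from the depleted fraction.
#' @param pathology_probs named list, group -> named probability vector over
#'   postmortem pathologies (`normal, PART, AD, DLB, FTD, vascular,
#'   unknown`); controls the latent-pathology mislabelling.
#' @param seed integer master seed; independent sub-streams are derived for
#'   the reference, metadata, counts and reads so each artifact can be
#'   regenerated in isolation.
#' @return An object of class `cohort_design` (a validated list).
#' @export
cohort_design <- function(n_per_group = c(control = 40, MCI = 18, AD = 35,
                                          C_to_MCI = 9, C_to_AD = 6, MCI_to_AD = 6),
                          n_genes_per_biotype = c(miRNA = 150, YRNA = 30,
                                                  tRNA = 40, piRNA = 30,
                                                  protein_coding = 30, other = 20),
                          isomir_family_sizes = 1:4,
                          isomir_family_probs = c(0.45, 0.30, 0.15, 0.10),
                          library_size_mean = 2e6,
                          library_size_sdlog = 0.25,
                          abundance_sdlog = 1.5,
                          phi = 0.2,
                          planted_effects = list(),
                          converter_effect_scale = 0.5,
                          trend_genes = NULL,
                          depleted_prob = 0.4,
                          depleted_cv_inflation = 2,
                          depleted_dropout_rate = 0.3,
                          pathology_probs = default_pathology_probs(),
                          seed = 1L) {
  if (length(n_per_group) == 0 || is.null(names(n_per_group)))
    stop("n_per_group must be a named vector")
  if (!all(names(n_per_group) %in% GROUPS))
    stop("unknown group(s): ",
         paste(setdiff(names(n_per_group), GROUPS), collapse = ", "))
  if (any(n_per_group <= 0)) stop("all group sizes must be positive")
  if (!all(names(n_genes_per_biotype) %in% BIOTYPES) ||
      any(n_genes_per_biotype <= 0))
    stop("n_genes_per_biotype must be positive and named by biotype")
  if (converter_effect_scale < 0 || converter_effect_scale > 1)
    stop("converter_effect_scale must lie in [0, 1]")
  if (depleted_cv_inflation < 1) stop("depleted_cv_inflation must be >= 1")
  stopifnot(depleted_prob >= 0, depleted_prob <= 1,
            depleted_dropout_rate >= 0, depleted_dropout_rate <= 1,
            library_size_mean > 0, all(phi >= 0))
  for (eff in planted_effects) {
    stopifnot(all(c("genes", "group", "log2FC") %in% names(eff)))
    if (!eff$group %in% c(GROUPS, "PART"))
      stop("planted effect group must be a clinical group or 'PART'")
  }
  structure(list(n_per_group = n_per_group,
                 n_genes_per_biotype = n_genes_per_biotype,
                 isomir_family_sizes = isomir_family_sizes,
                 isomir_family_probs = isomir_family_probs,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 abundance_sdlog = abundance_sdlog,
                 phi = phi,
                 planted_effects = planted_effects,
                 converter_effect_scale = converter_effect_scale,
                 trend_genes = trend_genes,
                 depleted_prob = depleted_prob,
                 depleted_cv_inflation = depleted_cv_inflation,
                 depleted_dropout_rate = depleted_dropout_rate,
                 pathology_probs = pathology_probs,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

default_pathology_probs <- function() {
  list(
    control   = c(normal = 0.15, PART = 0.11, AD = 0.11, unknown = 0.63),
    MCI       = c(AD = 0.15, PART = 0.05, DLB = 0.15, FTD = 0.05,
                  vascular = 0.05, unknown = 0.55),
    AD        = c(AD = 0.45, DLB = 0.05, FTD = 0.05, vascular = 0.05,
                  unknown = 0.40),
    C_to_MCI  = c(AD = 0.20, unknown = 0.80),
    C_to_AD   = c(AD = 0.50, unknown = 0.50),
    MCI_to_AD = c(AD = 0.50, unknown = 0.50)
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("cohort_design:",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
            collapse = " "), "\n")
  cat(sprintf("  %d canonical genes over %d biotypes; seed %d\n",
              sum(x$n_genes_per_biotype), length(x$n_genes_per_biotype),
              x$seed))
  invisible(x)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# One point mutation or one-nucleotide 3' extension/trim of a sequence.
mutate_seq <- function(s) {
  n <- nchar(s)
  op <- sample(3L, 1L)
  if (op == 1L && n > 16L) return(substr(s, 1L, n - 1L))
  if (op == 2L && n < 44L) return(paste0(s, sample(c("A", "C", "G", "T"), 1L)))
  pos <- sample(n, 1L)
  old <- substr(s, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(s, 1L, pos - 1L), new, substr(s, pos + 1L, n))
}

#' Simulate an annotated small-RNA sequence reference
#'
#' Generates unique sequences (15-45 nt) grouped into isomiR families: all
#' members of a family share a canonical gene and differ from each other by
#' at least one nucleotide (substitution or 3' length variant), mimicking
#' the sequence-level feature space of a by-sequence analysis.
#'
#' @param design a [cohort_design()].
#' @return data.frame of class `annotated_reference` with columns
#'   `sequence`, `canonical_gene`, `biotype`.
#' @export
simulate_reference <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(substream_seed(design$seed, 0L))
  prefix <- c(miRNA = "miR", YRNA = "RNY", tRNA = "tRNA", piRNA = "piR",
              protein_coding = "PCG", other = "MISC")
  seen <- new.env(hash = TRUE)
  rows <- vector("list", 0L)
  for (b in names(design$n_genes_per_biotype)) {
    for (g in seq_len(design$n_genes_per_biotype[[b]])) {
      gene <- paste0(prefix[[b]], "-", g)
      fam <- if (length(design$isomir_family_sizes) == 1L)
        design$isomir_family_sizes
      else sample(design$isomir_family_sizes, 1L,
                  prob = design$isomir_family_probs)
      base <- NULL
      for (k in seq_len(fam)) {
        ok <- FALSE
        for (try in 1:200) {
          s <- if (k == 1L) random_seq(sample(18:26, 1L)) else mutate_seq(base)
          if (is.null(seen[[s]])) { ok <- TRUE; break }
        }
        if (!ok) stop("could not generate a unique sequence for ", gene,
                      " after 200 attempts")
        seen[[s]] <- TRUE
        if (k == 1L) base <- s
        rows[[length(rows) + 1L]] <- list(sequence = s, canonical_gene = gene,
                                          biotype = b)
      }
    }
  }
  ref <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  class(ref) <- c("annotated_reference", "data.frame")
  ref
}

# Resolve planted-effect / trend gene references (canonical names or row
# indices) to reference row indices.
resolve_genes <- function(genes, reference) {
  if (is.numeric(genes)) {
    idx <- as.integer(genes)
    if (any(idx < 1L | idx > nrow(reference))) stop("gene index out of range")
    return(idx)
  }
  idx <- which(reference$canonical_gene %in% genes)
  missing <- setdiff(genes, reference$canonical_gene)
  if (length(missing)) stop("unknown canonical gene(s): ",
                            paste(missing, collapse = ", "))
  idx
}

rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  x <- round(rnorm(n, mean, sd))
  pmin(hi, pmax(lo, x))
}

simulate_metadata <- function(design) {
  set.seed(substream_seed(design$seed, 1L))
  groups <- rep(names(design$n_per_group), design$n_per_group)
  n <- length(groups)
  id <- sprintf("S%03d", seq_len(n))
  dx <- ifelse(groups %in% c("control", "C_to_MCI", "C_to_AD"), "control",
               ifelse(groups %in% c("MCI", "MCI_to_AD"), "MCI", "AD"))
  converts <- ifelse(groups == "C_to_MCI", "MCI",
                     ifelse(groups %in% c("C_to_AD", "MCI_to_AD"), "AD", "none"))
  # Years from blood draw to the later diagnosis: AD converters span a wide
  # preclinical window, MCI-to-AD converters progress within 1-2 years.
  years <- numeric(n)
  years[groups == "C_to_AD"] <- round(runif(sum(groups == "C_to_AD"), 2, 12), 1)
  years[groups == "C_to_MCI"] <- round(runif(sum(groups == "C_to_MCI"), 2, 9), 1)
  years[groups == "MCI_to_AD"] <- round(runif(sum(groups == "MCI_to_AD"), 1, 2), 1)
  path <- character(n)
  for (g in unique(groups)) {
    p <- design$pathology_probs[[g]]
    if (is.null(p)) p <- c(unknown = 1)
    i <- which(groups == g)
    path[i] <- sample(names(p), length(i), replace = TRUE, prob = p)
  }
  # Cognitive scores: group-conditional normals truncated to the valid
  # ranges, centred on published separations (DRS 136 control/impaired,
  # 124 MCI/AD; MMSE mild 20-26, moderate 10-19).
  drs_mean <- c(control = 140, MCI = 130, AD = 112)[dx]
  drs_sd <- c(control = 3, MCI = 4, AD = 8)[dx]
  mmse_mean <- c(control = 29, MCI = 24, AD = 17)[dx]
  mmse_sd <- c(control = 1, MCI = 2, AD = 4)[dx]
  drs <- rtruncnorm_int(n, drs_mean, drs_sd, 0, 144)
  mmse <- rtruncnorm_int(n, mmse_mean, mmse_sd, 0, 30)
  apoe_freq <- list(
    control = c("E2/E3" = 0.15, "E3/E3" = 0.62, "E3/E4" = 0.18, "E4/E4" = 0.05),
    MCI     = c("E2/E3" = 0.10, "E3/E3" = 0.55, "E3/E4" = 0.28, "E4/E4" = 0.07),
    AD      = c("E2/E3" = 0.06, "E3/E3" = 0.44, "E3/E4" = 0.38, "E4/E4" = 0.12))
  apoe_group <- ifelse(groups == "control", "control",
                       ifelse(groups %in% c("MCI", "C_to_MCI"), "MCI", "AD"))
  apoe <- vapply(apoe_group, function(g) {
    f <- apoe_freq[[g]]
    sample(names(f), 1L, prob = f)
  }, character(1))
  md <- data.frame(sample_id = id, fraction = "EV", group = groups,
                   dx_at_draw = dx, postmortem_dx = path,
                   converts_to = converts, years_to_conversion = years,
                   DRS = drs, MMSE = mmse, apoe = apoe,
                   sex = sample(c("F", "M"), n, replace = TRUE),
                   age = rtruncnorm_int(n, 74, 6, 55, 95),
                   stringsAsFactors = FALSE)
  dep <- runif(n) < design$depleted_prob
  if (any(dep)) {
    md_dep <- md[dep, , drop = FALSE]
    md_dep$fraction <- "depleted"
    md_dep$sample_id <- paste0(md_dep$sample_id, "_dep")
    md <- rbind(md, md_dep)
  }
  rownames(md) <- NULL
  md
}

#' Simulate a synthetic cohort: sample metadata plus sequence-level counts
#'
#' Counts follow a negative binomial with Var = mu + phi * mu^2. The
#' expected count of sequence i in sample j is
#' `baseline_i * libfactor_j * 2^(effect_ij)` where the planted log2
#' fold-change effect depends on the sample's group: converter samples
#' express `converter_effect_scale` times the effect of their future
#' diagnosis (on top of their group-at-draw signature), and trend genes add
#' a linear term `slope * (-years_to_conversion)` on the normalized scale.
#' Depleted-fraction samples have a planted random subset of sequences
#' dropped to zero and their dispersion inflated so the per-gene coefficient
#' of variation is multiplied by `depleted_cv_inflation`.
#'
#' Each artifact (reference, metadata, counts) uses its own RNG sub-stream,
#' and each sample's counts are drawn under a per-sample seed, so
#' non-converter columns are identical across designs that differ only in
#' `converter_effect_scale`.
#'
#' @param design a [cohort_design()].
#' @param reference an `annotated_reference`; simulated from the design if
#'   omitted.
#' @return list with elements `metadata` (data.frame), `counts`
#'   ([seq_counts]), `reference`, and `truth` (per-sequence baseline means,
#'   planted per-group log2FC matrix, trend slopes, depleted dropout set).
#' @export
simulate_cohort <- function(design, reference = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(reference)) reference <- simulate_reference(design)
  md <- simulate_metadata(design)
  n_seq <- nrow(reference)
  n_smp <- nrow(md)

  set.seed(substream_seed(design$seed, 2L))
  w <- stats::rlnorm(n_seq, 0, design$abundance_sdlog)
  baseline <- w / sum(w) * design$library_size_mean
  libfac <- stats::rlnorm(n_smp, 0, design$library_size_sdlog)
  dropout <- runif(n_seq) < design$depleted_dropout_rate

  # Planted per-group log2FC matrix (sequences x groups, plus PART column).
  eff_cols <- c(GROUPS, "PART")
  lfc <- matrix(0, n_seq, length(eff_cols), dimnames = list(NULL, eff_cols))
  for (eff in design$planted_effects) {
    idx <- resolve_genes(eff$genes, reference)
    lfc[idx, eff$group] <- lfc[idx, eff$group] + eff$log2FC
  }
  # Effective effect per sample: origin-group effect plus a scaled step
  # toward the conversion target's effect.
  origin <- c(control = "control", MCI = "MCI", AD = "AD",
              C_to_MCI = "control", C_to_AD = "control", MCI_to_AD = "MCI")
  target <- c(C_to_MCI = "MCI", C_to_AD = "AD", MCI_to_AD = "AD")

  slopes <- numeric(n_seq)
  if (!is.null(design$trend_genes)) {
    idx <- resolve_genes(design$trend_genes$gene, reference)
    slopes[idx] <- design$trend_genes$slope
  }

  phi_ev <- rep_len(design$phi, n_seq)
  counts <- matrix(0L, n_seq, n_smp)
  for (j in seq_len(n_smp)) {
    g <- md$group[j]
    e <- lfc[, origin[[g]]]
    if (g %in% names(target))
      e <- e + design$converter_effect_scale * (lfc[, target[[g]]] - e)
    if (md$postmortem_dx[j] == "PART") e <- e + lfc[, "PART"]
    mu <- baseline * 2^e
    if (md$converts_to[j] != "none")
      mu <- pmax(mu + slopes * (-md$years_to_conversion[j]), 0.01)
    mu <- mu * libfac[j]
    phi <- phi_ev
    if (md$fraction[j] == "depleted") {
      cc <- design$depleted_cv_inflation^2
      phi <- cc * phi_ev + (cc - 1) / pmax(mu, 1e-8)
    }
    set.seed(substream_seed(substream_seed(design$seed, 2L), 100L + j))
    x <- rnbinom(n_seq, mu = mu, size = 1 / pmax(phi, 1e-12))
    if (md$fraction[j] == "depleted") x[dropout] <- 0L
    counts[, j] <- x
  }
  colnames(counts) <- md$sample_id
  # Sequences never observed in any sample are unobservable downstream, so
  # they are dropped here too: the matrix round-trips through read counting.
  obs <- rowSums(counts) > 0L
  counts <- counts[obs, , drop = FALSE]
  sc <- build_seq_counts(counts, reference$sequence[obs], reference)
  # Map truth onto the realized gene IDs.
  m <- match(sc$annotation$sequence, reference$sequence)
  truth <- list(baseline = baseline[m],
                lfc = lfc[m, , drop = FALSE],
                trend_slope = slopes[m],
                depleted_dropout = dropout[m])
  rownames(truth$lfc) <- rownames(sc$counts)
  names(truth$baseline) <- names(truth$trend_slope) <-
    names(truth$depleted_dropout) <- rownames(sc$counts)
  list(metadata = md, counts = sc, reference = reference, truth = truth)
}

#' Emit synthetic FASTQ reads for a count matrix
#'
#' Each count unit becomes one read laid out as the NEXTFLEX-style library
#' structure the trimmer expects: 4 random nucleotides, the insert sequence,
#' 4 random nucleotides, then the 3' adapter (optionally padded with random
#' filler to a fixed read length). Optionally plants `n_short` junk reads
#' per sample whose inserts are shorter than 15 nt, which the trimmer must
#' discard. Qualities are constant.
#'
#' @param counts a [seq_counts] whose rows will be emitted.
#' @param adapter 3' adapter sequence (ACGT only).
#' @param out_dir directory for per-sample FASTQ files (`<sample>.fastq`).
#' @param n_random number of random bases on each side of the insert.
#' @param read_length if non-NULL, pad reads with random filler after the
#'   adapter up to this length.
#' @param n_short junk reads with sub-15-nt inserts planted per sample.
#' @param seed integer seed (per-sample sub-streams are derived from it).
#' @return named character vector of FASTQ paths (one per sample).
#' @export
simulate_reads <- function(counts, adapter, out_dir, n_random = 4L,
                           read_length = NULL, n_short = 0L, seed = 1L) {
  stopifnot(inherits(counts, "seq_counts"))
  if (grepl("[^ACGT]", adapter)) stop("adapter must contain only A/C/G/T")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ncol(counts$counts))
  names(paths) <- colnames(counts$counts)
  for (j in seq_len(ncol(counts$counts))) {
    set.seed(substream_seed(seed, 300L + j))
    cnt <- counts$counts[, j]
    inserts <- rep(counts$annotation$sequence, cnt)
    if (n_short > 0L)
      inserts <- c(inserts, vapply(sample(5:14, n_short, replace = TRUE),
                                   random_seq, character(1)))
    nr <- length(inserts)
    smp <- colnames(counts$counts)[j]
    fp <- file.path(out_dir, paste0(smp, ".fastq"))
    if (nr == 0L) {
      file.create(fp)
      paths[j] <- fp
      next
    }
    inserts <- sample(inserts)
    rand_block <- function(k) {
      m <- matrix(sample(c("A", "C", "G", "T"), k * n_random, replace = TRUE),
                  nrow = k)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    reads <- paste0(rand_block(nr), inserts, rand_block(nr), adapter)
    if (!is.null(read_length)) {
      pad <- pmax(0L, read_length - nchar(reads))
      filler <- vapply(pad, function(p)
        if (p == 0L) "" else random_seq(p), character(1))
      reads <- substr(paste0(reads, filler), 1L, read_length)
    }
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- sprintf("%s_read%06d", smp, seq_len(nr))
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(dna, fp, format = "fastq", qualities = qual)
    paths[j] <- fp
  }
  paths
}
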