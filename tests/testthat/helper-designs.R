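# Shared small study designs for the test suite. Sizes are kept modest so
# the default run stays fast; the statistical conditions (dispersion 0.2,
# 20 samples per group for calibration checks) are fixed, not tuned.

tiny_design <- function(seed = 1, ...) {
  args <- list(
    n_per_group = c(control = 10, AD = 10),
    n_genes_per_biotype = c(miRNA = 30, YRNA = 10, tRNA = 10, piRNA = 5,
                            protein_coding = 5, other = 5),
    library_size_mean = 5e4,
    depleted_prob = 0,
    seed = seed)
  over <- list(...)
  do.call(cohort_design, c(over, args[setdiff(names(args), names(over))]))
}

# A strongly separable two-group cohort: low dispersion, large planted
# effects on a handful of miRNA genes.
separable_design <- function(seed = 1, lfc = 3, n_planted = 10, ...) {
  tiny_design(seed = seed,
              n_genes_per_biotype = c(miRNA = 200, YRNA = 50, tRNA = 50),
              isomir_family_sizes = 1, isomir_family_probs = 1,
              phi = 0.05,
              planted_effects = list(list(genes = paste0("miR-", seq_len(n_planted)),
                                          group = "AD", log2FC = lfc)),
              ...)
}

# seq_counts from a reference plus per-sample count vectors (named args).
build_tiny_counts <- function(ref, ...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  evsmallrna:::build_seq_counts(m, ref$sequence, ref)
}

# Gaussian two-cluster feature matrix for testing the elastic-net loops
# directly (samples x features).
gaussian_clusters <- function(n_per_class = 16, n_feat = 20, shift = 3,
                              n_informative = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:n_feat)))
  y <- rep(c(0L, 1L), each = n_per_class)
  X[y == 1, seq_len(n_informative)] <-
    X[y == 1, seq_len(n_informative)] + shift
  list(X = scale(X), y = y)
}

# Metadata covering every curation rule case exactly once.
curation_fixture <- function() {
  data.frame(
    sample_id = sprintf("P%02d", 1:12),
    dx_at_draw = c("control", "control", "control", "control", "control",
                   "control", "MCI", "MCI", "MCI", "AD", "AD", "control"),
    postmortem_dx = c("AD",      # 1: discordant pathology in control
                      "PART",    # 2: confirmed PART
                      "unknown", # 3: flagged by the model
                      "unknown", # 4: clean control
                      "normal",  # 5: confirmed clean control
                      "AD",      # 6: control converting to AD (concordant)
                      "DLB",     # 7: DLB in MCI
                      "unknown", # 8: clean MCI
                      "unknown", # 9: MCI converting to AD
                      "FTD",     # 10: discordant pathology in AD
                      "unknown", # 11: clean AD
                      "unknown"),# 12: control converting to MCI
    converts_to = c("none", "none", "none", "none", "none", "AD",
                    "none", "none", "AD", "none", "none", "MCI"),
    years_to_conversion = c(0, 0, 0, 0, 0, 4, 0, 0, 1.5, 0, 0, 6),
    apoe = rep(c("E3/E3", "E3/E4"), 6),
    stringsAsFactors = FALSE)
}
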