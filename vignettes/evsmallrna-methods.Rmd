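---
title: "Methods: sequence-level EV small RNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-level EV small RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evsmallrna)
```

This vignette is the package's own account of its models, the decisions
taken where the design was genuinely open, and what the synthetic-data
tests do and do not establish about real plasma data.

## Why sequences, not genes

Plasma EV small RNA libraries built with full-length capture chemistry
retain every length and sequence variant of a transcript. Collapsing
isomiRs to canonical miRNA IDs discards information that can carry the
disease signal, so the unit of analysis throughout this package is the
exact insert sequence: two reads that differ by one nucleotide are two
features. Annotation is by exact lookup against a reference table mapping
sequence → canonical gene and biotype; when a sequence carries several
candidate biotypes, the winner follows the fixed multi-mapper priority
miRNA > YRNA > tRNA > piRNA > protein-coding > other. Per-isoform IDs are
generated deterministically from the count matrix (`<gene>-<k>`, `k` by
descending total count, ties by lexicographic sequence), so any two runs
over the same counts name features identically.

Genome alignment is deliberately out of scope: exact-sequence lookup
preserves the by-sequence semantics the downstream statistics need, and the
reference table is an explicit input. Reads with no adapter hit, inserts
under 15 nt after trimming, or an `N` in the insert are discarded with a
per-sample reason tally; conservation (retained = annotated + unannotated)
is asserted in the tests.

## Normalization and differential expression

Size factors are median-of-ratios: the per-sample median of
`count / geometric mean` over genes with no zero count in any sample. The
median is taken on the ratio scale; implementations that take it on the
log scale differ when the reference set has even size (the two middle
values are averaged arithmetically vs geometrically). The brute-force
oracle in the test suite pins the ratio-scale definition exactly.

The differential-expression test is a deliberately simple
negative-binomial Wald test. Per gene, with normalized counts:

* group means $m_1, m_2$ and pooled within-group variance $s^2$
  (denominator $n_1 + n_2 - 2$);
* moment dispersion $\hat\phi = \max(10^{-8}, (s^2 - \bar m)/\bar m^2)$,
  shared between groups;
* $\mathrm{Var}(m_k) \approx (m_k + \hat\phi m_k^2)/n_k$, delta-method SE
  on $\log_2(m_2/m_1)$, two-sided normal p, Benjamini–Hochberg adjustment
  (NA rows excluded from the denominator).

There is no dispersion shrinkage, no fold-change shrinkage and no
independent filtering, so results are close to, but not numerically
identical with, DESeq2-style machinery; the point is a transparent,
testable re-implementation with the same contract. Under the null synthetic
design (dispersion 0.2, 20 samples per group, 2000 sequences) the measured
type-I error at p < 0.05 stays within [0.03, 0.07] and the p-value
distribution passes a Kolmogorov–Smirnov uniformity check; with planted
|log2FC| = 2 essentially all planted genes reach padj < 0.05.

The expression filter (strictly > 10 in ≥ 50% of the compared samples) is
applied to **raw** counts before DE but to **normalized** values for the
%CV fraction comparison. The two sources describing the filter use
different wordings, and this split follows each context's phrasing; both
thresholds are exposed as parameters so the sensitivity of either choice
can be checked directly.

For the %CV comparison the filter is required to pass within each fraction
separately (both fractions must support a defined, nonzero mean), and the
two %CV distributions are compared with a Welch (unequal-variance) t-test —
the unequal-variance form is the safe default when only "t-test" is
specified.

## The three-loop elastic net

The classifier reproduces a repeated-random-split procedure: with features
restricted to DE sequences at unadjusted p < 0.05,

1. **Penalty tuning** — for each of `n_iter` random 80/20 splits, an
   internally cross-validated elastic-net path is fit on the 80% and its
   accuracy-optimal penalty is scored by accuracy on the 20% at a 0.5
   cutoff; the penalty of the best split wins (ties → first).
2. **Feature selection** — `n_iter` fresh splits at the fixed penalty; the
   nonzero-coefficient sequences of the best split's model are the
   signature.
3. **Performance** — `n_iter` fresh splits at fixed penalty and feature
   set give mean ± sd accuracy and AUC. AUC is the area under the
   empirical ROC of the held-out split in all contexts: the source
   procedure mixed a cross-validated AUC loss with split accuracies, and a
   single consistent definition was preferred here.

Open choices and how they were fixed:

* **Mixing parameter** α defaults to 0.5 — the canonical elastic-net
  midpoint between ridge and lasso; it is a plain argument for sensitivity
  analysis since the source never states its value.
* **Feature scale.** Penalized fits are scale-sensitive and the source
  states only that normalized counts were used; here features are
  median-of-ratios normalized, log2(x+1)-transformed and standardized per
  feature. The transform is stored in the model so projections of new
  samples are consistent.
* **Splits** are simple random (not stratified); a split whose training
  part lacks a class is redrawn (bounded retries).
* **Projection of converters.** The model is trained without the
  converters; new samples are normalized by median-of-ratios against the
  training cohort's gene-wise geometric means, then pushed through the
  stored transform and coefficients. Class assignment is at probability
  0.5.

Two behaviours of this design are worth knowing. First,
accuracy-tied penalty selection often lands on a heavily shrunken model
when the groups separate easily — rankings (and the waterfall) are crisp
but probabilities compress toward 0.5, so projected samples with partial
signal can sit just under the cutoff. Second, the procedure preselects
features on **all** samples before splitting; re-running the whole pipeline
on permuted labels therefore yields held-out accuracies far above chance
(≈ 0.9 in a 4000-gene, 40-sample permutation experiment) purely through
selection leakage. That optimism is a property of the published design,
reproduced faithfully; the package's permutation check is therefore stated
at the modelling level — fixed penalty and feature set, permuted labels —
where accuracy collapses to chance as it should. Performance numbers from
loop 3 should be read accordingly: they estimate the stability of a chosen
signature, not leakage-free generalization error.

The PART screen applies exactly this machinery to autopsy-confirmed
controls (normal ageing vs primary age-related tauopathy) and then flags
unautopsied controls whose PART probability is **at or above** 0.5 — the
boundary is inclusive by specification.

## Logistic benchmark and conversion trends

The comparison model is an unpenalized binomial GLM on the top-10 DE genes
(by adjusted p or |log2FC| — the two published descriptions disagree, so
the criterion is an explicit argument) over 100 random 80/20 splits, with
accuracy and pROC AUC summarized as mean ± sd. Perfect-separation fits are
kept (bounded IRLS) and counted.

Conversion trends regress normalized expression on
x = −years-to-conversion, so a sample drawn 4 years before diagnosis sits
at −4 and x increases toward 0 as conversion approaches. Slope p-values
are two-sided t-tests on the OLS slope; genes with R² ≥ 0.66 and p < 0.05
are flagged. The regression is computed by vectorized closed-form OLS and
cross-checked against `lm()` and a normal-equation oracle at 10⁻¹⁰.
Normalized counts are assumed (the source does not say); the alternative
is one argument away.

## Cohort curation

Rules apply in a fixed order, pathology before conversion: (1) AD
pathology in a non-converter control excludes it; (2) confirmed PART
controls are excluded from disease comparisons (but power the PART model);
(3) model-flagged suspected-PART controls are excluded; (4) DLB in a
clinically MCI sample excludes it; (5) FTD/vascular primary pathology in
non-converter MCI/AD samples is excluded by default — the handling of
these cases is not published, so the list is configurable; (6) converters
get their own groups. Pathology rules skip converters whose conversion
matches the pathology: a control who later converted to AD and shows AD
pathology is concordant evidence, not a confound. Curation is idempotent,
assigns every sample exactly one label, and is covered by an exhaustive
table-driven test with one fixture row per rule.

## The synthetic cohort generator

The generator is first-class, tested code; it emulates the structure the
analyses assume so that every pipeline property can be checked against
planted truth:

* **Counts** are negative binomial, `Var = μ + φμ²` (φ = 0.2 by default,
  the common order for biofluid RNA-seq), with log-normal per-sequence
  baseline abundances (sdlog 1.5, giving the few-dominant-transcripts skew
  typical of plasma) and log-normal library factors (sdlog 0.25).
* **Groups.** Default sizes (40 control / 18 MCI / 35 AD / 9 + 6 + 6
  converters) mirror a memory-clinic cohort of ~115 usable EV samples.
  Planted effects are per-group log2 fold changes on chosen genes;
  converter samples express
  `origin effect + scale × (target effect − origin effect)`, so the
  `converter_effect_scale` slider moves them from their group at draw
  (scale 0) to their future diagnosis (scale 1).
* **Trends.** Trend genes add `slope × (−years_to_conversion)` to the
  expected normalized expression of converter samples, additively, so OLS
  slope recovery is unbiased by construction; the recovery test plants
  slope 30 counts/year on a low-skew background (abundance sdlog 0.3,
  φ = 0.02 — "moderate noise" that keeps the 9-converter regression
  informative) and observes |bias| < 10% over 100 replicates.
* **Depleted fraction.** A matched EV-depleted sample (for a configurable
  fraction of subjects, default 0.4) gets a planted random dropout set
  (default 30% of sequences at zero) and dispersion inflated to
  `c²φ + (c²−1)/μ`, which multiplies the per-gene coefficient of variation
  by exactly `c` (default 2) — the lower diversity and higher variability
  reported for non-vesicular plasma RNA.
* **Metadata.** Postmortem pathology is drawn per clinical group with
  configurable probabilities (most samples `unknown`, controls sometimes
  PART or AD at autopsy, MCI sometimes DLB), DRS/MMSE are truncated
  group-conditional normals centred on published separations (DRS 136 and
  124; MMSE bands), ApoE genotype frequencies shift toward ε4 with
  disease. These fields drive curation and the cross-tabs; they are not
  generative for the counts except through the PART pathology label.
* **Reads.** Each count unit emits one FASTQ read (4 random nt + insert +
  4 random nt + adapter, constant quality), with optional planted sub-15-nt
  junk reads; the trimming/collapsing pipeline inverts this exactly, and
  that identity — plus the exact count of planted discards — is asserted on
  a 1000-sequence × 20-sample cohort.
* **Seeding.** Each artifact (reference, metadata, counts, reads) derives
  its own sub-seed from the master seed, and each sample's counts use a
  per-sample seed. Consequently non-converter columns are bit-identical
  across designs differing only in `converter_effect_scale`, which is what
  makes the projection-monotonicity experiment a paired comparison.

What passing these tests does **not** show: real plasma libraries have
sequencing errors, adapter dimers, mismatch-tolerant multi-mapping,
batch structure, and biological covariance between sequences (isomiRs of
one gene rise and fall together); the generator draws sequences
independently given their means and trims with exact matching. Effect-size
magnitudes in the defaults were chosen for testability — the source cohort
does not report its effect sizes — so recovery rates here say nothing about
power in any particular real study.

## Numerical choices and degenerate inputs

* Dispersion floor 10⁻⁸; genes with zero overall mean are reported NA and
  leave the BH denominator.
* A group mean of exactly zero enters the fold change through a 0.5
  pseudocount on both groups, preserving sign.
* Constant genes: log2FC = 0, p = 1 in DE; %CV = 0; trend slope 0 with
  R² defined as 0.
* Zero log2FC pairs in the concordance summary count as concordant only
  when both are zero.
* Gene-ID, split and iteration tie-breaks are all deterministic (first
  maximum, lexicographic sequence), so every procedure is reproducible
  from its seed.
* Sub-second problem sizes in the test suite were chosen so the whole
  suite, including the end-to-end properties (200-iteration elastic-net
  loops, 20-replicate projection experiment, 100-replicate slope
  recovery), runs in a few minutes on one core.

## Known limitations

The DE test's moment dispersion is noisy for small groups and the normal
Wald reference is slightly anti-conservative there; the three-loop
procedure's preselection leakage (above) means its reported accuracy is an
optimistic estimate by design; the PART screen inherits whatever
confounding separates autopsied from unautopsied controls; and the
generator's independence assumptions make multi-collinearity behaviour of
the elastic net on real isomiR families better than the tests alone can
certify.
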