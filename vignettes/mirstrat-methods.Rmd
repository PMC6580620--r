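---
title: "mirstrat: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirstrat: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstrat)
```

`mirstrat` turns aligned small RNA-seq reads into mature-miRNA expression
profiles and carries those profiles through subtype discovery,
classification and survival stratification. This vignette explains each
stage's model and assumptions, the parameters that matter, the numerical
and design decisions that were genuinely open, and what the synthetic
data generator does and does not emulate.

## Coordinates

All internal coordinates are 0-based half-open `[start, end)`. The two
external dialects the package reads — GFF3 (1-based, fully inclusive)
and the isoform-table convention (1-based, start included, end
excluded) — are converted at the boundary by `to_internal()` /
`from_internal()`, which are exact inverses of each other. Keeping a
single internal convention is what makes the deviation arithmetic below
immune to off-by-one drift between dialects.

## Read assignment

A mature miRNA is a ~22-nt product with annotated genomic ends; real
reads deviate from those ends through isomiR 5'/3' heterogeneity and
through non-templated additions (NTAs), extra 3' bases absent from the
genome. The quantifier therefore:

1. computes each alignment's *effective interval* — its reference span
   after trimming the terminal mismatch runs at both ends. Soft-clipped
   bases never consume reference, so NTAs reported as soft clips are
   outside the span by construction; NTAs absorbed by the aligner as
   terminal mismatches are removed by the trim. We read "mismatches at
   the read start and end are excluded" in this sense because terminal
   mismatches are exactly how NTAs surface in an end-to-end alignment.
2. matches the effective interval against mature loci on the same
   strand, accepting total deviation |Δstart| + |Δend| ≤ `max_dev`
   (default 4 nt). We interpret the *total* as the sum of the two end
   deviations, not their maximum; the sum reading is stricter and treats
   a (2,2) shift the same as a (4,0) shift. Strand agreement is
   mandatory — miRNA biogenesis is strand-specific, and matching across
   strands would conflate -5p/-3p products of palindromic regions.

A read's alignments are resolved jointly:

* unique mapper, one matching mature → assigned; no match →
  *unannotated*;
* unique mapper tied between distinct matures at equal deviation →
  discarded, unless the tied matures carry one identical sequence (a
  paralog boundary case, resolved like the rescue rule below);
* multi-mapper → counted once if and only if **every** alignment lands
  on an annotated mature and all matched matures share one identical
  mature sequence; otherwise discarded. The count goes to the
  lexicographically smallest `mature_id`, a deterministic canonical
  choice that keeps column sums well defined when the same molecule is
  annotated at several loci.

Every distinct read contributes exactly one unit to
`assigned + unannotated + discarded`, which the tests assert as a mass
balance. Samples with fewer than `min_reads` (default 500,000) distinct
reads are flagged for exclusion rather than silently dropped.

The same bounded-deviation matching drives `remap_isoforms()`, which
reassigns isoform-level counts produced under one annotation version to
the mature loci of another. Records matching several matures go to the
minimal-deviation locus; exact deviation ties are dropped (and reported)
rather than split fractionally — fractional splitting would complicate
the mass accounting for no identifiable benefit, since a tie at equal
deviation carries no evidence for either target.

Duplicate annotation identifiers assigned to distinct loci (a known
defect in some annotation releases, e.g. for mir-4477a/b and mir-10401)
are repaired by `correct_duplicate_ids()` with deterministic `-1`, `-2`
suffixes in (chromosome, start) order; the source material says such
records were "corrected" without stating how, so the suffix scheme is
this package's own convention and is documented as such.

## Normalization

`log2_cpm()` computes `log2((y + p_j) / (N_j + 2 p_j) * 1e6)` with the
pseudo-count scaled by relative library size, `p_j = prior * N_j /
mean(N)` (default prior 0.25), matching the documented behaviour of the
widely used log-CPM implementation in edgeR — which also serves as an
independent cross-check in the test suite. A fixed (unscaled)
pseudo-count is available via `scale_prior = FALSE`. Library sizes are
the raw assigned totals; no between-sample scaling factors are applied
by default because none are part of the modelled procedure.
`expressed_counts()` summarizes profile complexity as the number of
miRNAs above each threshold on a grid (default −5 to 20 log2-CPM in 0.5
steps). `standardize_rows()` (mean 0, sample SD 1, n−1 denominator)
prepares matrices for heatmap clustering; constant rows cannot be scaled
and are set to zero with a warning.

## Differential expression and the signature

`de_contrast()` runs one contrast (one-vs-rest or pairwise) per miRNA.
The default statistic is the two-sided Wilcoxon rank-sum test on
log2-CPM. This is a deliberate stand-in: the original analysis this
package models used a negative-binomial count-model engine, whose
internals are out of scope here. The rank-sum default is
distribution-free, calibrated (type-I error ≈ 0.05 in the acceptance
suite), and the `test_fun` plug-in point accepts any drop-in statistic
with a `p.value`. Consequently the package validates its signature
machinery by simulation (planted markers must be recovered exactly)
rather than by matching any particular published gene list.

Multiple testing uses Benjamini–Hochberg (`bh_adjust()`, delegating to
`stats::p.adjust` after validation; the tests compare against the
step-up definition directly). `build_signature()` takes the `k = 15`
smallest-q miRNAs passing `q ≤ 0.01` from each contrast and unions them,
breaking ties deterministically by (q, |log2 FC| descending, ID).
"Most significant" is read as smallest q; with BH this induces the same
order as p within a contrast, and makes the FDR filter and the ranking
consistent with each other. Both one-vs-rest and pairwise contrasts feed
the union by default (`contrasts = "both"`), configurable, since either
set alone is a defensible reading.

## Consensus clustering

`consensus_cluster()` implements the Monti resampling scheme: for each
k in 2..`maxK` (default 6), `reps` (default 1000) subsamples of
`ceiling(pItem * n)` items (default 80%; `pFeature` likewise for rows)
are clustered by hierarchical agglomeration — average linkage on
1 − Pearson correlation by default — and the consensus matrix records
the fraction of co-samplings in which each pair co-clustered. Final
labels come from average-linkage clustering of 1 − consensus. Item
consensus is the mean consensus of an item with the other members of
its assigned cluster. Numerical details:

* the RNG seed is a required argument — there is no silent global seed;
  a fixed seed reproduces the result bit-identically.
* constant sample vectors make correlation undefined and are refused by
  name, before any resampling.
* a pair never drawn together after `reps` subsamples yields an NA
  consensus entry; NA entries are imputed with column means for final
  clustering, with a warning.
* the CDF area for each k is the empirical consensus CDF integrated
  over the full [0, 1] range (equivalently 1 − mean consensus), so it
  grows as more pairs are confidently separated; the delta-area curve
  is the relative increase from k−1 to k.

`select_k()` returns the largest k whose relative delta-area is at
least `threshold` (default 0.1) — the last k at which adding a cluster
still increases consensus appreciably, which is the "increase in
consensus is low for k+1, therefore k" reading of a delta-area elbow
plot. The selection is advisory: the full curve travels with the
result, and selections resting on near-zero areas are flagged
low-confidence. On planted three-group cohorts the rule selects k = 3
with adjusted Rand index 1 across seeds.

Two idealized edge cases are worth naming. For *n* identical samples
any k-partition is equally valid, so consensus entries under cutree are
arbitrary rather than 1; the tests therefore probe stability with
well-separated profile groups (where consensus is provably 0/1), not
with literal duplicates. And for a single diffuse cluster the delta
curve need not be near zero; the low-confidence flag, not the k value
alone, is the package's statement about such data.

`chi2_enrichment()` (Pearson chi-square without continuity correction,
expected counts reported, small-expected warning) quantifies the
association between consensus clusters and clinical labels.
`ward_cluster()` provides the supervised heatmap clustering: Euclidean
distance, Ward linkage in the variance-minimizing squared-distance
formulation (`ward.D2`), with configurable row/column cuts (the modelled
analysis used 5 miRNA clusters and 4 sample clusters; a k-cut is used
because the original cut criterion is not stated).

## Subtype classification

`center_to_reference()` subtracts each gene's mean over a *fixed*
reference cohort from every test sample. Because the reference never
changes, previously centered values are invariant to the arrival of new
test samples — the property that removes cohort-composition bias from
nearest-centroid calls, and the reason classification is exactly
invariant to any gene-wise shift applied to reference and test alike.
`nearest_centroid()` correlates the centered sample with each subtype
centroid over shared genes (≥10 required). Spearman is the default
metric — customary for this classifier family and robust to scale
differences between platforms — with Pearson by flag. Samples whose best
correlation falls below `threshold` (default 0.1) are reported
unassigned; the modelled analysis excluded two such samples without
stating its cutoff, so the threshold is exposed and every call carries
its correlations and margin. Centroids are an input file, never bundled.

## Survival stratification

`cluster_score()` averages the log2-CPM of a miRNA set per sample; by
default all mature arms of the scoring precursors are averaged (which
arms the original analysis used is unstated, so a mature-ID list
overrides). `median_split()` dichotomizes at the median with
"strictly above → high": since "high" is defined as *higher than
median* expression, the median sample of an odd cohort goes low. Host
-gene (e.g. LINC00478) stratification is the same code path with a gene
expression column as the score. `km_estimate()` and `logrank_test()`
wrap the survival package's product-limit estimator and
observed-vs-expected test; the test suite checks them against a
hand-rolled product-limit oracle, closed forms, and a permutation
reference. `stratified_analysis()` computes the median split *within*
each stratum independently — samples outside a stratum can never move
its cutpoint — and applies an optional subgroup predicate (see
`luminal_a_filter()`: ER+, HER2−, node-negative, endocrine treatment,
no chemotherapy, no anti-HER2 therapy, optional radiotherapy filter)
before splitting. Strata emptied by the filter are reported, not
errors.

## What the synthetic data emulates — and what it does not

`simulate_annotation()` lays out matures and precursors on toy
chromosomes, both strands, with identical-sequence paralog groups
(rescuable multi-mappers) and near-identical decoy pairs (discardable
ones). `simulate_alignments()` draws reads multinomially from an
expression profile, adds discretized Gaussian end offsets (SD
`isomir_sd`, truncated at `isomir_max` per end — a rounded Gaussian is
the simplest model with tunable tail mass beyond the 4-nt rule) and,
with probability `nta_prob`, a 1–3 nt NTA encoded as a terminal
mismatch run so the trimming logic is genuinely exercised.
`simulate_cohort()` plants per-subtype marker shifts (default 15
markers, +3 log2 units, noise SD 1 — a strong but realistic
subtype-marker effect on the log2-CPM scale) on a shared baseline;
`simulate_survival()` draws exponential event times with a
multiplicative group hazard and independent exponential censoring. All
generators are seed-deterministic down to the serialized files.

Not emulated: sequencing error models, adapter artifacts, expression
correlation structure within real miRNA families, non-exponential
hazards, and informative censoring. Passing tests therefore demonstrate
algorithmic correctness on data satisfying the pipeline's assumptions,
not robustness to every pathology of real libraries.

## Problem sizes and budgets

The test and acceptance workloads are sized for a desk run: quantifier
recovery uses 10 samples × 10,000 reads over 20 matures; consensus
selection uses 30 samples × 60 features with 100 resamples; calibration
uses 2,000 null features (rank-sum) and 1,000 null replicates at
n = 100/100 (log-rank); the demo pipeline runs 12 samples × 1,500 reads
with 50 consensus resamples. These sizes give exact or tight
Monte-Carlo checks while keeping the full suite under a minute of
compute for most modules.

## Known limitations

* The default DE statistic is a rank-sum stand-in, not a count model;
  dispersion estimation and count-level inference are out of scope.
* Remapping is coordinate-based only; sequence-based remapping is not
  attempted.
* Nearest-centroid calls depend on the user-supplied centroid and
  reference files; no training is performed.
* Survival analysis is univariate (median split + log-rank);
  proportional-hazards regression and competing risks are out of scope.
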