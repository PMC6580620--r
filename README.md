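# mirstrat

Small RNA-seq analysis of tumor cohorts, from aligned reads to survival
stratification. `mirstrat` implements the full chain used to ask whether
mature-miRNA expression recapitulates and refines the intrinsic molecular
subtypes of breast cancer: a coordinate-deviation read counter with a
multi-mapper rescue rule, log2-CPM normalization, differential-expression
signatures, consensus clustering, reference-centered nearest-centroid
(PAM50-style) classification, and median-split Kaplan–Meier analysis — for
example of the miR-99a/let-7c/miR-125b polycistron score within the
Luminal A subtype. A synthetic-data module generates annotation,
alignments, expression cohorts and survival records with known ground
truth, so the entire pipeline is testable offline.

## Who it is for

Computational biologists quantifying mature miRNAs from small RNA-seq
alignments (SAM/BAM or tabular records plus a miRBase-dialect GFF3) and
relating the resulting profiles to molecular subtype and outcome; and
method developers who need a transparent, fully tested reference for the
individual steps.

## The methods at the core

**Read assignment.** Each aligned read is compared to annotated mature
loci after trimming terminal mismatch runs (which represent non-templated
3' additions). A read is counted for a mature miRNA when the total
coordinate deviation satisfies |Δstart| + |Δend| ≤ 4 nt on the same
strand. Multi-mapping reads are excluded *unless* every alignment lands
on annotated matures that all share one identical mature sequence, in
which case the read is counted once. The same bounded-deviation matching
remaps isoform quantifications across annotation versions (handling both
the GFF3 1-based-inclusive and the 1-based half-open isoform-table
coordinate dialects; internally everything is 0-based half-open).

**Normalization.** log2-CPM with a library-scaled pseudo-count:
`log2((y_gj + p_j) / (N_j + 2 p_j) * 1e6)` with `p_j = 0.25 * N_j / mean(N)`.

**Consensus clustering** (Monti resampling scheme): repeated 80% item
subsamples clustered by average-linkage on 1 − Pearson correlation; the
co-clustering frequency matrix, per-item consensus scores, and the
delta-area of the consensus CDF select the number of clusters k.

**Subtyping.** Nearest-centroid over genes centered against a *fixed*
reference cohort (so calls never depend on the composition of the test
cohort), Spearman correlation, with an unassignable-sample rule for low
correlations.

**Survival.** Per-subtype median split of an expression score (e.g. the
mean of the miR-99a/let-7c/miR-125b cluster arms), Kaplan–Meier curves
and log-rank tests, including the focused ER+/HER2−/node-negative/
endocrine-only Luminal A subgroup filter.

## Worked example

```r
library(mirstrat)

# synthetic annotation: 20 matures, 2 identical-sequence paralog groups
# (rescuable multi-mappers), 1 decoy pair (non-rescuable)
ann <- simulate_annotation(n_mirnas = 20, n_paralog_groups = 2,
                           n_decoy_groups = 1, seed = 7)
ann
#> mir_annotation [synthetic]: 20 matures at 22 loci, 22 precursors

sim <- simulate_alignments(ann, n_reads = 5000, isomir_sd = 1,
                           nta_prob = 0.2, seed = 8)
q <- quantify_sample(sim$alignments, ann, min_reads = 1000)
str(q$qc)
#> $ n_reads        : int 5000
#> $ assigned       : int 4485
#> $ unannotated    : int 14
#> $ discarded      : int 501
#> $ below_threshold: logi FALSE
```

4485 reads are counted; the 501 discards are almost entirely the decoy
pair, whose multi-mapped reads fail the identical-sequence rescue rule;
the 14 unannotated reads drew end offsets beyond the 4-nt deviation
bound. On a subtype-structured cohort the downstream stages recover the
planted truth:

```r
co <- simulate_cohort(n_per_subtype = 25, sigma = 1, seed = 11)  # 4 subtypes
sig <- build_signature(de_all_contrasts(co$expr, co$labels), k = 15, fdr = 0.01)
nrow(sig)
#> [1] 60        # all 4 x 15 planted markers, nothing else

cc <- consensus_cluster(co$expr, maxK = 6, reps = 100, seed = 12)
cc
#> delta area: k2=0.380 k3=0.662 k4=0.200 k5=0.009 k6=0.011
as.integer(select_k(cc))
#> [1] 4         # consensus stops improving after the 4 planted groups

calls <- classify_cohort(co$expr, co$centroids)
mean(calls$label == co$labels)
#> [1] 1
```

An end-to-end run from a single YAML config (quantify → normalize →
signature → cluster → subtype → survival, with a reproducibility
manifest):

```r
cfg <- write_demo_inputs("demo", seed = 17)
run_pipeline(cfg)   # writes demo/run/: counts.tsv, expression_log2cpm.tsv,
                    # signature.tsv, consensus_clusters.tsv, subtype_calls.tsv,
                    # survival_strata.tsv, manifest.json, run.log
```

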