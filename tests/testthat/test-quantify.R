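test_that("alignment matching trims terminal mismatch runs before measuring deviation", {
  ann <- tiny_annotation()
  idx <- build_locus_index(ann)

  exact <- aln_record("r1", "chrT", 100L, 122L)
  hit <- match_alignment(exact, idx)
  expect_identical(hit$mature_id, "mat-a-5p")
  expect_identical(hit$deviation, 0L)

  # dStart 1 + dEnd 3 = 4 -> in; dStart 1 + dEnd 4 = 5 -> out
  expect_identical(match_alignment(aln_record("r2", "chrT", 101L, 125L), idx)$deviation, 4L)
  expect_identical(nrow(match_alignment(aln_record("r3", "chrT", 101L, 126L), idx)), 0L)

  # 2-nt non-templated 3' addition absorbed as terminal mismatches:
  # aligned span overshoots by 2 but trims back to deviation 0
  nta <- aln_record("r4", "chrT", 100L, 124L, n_clip_end = 2L)
  expect_identical(match_alignment(nta, idx)$deviation, 0L)

  # strand contract: same interval, wrong strand
  expect_identical(nrow(match_alignment(aln_record("r5", "chrT", 100L, 122L, strand = "-"), idx)), 0L)
})

test_that("read resolution rescues identical-sequence multi-mappers and discards the rest", {
  ann <- tiny_annotation()
  idx <- build_locus_index(ann)

  # both alignments hit the two loci of the identical-sequence paralog
  grp <- rbind(aln_record("r1", "chrT", 1500L, 1522L, n_alignments = 2L),
               aln_record("r1", "chrU", 300L, 322L, n_alignments = 2L))
  res <- resolve_read(grp, idx)
  expect_identical(res$status, "assigned")
  expect_identical(res$mature_id, "mat-d")

  # one alignment annotated, one in empty space -> discard
  grp2 <- rbind(aln_record("r2", "chrT", 100L, 122L, n_alignments = 2L),
                aln_record("r2", "chrT", 5000L, 5022L, n_alignments = 2L))
  expect_identical(resolve_read(grp2, idx)$status, "ambiguous_discard")

  # two alignments on matures with different sequences -> discard
  grp3 <- rbind(aln_record("r3", "chrT", 100L, 122L, n_alignments = 2L),
                aln_record("r3", "chrT", 500L, 522L, n_alignments = 2L))
  expect_identical(resolve_read(grp3, idx)$status, "ambiguous_discard")

  # unique mapper off annotation -> unannotated
  expect_identical(resolve_read(aln_record("r4", "chrT", 5000L, 5022L), idx)$status,
                   "unannotated")
  expect_error(resolve_read(aln_record("r0", "chrT", 1L, 20L)[0L, ], idx),
               "empty")

  # order invariance under permutation of the alignment list
  expect_identical(resolve_read(grp[2:1, ], idx), resolve_read(grp, idx))
})

test_that("resolution rule equals brute force over all group configurations up to 3 alignments", {
  # four alignment archetypes: mature A, mature B (same sequence as A),
  # mature C (different sequence), unannotated space
  seq_ab <- paste0(strrep("ACGU", 5L), "AC")
  seq_c <- paste0(strrep("GGCU", 5L), "GG")
  pre <- data.frame(
    precursor_id = c("pA", "pB", "pC"), name = c("pA", "pB", "pC"),
    chrom = c("c1", "c2", "c3"), start = c(80L, 80L, 80L),
    end = c(160L, 160L, 160L), strand = "+", stringsAsFactors = FALSE
  )
  mat <- data.frame(
    mature_id = c("mA", "mB", "mC"), name = c("mA", "mB", "mC"),
    sequence = c(seq_ab, seq_ab, seq_c),
    precursor_id = c("pA", "pB", "pC"),
    chrom = c("c1", "c2", "c3"), start = c(100L, 100L, 100L),
    end = c(122L, 122L, 122L), strand = "+", stringsAsFactors = FALSE
  )
  ann <- mir_annotation(mat, pre)
  idx <- build_locus_index(ann)
  archetypes <- list(
    A = list(chrom = "c1", start = 100L, end = 122L),
    B = list(chrom = "c2", start = 100L, end = 122L),
    C = list(chrom = "c3", start = 100L, end = 122L),
    none = list(chrom = "c1", start = 900L, end = 922L)
  )
  for (n_aln in 1:3) {
    combos <- do.call(expand.grid,
                      c(rep(list(names(archetypes)), n_aln),
                        stringsAsFactors = FALSE))
    for (r in seq_len(nrow(combos))) {
      kinds <- unlist(combos[r, ])
      grp <- do.call(rbind, lapply(seq_along(kinds), function(i) {
        a <- archetypes[[kinds[i]]]
        aln_record("r", a$chrom, a$start, a$end, n_alignments = n_aln)
      }))
      got <- resolve_read(grp, idx)$status
      match_sets <- lapply(kinds, function(k) {
        a <- archetypes[[k]]
        bf <- bf_deviation_match(mat, a$chrom, a$start, a$end, "+", 4L)
        bf$sequence <- mat$sequence[match(bf$mature_id, mat$mature_id)]
        bf
      })
      expect_identical(got, bf_resolve(match_sets),
                       info = paste("config:", paste(kinds, collapse = "+")))
    }
  }
})

test_that("sample quantification recovers simulated ground truth and enforces QC", {
  ann <- simulate_annotation(n_mirnas = 20L, n_paralog_groups = 2L,
                             n_decoy_groups = 0L, seed = 31)
  sim <- simulate_alignments(ann, n_reads = 2000L, seed = 32)
  q <- quantify_sample(sim$alignments, ann, min_reads = 100L)
  expect_identical(q$counts, sim$true_counts)
  expect_false(q$qc$below_threshold)

  # read-threshold flag at the boundary
  small <- simulate_alignments(ann, n_reads = 99L, seed = 33)
  expect_true(quantify_sample(small$alignments, ann, min_reads = 100L)$qc$below_threshold)
  atln <- simulate_alignments(ann, n_reads = 100L, seed = 34)
  expect_false(quantify_sample(atln$alignments, ann, min_reads = 100L)$qc$below_threshold)

  # empty stream: zero vector, flagged
  empty <- quantify_sample(sim$alignments[0, ], ann, min_reads = 100L)
  expect_true(all(empty$counts == 0L))
  expect_true(empty$qc$below_threshold)

  # ungrouped stream: instruct to sort by name
  shuffled <- sim$alignments[c(1L, 3L, 1L), ]
  expect_error(quantify_sample(shuffled, ann), "sort")
})

test_that("isomiR offsets within the deviation bound keep recovery exact; beyond it reads go unannotated", {
  ann <- simulate_annotation(n_mirnas = 20L, n_paralog_groups = 0L,
                             n_decoy_groups = 0L, seed = 41)
  # per-end truncation at 2 nt caps total deviation at 4: still exact
  within <- simulate_alignments(ann, n_reads = 3000L, isomir_sd = 1.2,
                                isomir_max = 2L, nta_prob = 0.3, seed = 42)
  qw <- quantify_sample(within$alignments, ann, min_reads = 100L)
  expect_identical(qw$counts, within$true_counts)

  # wider offsets: exactly the reads with |dStart| + |dEnd| > 4 drop out
  wide <- simulate_alignments(ann, n_reads = 3000L, isomir_sd = 3,
                              isomir_max = 5L, seed = 43)
  qd <- quantify_sample(wide$alignments, ann, min_reads = 100L)
  dev <- abs(wide$truth$d_start) + abs(wide$truth$d_end)
  expected <- table(factor(wide$truth$mature_id[dev <= 4L],
                           levels = names(wide$true_counts)))
  expect_identical(qd$counts, stats::setNames(as.integer(expected),
                                              names(wide$true_counts)))
  expect_identical(qd$qc$unannotated, sum(dev > 4L))
})

test_that("read accounting conserves every distinct read", {
  ann <- simulate_annotation(seed = 51)
  sim <- simulate_alignments(ann, n_reads = 2500L, isomir_sd = 2,
                             isomir_max = 5L, nta_prob = 0.3, seed = 52)
  q <- quantify_sample(sim$alignments, ann, min_reads = 100L)
  expect_identical(q$qc$assigned + q$qc$unannotated + q$qc$discarded,
                   length(unique(sim$alignments$read_id)))
  expect_identical(sum(q$counts), q$qc$assigned)
})

test_that("SAM input round-trips through the record reader", {
  ann <- simulate_annotation(seed = 61)
  sim <- simulate_alignments(ann, n_reads = 400L, isomir_sd = 1,
                             nta_prob = 0.25, seed = 62)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$alignments, attr(ann, "chrom_lengths"), sam)
  rec <- read_sam_alignments(sam)
  cols <- c("read_id", "chrom", "start", "end", "strand",
            "n_clip_start", "n_clip_end", "n_alignments")
  a <- sim$alignments[cols]
  b <- rec[cols]
  o <- function(d) {
    d <- d[order(d$read_id, d$chrom, d$start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(o(a), o(b))
  # and quantification from SAM equals quantification from records
  q1 <- quantify_sample(sim$alignments, ann, min_reads = 10L)
  rec_sorted <- rec[order(match(rec$read_id, unique(sim$alignments$read_id))), ]
  q2 <- quantify_sample(rec_sorted, ann, min_reads = 10L)
  expect_identical(q1$counts, q2$counts)
})

test_that("cohort quantification drops below-threshold samples from the matrix", {
  ann <- simulate_annotation(n_decoy_groups = 0L, seed = 71)
  sims <- list(
    big1 = simulate_alignments(ann, n_reads = 800L, sample_id = "big1", seed = 72),
    big2 = simulate_alignments(ann, n_reads = 800L, sample_id = "big2", seed = 73),
    tiny = simulate_alignments(ann, n_reads = 50L, sample_id = "tiny", seed = 74)
  )
  qr <- quantify_cohort(lapply(sims, `[[`, "alignments"), ann, min_reads = 500L)
  expect_identical(qr$excluded, "tiny")
  expect_identical(colnames(qr$counts$values), c("big1", "big2"))
  expect_identical(qr$counts$values[, "big1"], sims$big1$true_counts)
  expect_identical(qr$counts$lib_sizes, colSums(qr$counts$values))
})
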