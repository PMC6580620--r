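test_that("coordinate conversions follow both external dialects and invert", {
  # GFF3 1-based inclusive: 100..121 is 22 nt
  g <- to_internal(100, 121, "gff3")
  expect_identical(g$start, 99L)
  expect_identical(g$end, 121L)
  expect_identical(g$end - g$start, 22L)
  # the isoform-table dialect includes the start and excludes the end
  t <- to_internal(100, 122, "tcga")
  expect_identical(t$start, 99L)
  expect_identical(t$end, 121L)

  set.seed(42)
  s <- sample.int(1e6, 200)
  e <- s + sample.int(30, 200, replace = TRUE)
  for (conv in c("gff3", "tcga")) {
    int <- to_internal(s, e, conv)
    back <- from_internal(int$start, int$end, conv)
    expect_identical(back$start, as.integer(s))
    expect_identical(back$end, as.integer(e))
  }
  expect_error(to_internal(10, 10, "tcga"), "start must precede end")
})

test_that("miRBase GFF3 parsing attaches matures to precursors and converts coordinates", {
  gff <- c(
    "##gff-version 3",
    "chr1\t.\tmiRNA_primary_transcript\t100\t180\t.\t+\t.\tID=MI001;Name=mir-x",
    "chr1\t.\tmiRNA_primary_transcript\t500\t580\t.\t-\t.\tID=MI002;Name=mir-y",
    "chr1\t.\tmiRNA\t100\t121\t.\t+\t.\tID=MIMAT001;Name=miR-x-5p;Derives_from=MI001",
    "chr1\t.\tmiRNA\t150\t171\t.\t+\t.\tID=MIMAT002;Name=miR-x-3p;Derives_from=MI001",
    "chr1\t.\tmiRNA\t520\t541\t.\t-\t.\tID=MIMAT003;Name=miR-y-5p;Derives_from=MI002"
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  ann <- parse_mirbase_gff3(path, "test")
  expect_equal(nrow(ann$matures), 3L)
  expect_equal(nrow(ann$precursors), 2L)
  m1 <- ann$matures[ann$matures$mature_id == "MIMAT001", ]
  expect_identical(m1$start, 99L)   # 1-based inclusive 100 -> internal 99
  expect_identical(m1$end, 121L)
  expect_identical(m1$precursor_id, "MI001")
  expect_identical(ann$matures$strand[ann$matures$mature_id == "MIMAT003"], "-")
})

test_that("malformed GFF3 lines and dangling Derives_from are reported precisely", {
  bad_attr <- c(
    "##gff-version 3",
    "chr1\t.\tmiRNA_primary_transcript\t100\t180\t.\t+\t.\tID=MI001;Name=mir-x",
    "chr1\t.\tmiRNA\t100\t121\t.\t+\t.\tID MIMAT001 no equals"
  )
  p1 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(bad_attr, p1)
  expect_error(parse_mirbase_gff3(p1), "line 3")

  dangling <- c(
    "##gff-version 3",
    "chr1\t.\tmiRNA_primary_transcript\t100\t180\t.\t+\t.\tID=MI001;Name=mir-x",
    "chr1\t.\tmiRNA\t100\t121\t.\t+\t.\tID=MIMAT001;Name=m;Derives_from=MI999"
  )
  p2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(dangling, p2)
  expect_error(parse_mirbase_gff3(p2), "MI999")
})

test_that("annotation GFF3 writer round-trips through the parser", {
  ann <- tiny_annotation()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_mirbase_gff3(ann, path)
  back <- parse_mirbase_gff3(path, "tiny")
  key <- function(a) {
    m <- a$matures[order(a$matures$mature_id, a$matures$chrom, a$matures$start), ]
    rownames(m) <- NULL
    m
  }
  expect_identical(key(back), key(ann))
  p <- function(a) {
    x <- a$precursors[order(a$precursors$precursor_id), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(p(back), p(ann))
})

test_that("duplicate precursor IDs at distinct loci get coordinate-ordered suffixes", {
  ann <- tiny_annotation()
  expect_identical(correct_duplicate_ids(ann), ann)  # all-unique: unchanged

  # two distinct loci sharing one precursor ID, with their matures
  seqd <- paste0("UUAG", strrep("CUAG", 4L), "UU")
  pre <- data.frame(
    precursor_id = c("mir-4477a", "mir-4477a"),
    name = c("mir-4477a", "mir-4477a"),
    chrom = c("chr9", "chr2"),
    start = c(1000L, 4000L), end = c(1090L, 4090L),
    strand = c("+", "+"), stringsAsFactors = FALSE
  )
  mat <- data.frame(
    mature_id = c("m1", "m2"), name = c("m1", "m2"),
    sequence = c(seqd, seqd),
    precursor_id = c("mir-4477a", "mir-4477a"),
    chrom = c("chr9", "chr2"),
    start = c(1010L, 4010L), end = c(1032L, 4032L),
    strand = c("+", "+"), stringsAsFactors = FALSE
  )
  fixed <- correct_duplicate_ids(mir_annotation(mat, pre))
  # chr2 sorts before chr9, so the chr2 locus takes -1
  expect_setequal(fixed$precursors$precursor_id, c("mir-4477a-1", "mir-4477a-2"))
  expect_identical(
    fixed$precursors$precursor_id[fixed$precursors$chrom == "chr2"],
    "mir-4477a-1")
  expect_identical(
    fixed$matures$precursor_id[fixed$matures$chrom == "chr9"],
    "mir-4477a-2")
})

test_that("three same-ID loci are suffixed in (chrom, start) order", {
  pre <- data.frame(
    precursor_id = rep("mir-10401", 3L), name = rep("mir-10401", 3L),
    chrom = c("chr3", "chr1", "chr1"),
    start = c(100L, 900L, 200L), end = c(200L, 1000L, 300L),
    strand = "+", stringsAsFactors = FALSE
  )
  mat <- data.frame(
    mature_id = paste0("m", 1:3), name = paste0("m", 1:3),
    sequence = rep(strrep("ACGU", 5L), 3L),
    precursor_id = rep("mir-10401", 3L),
    chrom = pre$chrom, start = pre$start + 10L, end = pre$start + 30L,
    strand = "+", stringsAsFactors = FALSE
  )
  fixed <- correct_duplicate_ids(mir_annotation(mat, pre))
  # brute-force expected order: (chr1,200) < (chr1,900) < (chr3,100)
  o <- order(pre$chrom, pre$start)
  expected <- character(3L)
  expected[o] <- paste0("mir-10401-", 1:3)
  expect_identical(fixed$precursors$precursor_id, expected)
})

test_that("locus index queries equal a brute-force linear scan", {
  ann <- tiny_annotation()
  idx <- build_locus_index(ann)

  exact <- query_index(idx, "chrT", 100L, 122L, "+")
  expect_identical(exact$mature_id, "mat-a-5p")
  expect_identical(nrow(query_index(idx, "chrT", 100L, 122L, "-")), 0L)

  set.seed(7)
  big <- simulate_annotation(n_mirnas = 40L, n_paralog_groups = 4L,
                             n_decoy_groups = 2L, seed = 7)
  bidx <- build_locus_index(big)
  chroms <- unique(big$matures$chrom)
  for (i in 1:300) {
    ch <- sample(chroms, 1L)
    s <- sample.int(12000L, 1L)
    e <- s + sample.int(60L, 1L)
    st <- sample(c("+", "-"), 1L)
    got <- query_index(bidx, ch, s, e, st)
    want <- bf_query(big$matures, ch, s, e, st)
    expect_identical(rownames(got), rownames(want))
  }
})

test_that("isoform remapping assigns by bounded minimal deviation and conserves mass", {
  ann <- tiny_annotation()
  # internal locus 100..122 in the 1-based half-open dialect is 101..123
  rec <- data.frame(
    sample_id = "s1", chrom = "chrT",
    start = c(101L, 103L, 104L), end = c(123L, 125L, 125L),
    strand = "+", read_count = c(10L, 5L, 3L), stringsAsFactors = FALSE
  )
  cm <- remap_isoforms(rec, ann, max_dev = 4L, convention = "tcga")
  rep <- attr(cm, "report")
  # exact record: deviation 0; |+2|+|+2| = 4 assigned; |+3|+|+2| = 5 dropped
  expect_identical(rep$assignments$deviation[1:2], c(0L, 4L))
  expect_identical(rep$assignments$status[3], "no_match")
  expect_identical(cm$values["mat-a-5p", "s1"], 15L)
  expect_identical(rep$assigned_reads + rep$dropped_reads, sum(rec$read_count))
  expect_error(remap_isoforms(rec, ann, max_dev = -1), "non-negative")
})

test_that("remapping matches an exhaustive deviation scan on random records", {
  ann <- simulate_annotation(n_mirnas = 30L, n_paralog_groups = 3L,
                             n_decoy_groups = 0L, seed = 13)
  m <- ann$matures
  set.seed(14)
  picks <- sample.int(nrow(m), 50L, replace = TRUE)
  rec <- data.frame(
    sample_id = "s1",
    chrom = m$chrom[picks],
    start = m$start[picks] + sample(-6:6, 50L, replace = TRUE),
    end = m$end[picks] + sample(-6:6, 50L, replace = TRUE),
    strand = m$strand[picks],
    read_count = sample.int(20L, 50L, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rec <- rec[rec$start < rec$end, ]
  cm <- remap_isoforms(rec, ann, max_dev = 4L, convention = "internal")
  got <- attr(cm, "report")$assignments

  for (i in seq_len(nrow(rec))) {
    bf <- bf_deviation_match(m, rec$chrom[i], rec$start[i], rec$end[i],
                             rec$strand[i], 4L)
    if (nrow(bf) == 0L) {
      expect_identical(got$status[i], "no_match")
    } else {
      best_ids <- unique(bf$mature_id[bf$deviation == min(bf$deviation)])
      if (length(best_ids) > 1L) {
        expect_identical(got$status[i], "ambiguous_tie")
      } else {
        expect_identical(got$assigned_mature_id[i], best_ids)
        expect_identical(got$deviation[i], min(bf$deviation))
      }
    }
  }
  expect_identical(
    attr(cm, "report")$assigned_reads + attr(cm, "report")$dropped_reads,
    sum(rec$read_count))
})
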