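# Read-to-mature-miRNA counting: coordinate-deviation matching with
# terminal-mismatch trimming, multi-mapper rescue, and sample-level QC.

#' Construct a mature-miRNA count matrix
#'
#' @param values non-negative integer matrix, rows = `mature_id`,
#'   columns = `sample_id`.
#' @return Object of class `mir_counts`: the matrix plus `lib_sizes`
#'   (column sums of assigned reads).
#' @export
mir_count_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("count matrix needs mature_id rownames and sample_id colnames")
  }
  if (any(values < 0)) stop("counts must be non-negative")
  storage.mode(values) <- "integer"
  structure(list(values = values, lib_sizes = colSums(values)),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat("mir_counts: ", nrow(x$values), " matures x ", ncol(x$values),
      " samples; median library size ",
      stats::median(x$lib_sizes), "\n", sep = "")
  invisible(x)
}

# ---- alignment input -------------------------------------------------------

# Parse an MD tag into the lengths of the terminal mismatch runs along the
# reference (left run, right run). Deletions terminate a run.
md_terminal_mismatches <- function(md) {
  if (is.na(md) || !nzchar(md)) return(c(0L, 0L))
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  run <- function(tk) {
    n <- 0L
    for (t in tk) {
      if (grepl("^\\d+$", t)) {
        if (as.integer(t) > 0L) break else next
      }
      if (startsWith(t, "^")) break  # deletion
      n <- n + 1L
    }
    n
  }
  c(run(toks), run(rev(toks)))
}

#' Read alignment records from a SAM or BAM file
#'
#' Converts each mapped alignment into the tabular record the quantifier
#' consumes. The interval is the reference span of the alignment
#' (internal 0-based half-open); soft-clipped bases never consume
#' reference and so are already outside it, which is how non-templated
#' terminal additions reported as soft clips drop out of the coordinate
#' comparison. Terminal mismatch runs are taken from the MD tag when
#' present (`n_clip_start`/`n_clip_end`, genomic left/right) so that
#' NTAs absorbed into the alignment as end mismatches can be trimmed
#' before deviation is computed.
#'
#' @param path SAM (text) or BAM file.
#' @return data.frame of alignment records: `read_id`, `chrom`, `start`,
#'   `end`, `strand`, `n_clip_start`, `n_clip_end`, `edit_ops`,
#'   `n_alignments` (alignments per read in the file).
#' @export
read_sam_alignments <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar"),
    tag = c("MD", "NM"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_clip_start = integer(), n_clip_end = integer(),
                      edit_ops = integer(), n_alignments = integer()))
  }
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  md <- if (!is.null(res$tag$MD)) res$tag$MD else rep(NA_character_, n)
  nm <- if (!is.null(res$tag$NM)) res$tag$NM else rep(NA_integer_, n)
  runs <- t(vapply(md, md_terminal_mismatches, integer(2)))
  out <- data.frame(
    read_id = res$qname,
    chrom = as.character(res$rname),
    start = res$pos - 1L,           # SAM POS is 1-based
    end = res$pos - 1L + ref_width,
    strand = as.character(res$strand),
    n_clip_start = runs[, 1],
    n_clip_end = runs[, 2],
    edit_ops = ifelse(is.na(nm), 0L, as.integer(nm)),
    stringsAsFactors = FALSE
  )
  out$n_alignments <- as.integer(table(out$read_id)[out$read_id])
  rownames(out) <- NULL
  out
}

# ---- matching --------------------------------------------------------------

# effective (trimmed) interval of alignment records
effective_interval <- function(aln) {
  list(start = aln$start + aln$n_clip_start,
       end = aln$end - aln$n_clip_end)
}

#' Match one alignment to mature loci by bounded coordinate deviation
#'
#' The alignment's effective interval — its reference span after trimming
#' the terminal mismatch runs at both ends, which represent non-templated
#' additions rather than genuine end shifts — is compared to every mature
#' locus on the same chromosome and strand. Candidates whose total
#' deviation |dStart| + |dEnd| is at most `max_dev` are returned sorted
#' by deviation.
#'
#' @param aln one alignment record (single-row data.frame or list with
#'   fields `chrom`, `start`, `end`, `strand`, `n_clip_start`,
#'   `n_clip_end`).
#' @param index a [build_locus_index()] object.
#' @param max_dev maximum total deviation in nt (default 4).
#' @return data.frame of candidate loci with a `deviation` column,
#'   sorted by increasing deviation.
#' @export
match_alignment <- function(aln, index, max_dev = 4L) {
  stopifnot(inherits(index, "mir_locus_index"))
  eff <- effective_interval(aln)
  dev <- locus_deviations(index$matures, aln$chrom, eff$start, eff$end,
                          aln$strand)
  ok <- which(!is.na(dev) & dev <= max_dev)
  out <- index$matures[ok, , drop = FALSE]
  out$deviation <- dev[ok]
  out[order(out$deviation, out$mature_id), , drop = FALSE]
}

# Vectorized matching of many alignment records against the index: one
# findOverlaps call on max_dev-expanded effective intervals, then exact
# deviation filtering. Returns a data.frame (aln_row, locus_row, deviation,
# mature_id, sequence).
match_alignments_bulk <- function(aln, index, max_dev = 4L) {
  n <- nrow(aln)
  if (n == 0L) {
    return(data.frame(aln_row = integer(), locus_row = integer(),
                      deviation = integer(), mature_id = character(),
                      sequence = character()))
  }
  eff <- effective_interval(aln)
  q <- GenomicRanges::GRanges(
    seqnames = aln$chrom,
    ranges = IRanges::IRanges(start = pmax(eff$start - max_dev, 0L) + 1L,
                              end = eff$end + max_dev),
    strand = aln$strand
  )
  hits <- GenomicRanges::findOverlaps(q, index$granges, ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dev <- abs(index$matures$start[si] - eff$start[qi]) +
    abs(index$matures$end[si] - eff$end[qi])
  keep <- dev <= max_dev
  data.frame(aln_row = qi[keep], locus_row = si[keep],
             deviation = as.integer(dev[keep]),
             mature_id = index$matures$mature_id[si[keep]],
             sequence = index$matures$sequence[si[keep]],
             stringsAsFactors = FALSE)
}

# ---- per-read resolution ---------------------------------------------------

# core rule shared by resolve_read and quantify_sample, on plain vectors:
# m_aln (local alignment index per match row), m_dev, m_id, m_seq
resolve_group <- function(n_aln, m_aln, m_dev, m_id, m_seq) {
  if (n_aln == 0L) stop("empty alignment group")

  if (n_aln == 1L) {
    if (length(m_aln) == 0L) {
      return(list(status = "unannotated", mature_id = NA_character_,
                  total_deviation = NA_integer_))
    }
    best <- min(m_dev)
    ids <- unique(m_id[m_dev == best])
    if (length(ids) == 1L) {
      return(list(status = "assigned", mature_id = ids,
                  total_deviation = as.integer(best)))
    }
    # deviation tie between distinct matures: rescue only if they are one
    # sequence (boundary paralogs), otherwise discard
    seqs <- unique(m_seq[m_dev == best])
    if (length(seqs) == 1L && !anyNA(seqs)) {
      return(list(status = "assigned", mature_id = min(ids),
                  total_deviation = as.integer(best)))
    }
    return(list(status = "ambiguous_discard", mature_id = NA_character_,
                total_deviation = NA_integer_))
  }

  # multi-mapper: every alignment must land on annotation, and all matched
  # matures must share one identical mature sequence
  if (length(unique(m_aln)) < n_aln) {
    return(list(status = "ambiguous_discard", mature_id = NA_character_,
                total_deviation = NA_integer_))
  }
  seqs <- unique(m_seq)
  if (length(seqs) == 1L && !anyNA(seqs)) {
    list(status = "assigned", mature_id = min(unique(m_id)),
         total_deviation = as.integer(min(m_dev)))
  } else {
    list(status = "ambiguous_discard", mature_id = NA_character_,
         total_deviation = NA_integer_)
  }
}

#' Resolve all alignments of one read to a single assignment
#'
#' A unique mapper is assigned to the mature locus it matches (minimal
#' deviation; a deviation tie between distinct matures is discarded
#' unless the tied matures carry one identical sequence). A read with no
#' matching annotation is `unannotated`. A multi-mapping read is rescued
#' — counted once — only when every one of its alignments matches an
#' annotated mature locus and all matched matures share one identical
#' mature sequence; the count goes to the lexicographically smallest
#' `mature_id`. Anything else is `ambiguous_discard`.
#'
#' @param group data.frame of alignment records sharing one `read_id`.
#' @param index a [build_locus_index()] object.
#' @param max_dev maximum total deviation in nt (default 4).
#' @return list with `read_id`, `status` (`assigned` / `unannotated` /
#'   `ambiguous_discard`), `mature_id`, `total_deviation`.
#' @export
resolve_read <- function(group, index, max_dev = 4L) {
  group <- as.data.frame(group)
  if (nrow(group) == 0L) stop("empty alignment group")
  if (length(unique(group$read_id)) != 1L) {
    stop("alignment group must share one read_id")
  }
  matches <- match_alignments_bulk(group, index, max_dev)
  res <- resolve_group(nrow(group), matches$aln_row, matches$deviation,
                       matches$mature_id, matches$sequence)
  c(list(read_id = group$read_id[1L]), res)
}

#' Quantify one sample from its alignment records
#'
#' Groups a name-grouped alignment stream by `read_id`, resolves each
#' read with the deviation-bounded assignment and multi-mapper rescue
#' rules, and returns per-mature counts (each read counted at most once)
#' plus a QC report. Samples with fewer than `min_reads` distinct reads
#' are flagged for exclusion.
#'
#' @param alignments data.frame of alignment records (see
#'   [read_sam_alignments()]); records of one read must be contiguous.
#' @param ann a corrected [mir_annotation()] object.
#' @param index optional prebuilt [build_locus_index()]; built from `ann`
#'   when `NULL`.
#' @param max_dev maximum total deviation in nt (default 4).
#' @param min_reads QC threshold on total distinct reads (default 500000).
#' @return list with `counts` (named integer vector over all mature IDs)
#'   and `qc` (totals of assigned / unannotated / discarded reads,
#'   `n_reads`, `below_threshold`).
#' @export
quantify_sample <- function(alignments, ann, index = NULL, max_dev = 4L,
                            min_reads = 500000L) {
  stopifnot(inherits(ann, "mir_annotation"))
  if (is.null(index)) index <- build_locus_index(ann)
  alignments <- as.data.frame(alignments)
  ids <- sort(unique(ann$matures$mature_id))
  counts <- stats::setNames(integer(length(ids)), ids)

  if (nrow(alignments) == 0L) {
    qc <- list(n_reads = 0L, assigned = 0L, unannotated = 0L, discarded = 0L,
               below_threshold = TRUE, min_reads = min_reads)
    return(list(counts = counts, qc = qc))
  }
  r <- rle(alignments$read_id)
  if (anyDuplicated(r$values)) {
    stop("alignment stream is not grouped by read name; ",
         "sort the input by read name (e.g. samtools sort -n) first")
  }
  grp <- rep(seq_along(r$values), r$lengths)
  matches <- match_alignments_bulk(alignments, index, max_dev)
  first_row <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  match_grp <- grp[matches$aln_row]
  grp_fac <- factor(match_grp, levels = seq_along(r$values))
  by_aln <- split(matches$aln_row, grp_fac)
  by_dev <- split(matches$deviation, grp_fac)
  by_id <- split(matches$mature_id, grp_fac)
  by_seq <- split(matches$sequence, grp_fac)

  status <- character(length(r$values))
  for (g in seq_along(r$values)) {
    res <- resolve_group(r$lengths[g], by_aln[[g]] - first_row[g],
                         by_dev[[g]], by_id[[g]], by_seq[[g]])
    status[g] <- res$status
    if (res$status == "assigned") {
      counts[res$mature_id] <- counts[res$mature_id] + 1L
    }
  }
  n_reads <- length(r$values)
  qc <- list(
    n_reads = n_reads,
    assigned = sum(status == "assigned"),
    unannotated = sum(status == "unannotated"),
    discarded = sum(status == "ambiguous_discard"),
    below_threshold = n_reads < min_reads,
    min_reads = min_reads
  )
  list(counts = counts, qc = qc)
}

#' Quantify several samples into one count matrix
#'
#' @param sample_alignments named list of per-sample alignment record
#'   data.frames (names are sample IDs).
#' @param ann a corrected [mir_annotation()] object.
#' @param ... passed to [quantify_sample()].
#' @return list with `counts` (a [mir_count_matrix()] over retained
#'   samples), `qc` (per-sample QC list) and `excluded` (sample IDs
#'   flagged below the read threshold).
#' @export
quantify_cohort <- function(sample_alignments, ann, ...) {
  stopifnot(is.list(sample_alignments), !is.null(names(sample_alignments)))
  index <- build_locus_index(ann)
  per <- lapply(sample_alignments, quantify_sample, ann = ann, index = index, ...)
  mat <- do.call(cbind, lapply(per, `[[`, "counts"))
  colnames(mat) <- names(sample_alignments)
  qc <- lapply(per, `[[`, "qc")
  excluded <- names(per)[vapply(qc, `[[`, logical(1), "below_threshold")]
  keep <- setdiff(colnames(mat), excluded)
  if (length(keep) == 0L) stop("all samples fall below the read threshold")
  list(counts = mir_count_matrix(mat[, keep, drop = FALSE]),
       qc = qc, excluded = excluded)
}
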