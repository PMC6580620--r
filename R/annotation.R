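# miRNA annotation: parsing, correction, indexing and cross-version
# isoform remapping.
#
# An annotation set holds mature miRNAs (each possibly at several genomic
# loci, as for paralogous precursors encoding one mature sequence) and their
# precursor hairpins. All coordinates are internal 0-based half-open.

#' Construct an annotation set
#'
#' @param matures data.frame with one row per mature locus: columns
#'   `mature_id`, `name`, `sequence` (RNA alphabet, uppercase; may be `NA`
#'   when the source carries no sequences), `precursor_id`, `chrom`,
#'   `start`, `end`, `strand` (internal 0-based half-open coordinates).
#' @param precursors data.frame with columns `precursor_id`, `name`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param version_tag free-text annotation version label, e.g. `"miRBase22"`.
#' @return An object of class `mir_annotation`.
#' @export
mir_annotation <- function(matures, precursors, version_tag = "unversioned") {
  req_m <- c("mature_id", "name", "sequence", "precursor_id",
             "chrom", "start", "end", "strand")
  req_p <- c("precursor_id", "name", "chrom", "start", "end", "strand")
  stopifnot(all(req_m %in% names(matures)), all(req_p %in% names(precursors)))
  matures <- as.data.frame(matures)[req_m]
  precursors <- as.data.frame(precursors)[req_p]
  check_strand(matures$strand)
  check_strand(precursors$strand)
  if (any(matures$start >= matures$end) || any(precursors$start >= precursors$end)) {
    stop("invalid interval: start must precede end")
  }
  has_seq <- !is.na(matures$sequence)
  if (any(has_seq)) {
    len <- nchar(matures$sequence[has_seq])
    if (any(len < 14L)) stop("mature sequences must be at least 14 nt")
    width <- matures$end[has_seq] - matures$start[has_seq]
    if (any(width != len)) {
      stop("mature locus width must equal sequence length for: ",
           paste(unique(matures$mature_id[has_seq][width != len]), collapse = ", "))
    }
  }
  missing_pre <- setdiff(matures$precursor_id, precursors$precursor_id)
  if (length(missing_pre)) {
    stop("mature features reference unknown precursors: ",
         paste(missing_pre, collapse = ", "))
  }
  # one mature_id, several loci is legitimate (paralogs); but the sequence
  # must then be the one sequence that identity implies
  if (any(has_seq)) {
    nseq <- tapply(matures$sequence[has_seq], matures$mature_id[has_seq],
                   function(s) length(unique(s)))
    if (any(nseq > 1L)) {
      stop("mature_id with conflicting sequences (run correct_duplicate_ids): ",
           paste(names(nseq)[nseq > 1L], collapse = ", "))
    }
  }
  structure(
    list(matures = matures, precursors = precursors, version_tag = version_tag),
    class = "mir_annotation"
  )
}

#' @export
print.mir_annotation <- function(x, ...) {
  cat("mir_annotation [", x$version_tag, "]: ",
      length(unique(x$matures$mature_id)), " matures at ",
      nrow(x$matures), " loci, ",
      nrow(x$precursors), " precursors\n", sep = "")
  invisible(x)
}

# validate raw GFF3 lines before handing the file to rtracklayer, so that a
# malformed attribute column is reported with its line number
validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      stop("malformed GFF3 record at line ", i, ": expected 9 tab-separated fields")
    }
    attrs <- strsplit(fields[9], ";", fixed = TRUE)[[1]]
    attrs <- attrs[nzchar(trimws(attrs))]
    if (!all(grepl("=", attrs, fixed = TRUE))) {
      stop("malformed attribute at line ", i, ": expected key=value pairs")
    }
  }
  invisible(lines)
}

#' Parse a miRBase-dialect GFF3 annotation
#'
#' Reads `miRNA_primary_transcript` (precursor) and `miRNA` (mature)
#' features; matures are attached to their precursor via the
#' `Derives_from` attribute. GFF3 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention. An optional
#' `sequence` attribute on mature features (emitted by
#' [write_mirbase_gff3()] and the synthetic generator) supplies mature
#' sequences; real miRBase files carry none, in which case sequences are
#' `NA` and sequence-dependent rules degrade explicitly.
#'
#' @param path GFF3 file path.
#' @param version_tag version label stored on the result.
#' @return A [mir_annotation()] object.
#' @export
parse_mirbase_gff3 <- function(path, version_tag = "miRBase22") {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  pre <- gr[type == "miRNA_primary_transcript"]
  mat <- gr[type == "miRNA"]
  if (length(pre) == 0L && length(mat) == 0L) {
    stop("no miRNA_primary_transcript or miRNA features found in ", path)
  }
  precursors <- data.frame(
    precursor_id = as.character(pre$ID),
    name = as.character(pre$Name),
    chrom = as.character(GenomeInfoDb::seqnames(pre)),
    start = GenomicRanges::start(pre) - 1L,  # 1-based inclusive -> internal
    end = GenomicRanges::end(pre),
    strand = as.character(GenomicRanges::strand(pre)),
    stringsAsFactors = FALSE
  )
  derives <- as.character(mat$Derives_from)
  unknown <- setdiff(derives, precursors$precursor_id)
  if (length(unknown)) {
    stop("mature feature(s) with unknown Derives_from: ",
         paste(unique(unknown), collapse = ", "))
  }
  seq_attr <- if (!is.null(mat$sequence)) as.character(mat$sequence) else rep(NA_character_, length(mat))
  matures <- data.frame(
    mature_id = as.character(mat$ID),
    name = as.character(mat$Name),
    sequence = toupper(seq_attr),
    precursor_id = derives,
    chrom = as.character(GenomeInfoDb::seqnames(mat)),
    start = GenomicRanges::start(mat) - 1L,
    end = GenomicRanges::end(mat),
    strand = as.character(GenomicRanges::strand(mat)),
    stringsAsFactors = FALSE
  )
  mir_annotation(matures, precursors, version_tag)
}

#' Write an annotation set as miRBase-dialect GFF3
#'
#' Emits precursors as `miRNA_primary_transcript` and matures as `miRNA`
#' features with `ID`/`Name`/`Derives_from` attributes; mature sequences,
#' when present, are stored in a `sequence` attribute so that
#' [parse_mirbase_gff3()] round-trips the set. Internal coordinates are
#' converted back to GFF3 1-based inclusive.
#'
#' @param ann a [mir_annotation()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mirbase_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "mir_annotation"))
  p <- ann$precursors
  m <- ann$matures
  pre_lines <- sprintf(
    "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    p$chrom, p$start + 1L, p$end, p$strand, p$precursor_id, p$name
  )
  seq_part <- ifelse(is.na(m$sequence), "", sprintf(";sequence=%s", m$sequence))
  mat_lines <- sprintf(
    "%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s%s",
    m$chrom, m$start + 1L, m$end, m$strand, m$mature_id, m$name,
    m$precursor_id, seq_part
  )
  writeLines(c("##gff-version 3", pre_lines, mat_lines), path)
  invisible(path)
}

# deterministic -1, -2, ... suffixing of an ID vector grouped by locus order
suffix_in_coord_order <- function(ids, chrom, start) {
  out <- ids
  for (id in unique(ids[duplicated(ids)])) {
    sel <- which(ids == id)
    ord <- sel[order(chrom[sel], start[sel])]
    out[ord] <- paste0(id, "-", seq_along(ord))
  }
  out
}

#' Correct duplicate identifiers assigned to distinct loci
#'
#' miRBase release 22 assigned identical IDs to distinct primary miRNA
#' loci (mir-4477a, mir-4477b, mir-10401). Any precursor ID shared by
#' features at distinct genomic loci is disambiguated with a
#' deterministic `-1`, `-2`, ... suffix in (chrom, start) coordinate
#' order; mature features are re-attached to the suffixed precursor that
#' contains their locus. A mature ID shared by loci with *different*
#' sequences is disambiguated the same way (identical-sequence
#' multi-locus matures are legitimate paralogs and kept as one entity).
#' Sets with all-unique IDs are returned unchanged.
#'
#' @param ann a [mir_annotation()] object.
#' @return A corrected [mir_annotation()] object.
#' @export
correct_duplicate_ids <- function(ann) {
  stopifnot(inherits(ann, "mir_annotation"))
  p <- ann$precursors
  m <- ann$matures

  # precursors: same ID at >1 distinct locus
  locus_key <- paste(p$chrom, p$start, p$end, p$strand)
  n_loci <- tapply(locus_key, p$precursor_id, function(k) length(unique(k)))
  dup_pre <- names(n_loci)[n_loci > 1L]
  if (length(dup_pre)) {
    affected <- p$precursor_id %in% dup_pre
    new_pre_id <- p$precursor_id
    new_pre_id[affected] <- suffix_in_coord_order(
      p$precursor_id[affected], p$chrom[affected], p$start[affected]
    )
    # re-attach matures of a duplicated precursor by locus containment
    for (i in which(m$precursor_id %in% dup_pre)) {
      cand <- which(affected &
                      p$chrom == m$chrom[i] & p$strand == m$strand[i] &
                      p$start <= m$start[i] & p$end >= m$end[i] &
                      p$precursor_id == m$precursor_id[i])
      if (length(cand) == 0L) {
        stop("mature ", m$mature_id[i], " not contained in any locus of its ",
             "duplicated precursor ", m$precursor_id[i])
      }
      m$precursor_id[i] <- new_pre_id[cand[1L]]
    }
    p$precursor_id <- new_pre_id
  }

  # matures: same ID with conflicting sequences (or, sequence-free
  # annotations: same ID at distinct loci under distinct precursors is kept,
  # since paralogy cannot be ruled out without sequences)
  has_seq <- !is.na(m$sequence)
  if (any(has_seq)) {
    nseq <- tapply(m$sequence[has_seq], m$mature_id[has_seq],
                   function(s) length(unique(s)))
    dup_mat <- names(nseq)[nseq > 1L]
    if (length(dup_mat)) {
      affected <- m$mature_id %in% dup_mat
      m$mature_id[affected] <- suffix_in_coord_order(
        m$mature_id[affected], m$chrom[affected], m$start[affected]
      )
    }
  }
  mir_annotation(m, p, ann$version_tag)
}

#' Build an interval index over mature miRNA loci
#'
#' Wraps the mature loci in a `GRanges` so that overlap queries run in
#' O(log n + hits) via the interval-tree machinery behind
#' [GenomicRanges::findOverlaps()]. Each locus of a multi-locus mature is
#' indexed independently; hits carry the owning `mature_id`.
#'
#' @param ann a corrected [mir_annotation()] object.
#' @return An object of class `mir_locus_index`.
#' @export
build_locus_index <- function(ann) {
  stopifnot(inherits(ann, "mir_annotation"))
  m <- ann$matures
  gr <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    # internal half-open -> IRanges 1-based inclusive
    ranges = IRanges::IRanges(start = m$start + 1L, end = m$end),
    strand = m$strand
  )
  structure(list(granges = gr, matures = m), class = "mir_locus_index")
}

#' Query a locus index
#'
#' Returns all mature loci overlapping the query interval on the same
#' strand.
#'
#' @param index a [build_locus_index()] object.
#' @param chrom,start,end query interval (internal 0-based half-open).
#' @param strand `"+"` or `"-"`; strand matching is mandatory.
#' @return The matching rows of the annotation's mature-locus table.
#' @export
query_index <- function(index, chrom, start, end, strand) {
  stopifnot(inherits(index, "mir_locus_index"))
  check_strand(strand)
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
  hits <- GenomicRanges::findOverlaps(q, index$granges, ignore.strand = FALSE)
  index$matures[S4Vectors::subjectHits(hits), , drop = FALSE]
}

# total coordinate deviation |delta start| + |delta end| between an interval
# and each row of a locus table restricted to same chrom/strand
locus_deviations <- function(matures, chrom, start, end, strand) {
  same <- matures$chrom == chrom & matures$strand == strand
  dev <- rep(NA_integer_, nrow(matures))
  dev[same] <- abs(matures$start[same] - start) + abs(matures$end[same] - end)
  dev
}

#' Remap isoform records onto a target annotation
#'
#' Cross-version remapping of mature-miRNA isoform quantifications: each
#' record's interval, converted from its source coordinate dialect, is
#' matched to the target mature loci on the same strand allowing a total
#' coordinate deviation |dStart| + |dEnd| of at most `max_dev` nt. A
#' record matching several loci goes to the minimal-deviation locus;
#' deviation ties are dropped (and reported) rather than split. Records
#' matching nothing are dropped and reported. Read counts are conserved:
#' assigned + dropped = input total.
#'
#' @param records data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `strand`, `read_count` and optionally `source_mature_id`.
#' @param target a corrected [mir_annotation()] object (the remap target).
#' @param max_dev maximum total coordinate deviation in nt (default 4).
#' @param convention the records' coordinate dialect: `"tcga"` (1-based
#'   half-open), `"gff3"` (1-based inclusive) or `"internal"`.
#' @return A [mir_count_matrix()] with one column per `sample_id`;
#'   attribute `report` holds assigned/dropped read-count totals and the
#'   per-record assignment table.
#' @export
remap_isoforms <- function(records, target, max_dev = 4L,
                           convention = c("tcga", "gff3", "internal")) {
  convention <- match.arg(convention)
  stopifnot(inherits(target, "mir_annotation"))
  if (max_dev < 0) stop("max_dev must be non-negative")
  records <- as.data.frame(records)
  stopifnot(all(c("sample_id", "chrom", "start", "end", "strand", "read_count")
                %in% names(records)))
  if (any(records$read_count < 0)) stop("read_count must be non-negative")
  if (convention != "internal") {
    conv <- to_internal(records$start, records$end, convention)
    records$start <- conv$start
    records$end <- conv$end
  }

  m <- target$matures
  n <- nrow(records)
  assigned_to <- rep(NA_character_, n)
  deviation <- rep(NA_integer_, n)
  status <- rep("no_match", n)
  for (i in seq_len(n)) {
    dev <- locus_deviations(m, records$chrom[i], records$start[i],
                            records$end[i], records$strand[i])
    ok <- which(!is.na(dev) & dev <= max_dev)
    if (length(ok) == 0L) next
    best <- min(dev[ok])
    best_rows <- ok[dev[ok] == best]
    best_ids <- unique(m$mature_id[best_rows])
    if (length(best_ids) > 1L) {
      status[i] <- "ambiguous_tie"
      next
    }
    status[i] <- "assigned"
    assigned_to[i] <- best_ids
    deviation[i] <- best
  }

  samples <- sort(unique(records$sample_id))
  ids <- sort(unique(m$mature_id))
  values <- matrix(0L, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
  hit <- status == "assigned"
  if (any(hit)) {
    agg <- stats::aggregate(records$read_count[hit],
                            by = list(id = assigned_to[hit],
                                      sample = records$sample_id[hit]),
                            FUN = sum)
    values[cbind(agg$id, agg$sample)] <- as.integer(agg$x)
  }
  cm <- mir_count_matrix(values)
  attr(cm, "report") <- list(
    assigned_reads = sum(records$read_count[hit]),
    dropped_reads = sum(records$read_count[!hit]),
    n_no_match = sum(status == "no_match"),
    n_ambiguous_tie = sum(status == "ambiguous_tie"),
    assignments = data.frame(records,
                             assigned_mature_id = assigned_to,
                             deviation = deviation,
                             status = status,
                             stringsAsFactors = FALSE)
  )
  cm
}
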