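# Synthetic-data generators: annotation with paralog and decoy groups,
# alignments with isomiR offsets and non-templated additions,
# subtype-structured expression cohorts, exponential survival records.
# Every generator is seed-deterministic and returns its ground truth.

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a toy miRNA annotation
#'
#' Lays out mature miRNAs (and surrounding precursors) on toy
#' chromosomes, on both strands. `n_paralog_groups` matures receive a
#' second genomic locus with the *identical* mature sequence — the
#' multi-mapper configuration the rescue rule accepts. `n_decoy_groups`
#' pairs of matures get near-identical but *distinct* sequences and are
#' marked as co-alignment groups — multi-mappers the rule must discard.
#'
#' @param n_mirnas number of distinct matures (default 20).
#' @param n_paralog_groups matures with a second identical-sequence
#'   locus (default 2).
#' @param n_decoy_groups decoy pairs with distinct sequences (default
#'   1); consumes 2 matures each.
#' @param mature_len mature length in nt (default 22).
#' @param seed RNG seed.
#' @return A [mir_annotation()] with attributes `sim_groups` (list of
#'   mature-ID sets whose loci are co-alignment targets) and
#'   `chrom_lengths`.
#' @export
simulate_annotation <- function(n_mirnas = 20L, n_paralog_groups = 2L,
                                n_decoy_groups = 1L, mature_len = 22L,
                                seed) {
  stopifnot(n_mirnas >= 2L * n_decoy_groups + n_paralog_groups)
  set.seed(seed)
  chroms <- c("chrS1", "chrS2")
  seqs <- random_rna(n_mirnas, mature_len)

  # decoys: pairs of distinct matures whose sequences differ in one base
  decoy_pairs <- list()
  if (n_decoy_groups > 0L) {
    for (d in seq_len(n_decoy_groups)) {
      a <- 2L * d - 1L
      b <- 2L * d
      s <- strsplit(seqs[a], "")[[1]]
      pos <- sample.int(mature_len, 1L)
      s[pos] <- sample(setdiff(c("A", "C", "G", "U"), s[pos]), 1L)
      seqs[b] <- paste(s, collapse = "")
      decoy_pairs[[d]] <- c(a, b)
    }
  }
  paralog_idx <- if (n_paralog_groups > 0L) {
    (2L * n_decoy_groups + 1L):(2L * n_decoy_groups + n_paralog_groups)
  } else integer()

  mk_id <- function(i) sprintf("sim-mir-%03d", i)
  mat_rows <- list()
  pre_rows <- list()
  cursor <- stats::setNames(rep(1000L, length(chroms)), chroms)
  place <- function(i, suffix = "") {
    chrom <- chroms[(i + nchar(suffix)) %% length(chroms) + 1L]
    start <- cursor[[chrom]]
    cursor[[chrom]] <<- start + 500L
    strand <- if (i %% 2L == 0L) "-" else "+"
    pre_id <- paste0("sim-pre-", sprintf("%03d", i), suffix)
    pre_rows[[length(pre_rows) + 1L]] <<- data.frame(
      precursor_id = pre_id, name = pre_id, chrom = chrom,
      start = start - 20L, end = start + mature_len + 20L, strand = strand,
      stringsAsFactors = FALSE
    )
    mat_rows[[length(mat_rows) + 1L]] <<- data.frame(
      mature_id = mk_id(i), name = mk_id(i), sequence = seqs[i],
      precursor_id = pre_id, chrom = chrom, start = start,
      end = start + mature_len, strand = strand, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n_mirnas)) place(i)
  for (i in paralog_idx) place(i, suffix = "b")  # second locus, same sequence

  matures <- do.call(rbind, mat_rows)
  precursors <- do.call(rbind, pre_rows)
  ann <- mir_annotation(matures, precursors, version_tag = "synthetic")
  groups <- c(
    lapply(paralog_idx, function(i) mk_id(i)),
    lapply(decoy_pairs, function(pr) mk_id(pr))
  )
  attr(ann, "sim_groups") <- groups
  attr(ann, "chrom_lengths") <- stats::setNames(
    vapply(chroms, function(ch) {
      max(c(precursors$end[precursors$chrom == ch], 0L)) + 1000L
    }, integer(1)), chroms)
  ann
}

# loci that reads of a mature align to: its own loci plus the loci of any
# sim-group partners (decoys)
co_alignment_loci <- function(ann, mature_id) {
  ids <- mature_id
  for (g in attr(ann, "sim_groups")) {
    if (mature_id %in% g) ids <- union(ids, g)
  }
  ann$matures[ann$matures$mature_id %in% ids, , drop = FALSE]
}

#' Simulate aligned reads from an annotation
#'
#' Draws reads multinomially from an expression profile over matures.
#' Each read gets independent start/end offsets (a rounded Gaussian with
#' SD `isomir_sd`, truncated at `isomir_max` per end — the isomiR end
#' heterogeneity the deviation rule absorbs) and, with probability
#' `nta_prob`, a 1-3 nt non-templated terminal addition at the 3' end
#' encoded as a terminal mismatch run. Reads from a mature belonging to
#' a paralog or decoy group are emitted with one alignment per group
#' locus (multi-mappers). Output is name-grouped.
#'
#' @param ann a [simulate_annotation()] result.
#' @param profile named non-negative weights over mature IDs (default
#'   uniform over all matures).
#' @param n_reads number of reads.
#' @param isomir_sd SD of the discretized end-offset distribution
#'   (default 0 = exact ends).
#' @param isomir_max truncation of each end offset in nt (default 3).
#' @param nta_prob probability of a terminal addition (default 0).
#' @param sample_id prefix for read names.
#' @param seed RNG seed.
#' @return list: `alignments` (record data.frame as consumed by
#'   [quantify_sample()]), `truth` (per-read source mature, offsets, NTA
#'   length, multimap size), `true_counts` (named per-mature totals).
#' @export
simulate_alignments <- function(ann, profile = NULL, n_reads = 1000L,
                                isomir_sd = 0, isomir_max = 3L,
                                nta_prob = 0, sample_id = "sim",
                                seed) {
  set.seed(seed)
  ids <- sort(unique(ann$matures$mature_id))
  if (is.null(profile)) profile <- stats::setNames(rep(1, length(ids)), ids)
  profile <- profile[intersect(names(profile), ids)]
  stopifnot(length(profile) > 0L, all(profile >= 0))
  src <- sample(names(profile), n_reads, replace = TRUE,
                prob = profile / sum(profile))
  draw_offset <- function(n) {
    if (isomir_sd == 0) return(integer(n))
    off <- as.integer(round(stats::rnorm(n, 0, isomir_sd)))
    pmin(pmax(off, -isomir_max), isomir_max)
  }
  ds <- draw_offset(n_reads)
  de <- draw_offset(n_reads)
  nta <- ifelse(stats::runif(n_reads) < nta_prob,
                sample(1:3, n_reads, replace = TRUE), 0L)

  # locus rows each mature's reads align to (own loci + sim-group partners)
  locus_rows <- lapply(stats::setNames(ids, ids), function(id) {
    which(ann$matures$mature_id %in%
            co_alignment_loci(ann, id)$mature_id)
  })
  rows_per_read <- locus_rows[src]
  n_aln <- lengths(rows_per_read)
  truth <- data.frame(
    read_id = sprintf("%s_r%06d", sample_id, seq_len(n_reads)),
    mature_id = src, d_start = ds, d_end = de, nta_len = nta,
    n_alignments = n_aln, stringsAsFactors = FALSE
  )
  ri <- rep(seq_len(n_reads), n_aln)      # read index per alignment row
  lr <- unlist(rows_per_read, use.names = FALSE)
  m <- ann$matures
  start <- m$start[lr] + ds[ri]
  end <- m$end[lr] + de[ri]
  strand <- m$strand[lr]
  # NTA at the 3' end: genomic right on +, genomic left on -
  plus <- strand == "+"
  n_clip_start <- ifelse(!plus, nta[ri], 0L)
  n_clip_end <- ifelse(plus, nta[ri], 0L)
  start <- start - n_clip_start
  end <- end + n_clip_end
  alignments <- data.frame(
    read_id = truth$read_id[ri], chrom = m$chrom[lr],
    start = start, end = end, strand = strand,
    n_clip_start = as.integer(n_clip_start),
    n_clip_end = as.integer(n_clip_end),
    edit_ops = as.integer(n_clip_start + n_clip_end),
    n_alignments = n_aln[ri], stringsAsFactors = FALSE
  )
  true_counts <- stats::setNames(integer(length(ids)), ids)
  tc <- table(src)
  true_counts[names(tc)] <- as.integer(tc)
  list(alignments = alignments, truth = truth, true_counts = true_counts)
}

#' Write simulated alignment records as SAM text
#'
#' Terminal additions appear as terminal mismatches: the CIGAR is a
#' single match run over the reference span and the MD tag carries the
#' mismatch runs at the ends, so [read_sam_alignments()] round-trips the
#' records.
#'
#' @param alignments record data.frame from [simulate_alignments()].
#' @param chrom_lengths named lengths for the `@SQ` header (e.g.
#'   `attr(ann, "chrom_lengths")`).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:queryname",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  md_for <- function(a, mid, b) {
    paste0(paste(rep("0A", a), collapse = ""), mid,
           paste(rep("A0", b), collapse = ""))
  }
  w <- alignments$end - alignments$start
  md <- mapply(md_for, alignments$n_clip_start,
               w - alignments$n_clip_start - alignments$n_clip_end,
               alignments$n_clip_end)
  body <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*\tNM:i:%d\tMD:Z:%s",
    alignments$read_id,
    ifelse(alignments$strand == "-", 16L, 0L),
    alignments$chrom,
    alignments$start + 1L,
    w,
    alignments$n_clip_start + alignments$n_clip_end,
    md
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a subtype-structured expression cohort
#'
#' Per-subtype centroids on the log2 scale: a shared baseline plus a
#' `marker_shift` upshift of each subtype's own marker block. Samples
#' are centroid plus i.i.d. Gaussian noise. This is the structure the
#' signature, clustering and nearest-centroid stages assume.
#'
#' @param subtypes subtype names (default the four intrinsic groups).
#' @param n_per_subtype samples per subtype (scalar or vector).
#' @param n_features total features (default 200).
#' @param n_markers markers per subtype (default 15).
#' @param marker_shift upshift of a subtype's markers in log2 units
#'   (default 3).
#' @param sigma per-feature noise SD in log2 units (default 1).
#' @param seed RNG seed.
#' @return list: `expr` (feature x sample matrix), `labels`,
#'   `centroids` (feature x subtype), `markers` (per-subtype ID list).
#' @export
simulate_cohort <- function(subtypes = c("Basal", "Her2", "LumA", "LumB"),
                            n_per_subtype = 25L, n_features = 200L,
                            n_markers = 15L, marker_shift = 3,
                            sigma = 1, seed) {
  set.seed(seed)
  ns <- length(subtypes)
  stopifnot(n_features >= ns * n_markers)
  if (length(n_per_subtype) == 1L) n_per_subtype <- rep(n_per_subtype, ns)
  feats <- sprintf("sim-mir-%03d", seq_len(n_features))
  baseline <- stats::rnorm(n_features, mean = 5, sd = 2)
  centroids <- matrix(baseline, n_features, ns,
                      dimnames = list(feats, subtypes))
  markers <- list()
  for (i in seq_len(ns)) {
    idx <- ((i - 1L) * n_markers + 1L):(i * n_markers)
    centroids[idx, i] <- centroids[idx, i] + marker_shift
    markers[[subtypes[i]]] <- feats[idx]
  }
  labels <- rep(subtypes, n_per_subtype)
  expr <- matrix(NA_real_, n_features, length(labels),
                 dimnames = list(feats, sprintf("sample_%03d", seq_along(labels))))
  for (j in seq_along(labels)) {
    expr[, j] <- centroids[, labels[j]] + stats::rnorm(n_features, 0, sigma)
  }
  list(expr = expr, labels = stats::setNames(labels, colnames(expr)),
       centroids = centroids, markers = markers)
}

#' Simulate exponential survival records with a group effect
#'
#' Event times are exponential with hazard `baseline_hazard` in the
#' first group and `baseline_hazard * hazard_ratio` in the others;
#' censoring is an independent exponential with rate `censor_rate`
#' (0 = no censoring).
#'
#' @param groups per-sample group labels (first sorted level is the
#'   reference hazard).
#' @param baseline_hazard reference-group hazard rate (events per unit
#'   time).
#' @param hazard_ratio multiplicative hazard of the non-reference
#'   groups (default 1).
#' @param censor_rate exponential censoring rate (default 0).
#' @param seed RNG seed.
#' @return data.frame: `sample_id`, `group`, `time`, `event`.
#' @export
simulate_survival <- function(groups, baseline_hazard = 0.1,
                              hazard_ratio = 1, censor_rate = 0, seed) {
  set.seed(seed)
  groups <- as.character(groups)
  ref <- sort(unique(groups))[1L]
  hazard <- ifelse(groups == ref, baseline_hazard,
                   baseline_hazard * hazard_ratio)
  t_event <- stats::rexp(length(groups), rate = hazard)
  t_cens <- if (censor_rate > 0) {
    stats::rexp(length(groups), rate = censor_rate)
  } else {
    rep(Inf, length(groups))
  }
  data.frame(
    sample_id = if (!is.null(names(groups))) names(groups)
                else sprintf("sample_%03d", seq_along(groups)),
    group = groups,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
}
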