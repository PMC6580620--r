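# Shared fixtures and independent brute-force oracles. Oracles implement
# the rules from first principles (linear scans, closed forms) and are
# kept free of the package's own code paths.

rna <- function(s) toupper(gsub("T", "U", s))

# tiny hand-built annotation: three single-locus matures on both strands
# plus one two-locus paralog with an identical sequence
tiny_annotation <- function() {
  seq22a <- strrep("ACGU", 5L)          # 20 nt
  seq22a <- paste0(seq22a, "AC")        # 22 nt
  seq22b <- paste0("GGCA", strrep("UGCA", 4L), "GG")  # 22 nt
  seq20c <- strrep("CAGU", 5L)          # 20 nt
  seq22d <- paste0("UUAG", strrep("CUAG", 4L), "UU")  # 22 nt
  precursors <- data.frame(
    precursor_id = c("pre-a", "pre-b", "pre-c", "pre-d1", "pre-d2"),
    name = c("pre-a", "pre-b", "pre-c", "pre-d1", "pre-d2"),
    chrom = c("chrT", "chrT", "chrT", "chrT", "chrU"),
    start = c(80L, 480L, 880L, 1480L, 280L),
    end = c(160L, 560L, 960L, 1560L, 360L),
    strand = c("+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE
  )
  matures <- data.frame(
    mature_id = c("mat-a-5p", "mat-b-5p", "mat-c-3p", "mat-d", "mat-d"),
    name = c("mat-a-5p", "mat-b-5p", "mat-c-3p", "mat-d", "mat-d"),
    sequence = c(seq22a, seq22b, seq20c, seq22d, seq22d),
    precursor_id = c("pre-a", "pre-b", "pre-c", "pre-d1", "pre-d2"),
    chrom = c("chrT", "chrT", "chrT", "chrT", "chrU"),
    start = c(100L, 500L, 900L, 1500L, 300L),
    end = c(122L, 522L, 920L, 1522L, 322L),
    strand = c("+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE
  )
  mir_annotation(matures, precursors, "tiny")
}

aln_record <- function(read_id, chrom, start, end, strand = "+",
                       n_clip_start = 0L, n_clip_end = 0L, n_alignments = 1L) {
  data.frame(read_id = read_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             n_clip_start = as.integer(n_clip_start),
             n_clip_end = as.integer(n_clip_end),
             edit_ops = as.integer(n_clip_start + n_clip_end),
             n_alignments = as.integer(n_alignments),
             stringsAsFactors = FALSE)
}

# linear-scan overlap oracle over the mature-locus table
bf_query <- function(matures, chrom, start, end, strand) {
  hit <- matures$chrom == chrom & matures$strand == strand &
    matures$start < end & matures$end > start
  matures[hit, , drop = FALSE]
}

# exhaustive deviation-scan oracle for one interval
bf_deviation_match <- function(matures, chrom, start, end, strand, max_dev) {
  dev <- abs(matures$start - start) + abs(matures$end - end)
  ok <- matures$chrom == chrom & matures$strand == strand & dev <= max_dev
  data.frame(mature_id = matures$mature_id[ok], deviation = dev[ok],
             stringsAsFactors = FALSE)
}

# first-principles evaluation of the read-resolution rule; `match_sets` is
# a list (one element per alignment) of data.frames with mature_id,
# sequence, deviation
bf_resolve <- function(match_sets) {
  n <- length(match_sets)
  if (n == 1L) {
    m <- match_sets[[1L]]
    if (nrow(m) == 0L) return("unannotated")
    best <- m[m$deviation == min(m$deviation), , drop = FALSE]
    if (length(unique(best$mature_id)) == 1L) return("assigned")
    if (length(unique(best$sequence)) == 1L && !anyNA(best$sequence)) {
      return("assigned")
    }
    return("ambiguous_discard")
  }
  if (any(vapply(match_sets, nrow, integer(1)) == 0L)) {
    return("ambiguous_discard")
  }
  seqs <- unique(unlist(lapply(match_sets, function(m) m$sequence)))
  if (length(seqs) == 1L && !anyNA(seqs)) "assigned" else "ambiguous_discard"
}

# Benjamini-Hochberg from the step-up definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Kaplan-Meier as the explicit product over event times
bf_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = times, survival = surv)
}

# Ward (ward.D2) agglomeration via the Lance-Williams recurrence on
# squared Euclidean distances, returning merge heights and the partition
# at every k
bf_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  size <- rep(1L, n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1L)
  partitions <- list()
  D <- d2
  diag(D) <- Inf
  for (step in seq_len(n - 1L)) {
    # smallest distance among active pairs, lowest pair index on ties
    best <- c(NA_integer_, NA_integer_)
    best_val <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        if (D[a, b] < best_val - 1e-12) {
          best_val <- D[a, b]
          best <- c(a, b)
        }
      }
    }
    a <- best[1L]; b <- best[2L]
    heights[step] <- sqrt(best_val)
    # Lance-Williams update for Ward: d2(ab, c)
    for (c in setdiff(active, c(a, b))) {
      na <- size[a]; nb <- size[b]; nc <- size[c]
      D[a, c] <- D[c, a] <-
        ((na + nc) * D[a, c] + (nb + nc) * D[b, c] - nc * D[a, b]) /
        (na + nb + nc)
    }
    size[a] <- size[a] + size[b]
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
    D[b, ] <- D[, b] <- Inf
    partitions[[step]] <- {
      lab <- integer(n)
      for (g in seq_along(active)) lab[members[[active[g]]]] <- g
      lab
    }
  }
  list(heights = heights, partitions = partitions)
}
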