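# log2-CPM normalization and expression-complexity summaries.

#' log2 counts-per-million with a library-scaled pseudo-count
#'
#' Computes `log2((count + p_j) / (N_j + 2 p_j) * 1e6)` per sample `j`,
#' where by default the pseudo-count is library-scaled,
#' `p_j = prior * N_j / mean(N)`, matching the documented behaviour of
#' the standard log-CPM implementation in the edgeR package; a plain
#' fixed pseudo-count (`p_j = prior` for every sample) is available with
#' `scale_prior = FALSE`. Effective library sizes are the raw assigned
#' totals; between-sample normalization factors are fixed at 1.
#'
#' @param counts a [mir_count_matrix()] or a plain non-negative matrix.
#' @param prior pseudo-count before scaling (default 0.25).
#' @param scale_prior scale the pseudo-count by relative library size
#'   (default `TRUE`).
#' @return Object of class `mir_expression`: list with `values` (the
#'   log2-CPM matrix), `prior` and `lib_sizes`.
#' @export
log2_cpm <- function(counts, prior = 0.25, scale_prior = TRUE) {
  if (inherits(counts, "mir_counts")) {
    values <- counts$values
    lib <- counts$lib_sizes
  } else {
    values <- as.matrix(counts)
    lib <- colSums(values)
  }
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(values)[lib <= 0], collapse = ", "))
  }
  p <- if (scale_prior) prior * lib / mean(lib) else rep(prior, length(lib))
  cpm <- sweep(values, 2, p, `+`)
  cpm <- sweep(cpm, 2, lib + 2 * p, `/`) * 1e6
  out <- log2(cpm)
  structure(list(values = out, prior = prior, lib_sizes = lib),
            class = "mir_expression")
}

#' @export
print.mir_expression <- function(x, ...) {
  cat("mir_expression: ", nrow(x$values), " matures x ", ncol(x$values),
      " samples (log2-CPM, prior ", x$prior, ")\n", sep = "")
  invisible(x)
}

#' Cumulative counts of expressed miRNAs across a threshold grid
#'
#' For each threshold `t` on the grid `seq(lo, hi, by = step)`, counts
#' the miRNAs with log2-CPM value >= `t` in each sample; the mean curve
#' across samples summarizes the cohort's expression complexity.
#'
#' @param expr a [log2_cpm()] result or plain matrix of log2-CPM values.
#' @param lo,hi,step grid of thresholds in log2-CPM units (defaults
#'   -5 to 20 spaced by 0.5).
#' @return data.frame: `threshold`, one column per sample, and `mean`.
#' @export
expressed_counts <- function(expr, lo = -5, hi = 20, step = 0.5) {
  stopifnot(lo < hi, step > 0)
  values <- if (inherits(expr, "mir_expression")) expr$values else as.matrix(expr)
  grid <- seq(lo, hi, by = step)
  counts <- vapply(grid, function(t) colSums(values >= t),
                   numeric(ncol(values)))
  counts <- if (is.matrix(counts)) t(counts) else matrix(counts, ncol = 1L)
  out <- data.frame(threshold = grid, counts, check.names = FALSE)
  names(out) <- c("threshold", colnames(values))
  out$mean <- rowMeans(out[, -1L, drop = FALSE])
  out
}

#' Standardize matrix rows to mean 0, sample SD 1
#'
#' Row mean-centering followed by division by the row sample standard
#' deviation (n-1 denominator); the transformation applied before
#' distance computation in supervised heatmap clustering. Constant rows
#' cannot be scaled and are set to zero with a warning.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape with standardized rows.
#' @export
standardize_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sum(const), " constant row(s) set to zero")
    s[const] <- 1
    centered[const, ] <- 0
  }
  centered / s
}
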