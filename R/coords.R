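# Coordinate-convention logic. Everything inside the package is 0-based
# half-open [start, end); readers and writers convert at the boundary.
#
# Supported external dialects:
#   "gff3" - 1-based, fully inclusive [start, end]    (miRBase GFF3)
#   "tcga" - 1-based, half-open [start, end)          (isoform tables)

#' Convert external coordinates to the internal 0-based half-open convention
#'
#' @param start,end integer vectors in the source convention.
#' @param convention `"gff3"` (1-based inclusive) or `"tcga"` (1-based
#'   half-open, start included, end excluded).
#' @return A list with integer vectors `start` and `end`, 0-based half-open.
#' @export
to_internal <- function(start, end, convention = c("gff3", "tcga")) {
  convention <- match.arg(convention)
  start <- as.integer(start)
  end <- as.integer(end)
  out <- switch(convention,
    gff3 = list(start = start - 1L, end = end),
    tcga = list(start = start - 1L, end = end - 1L)
  )
  if (any(out$start >= out$end)) {
    stop("invalid interval: start must precede end after conversion")
  }
  out
}

#' Convert internal 0-based half-open coordinates to an external convention
#'
#' Inverse of [to_internal()]: `from_internal(to_internal(s, e, c), c)`
#' returns `s`, `e` for either dialect.
#'
#' @param start,end integer vectors, internal convention.
#' @param convention target dialect, see [to_internal()].
#' @return list with `start` and `end` in the target convention.
#' @export
from_internal <- function(start, end, convention = c("gff3", "tcga")) {
  convention <- match.arg(convention)
  start <- as.integer(start)
  end <- as.integer(end)
  switch(convention,
    gff3 = list(start = start + 1L, end = end),
    tcga = list(start = start + 1L, end = end + 1L)
  )
}

# internal: validate a strand vector
check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(strand)
}
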