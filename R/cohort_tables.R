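# Clinical cohort tables: the bundled receptor-status breakdown of the
# study cohort and its per-subtype aggregation.

#' Load the bundled cohort receptor-status table
#'
#' Patient counts of the sequenced breast-tumor cohort broken down by
#' intrinsic subtype and ER/HER2/PR receptor status (one row per
#' combination, column `n`).
#'
#' @param path optional alternative TSV with columns `subtype`, `er`,
#'   `her2`, `pr`, `n`.
#' @return data.frame.
#' @export
load_receptor_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_receptor_status.tsv",
                        package = "mirstrat")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subtype", "n") %in% names(tab)), all(tab$n >= 0))
  tab
}

#' Aggregate receptor-status rows to per-subtype sample counts
#'
#' @param tab a [load_receptor_table()] data.frame.
#' @return named integer vector of per-subtype totals, sorted by
#'   subtype name.
#' @export
aggregate_subtype_counts <- function(tab) {
  agg <- tapply(tab$n, tab$subtype, sum)
  out <- as.integer(agg)
  names(out) <- names(agg)
  out[sort(names(out))]
}
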