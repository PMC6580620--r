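# Differential-expression contrasts (one-vs-rest and all pairwise),
# multiple-testing control and the top-k union signature.

#' Run one differential-expression contrast
#'
#' Compares log2-CPM expression between two sample groups for every
#' miRNA. The default statistic is the two-sided Wilcoxon rank-sum test
#' — a distribution-free stand-in for a count-model test; any statistic
#' with the same interface can be plugged in via `test_fun`. Fold change
#' is the difference of group means on the log2 scale, positive when the
#' first-named group is higher.
#'
#' @param expr a [log2_cpm()] result or plain log2-CPM matrix.
#' @param labels per-sample group labels (length = number of columns).
#' @param group1 label (or vector of labels) defining the first group.
#' @param group2 label(s) defining the second group, or `"rest"` for all
#'   samples outside `group1` (one-vs-rest contrast).
#' @param test_fun function(x, y) returning a list/htest with `p.value`
#'   and optionally `statistic`; default Wilcoxon rank-sum.
#' @return data.frame of class `mir_contrast`: `mature_id`, `statistic`,
#'   `p`, `q` (Benjamini-Hochberg), `log2_fc`; attribute `contrast` holds
#'   the label.
#' @export
de_contrast <- function(expr, labels, group1, group2 = "rest",
                        test_fun = NULL) {
  values <- if (inherits(expr, "mir_expression")) expr$values else as.matrix(expr)
  stopifnot(length(labels) == ncol(values))
  in1 <- labels %in% group1
  in2 <- if (identical(group2, "rest")) !in1 else labels %in% group2
  if (sum(in1) < 2L || sum(in2) < 2L) {
    stop("both contrast groups need at least 2 samples")
  }
  if (is.null(test_fun)) {
    test_fun <- function(x, y) {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    }
  }
  x1 <- values[, in1, drop = FALSE]
  x2 <- values[, in2, drop = FALSE]
  res <- lapply(seq_len(nrow(values)), function(i) {
    xi <- x1[i, ]; yi <- x2[i, ]
    if (length(unique(c(xi, yi))) == 1L) {
      return(list(statistic = NA_real_, p.value = 1))
    }
    test_fun(xi, yi)
  })
  p <- vapply(res, function(r) unname(r$p.value), numeric(1))
  stat <- vapply(res, function(r) {
    s <- r$statistic
    if (is.null(s)) NA_real_ else unname(s)
  }, numeric(1))
  lbl <- paste0(paste(group1, collapse = "+"), "_vs_",
                if (identical(group2, "rest")) "rest"
                else paste(group2, collapse = "+"))
  out <- data.frame(
    mature_id = rownames(values),
    statistic = stat,
    p = p,
    q = bh_adjust(p),
    log2_fc = rowMeans(x1) - rowMeans(x2),
    stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- lbl
  class(out) <- c("mir_contrast", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_i = min_k>=i (m p_(k) / k)` capped at 1,
#' delegated to [stats::p.adjust()] after input validation.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return vector of q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Run the full contrast set for a subtype-labelled cohort
#'
#' One-vs-rest contrasts for every subtype and/or all pairwise
#' contrasts between subtypes, mirroring the two approaches used to
#' identify subtype-associated miRNAs.
#'
#' @param expr a [log2_cpm()] result or log2-CPM matrix.
#' @param labels per-sample subtype labels.
#' @param contrasts `"both"` (default), `"pairwise"` or `"ovr"`.
#' @param ... passed to [de_contrast()].
#' @return named list of [de_contrast()] results.
#' @export
de_all_contrasts <- function(expr, labels,
                             contrasts = c("both", "pairwise", "ovr"), ...) {
  contrasts <- match.arg(contrasts)
  groups <- sort(unique(labels))
  out <- list()
  if (contrasts %in% c("both", "ovr")) {
    for (g in groups) {
      r <- de_contrast(expr, labels, g, "rest", ...)
      out[[attr(r, "contrast")]] <- r
    }
  }
  if (contrasts %in% c("both", "pairwise")) {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    for (pr in pairs) {
      r <- de_contrast(expr, labels, pr[1L], pr[2L], ...)
      out[[attr(r, "contrast")]] <- r
    }
  }
  out
}

#' Build the top-k union signature across contrasts
#'
#' From each contrast, takes the `k` most significant miRNAs (smallest
#' q) passing `q <= fdr`, and unions them. Ties are broken
#' deterministically by (q, |fold change| descending, mature_id). Each
#' signature member records the contrasts that contributed it.
#'
#' @param results list of [de_contrast()] results.
#' @param k top hits per contrast (default 15).
#' @param fdr FDR significance cutoff (default 0.01).
#' @return data.frame of class `mir_signature`: `mature_id`, `contrasts`
#'   (comma-joined provenance), ordered by mature_id.
#' @export
build_signature <- function(results, k = 15L, fdr = 0.01) {
  stopifnot(length(results) >= 1L)
  picks <- list()
  for (r in results) {
    lbl <- attr(r, "contrast")
    sig <- r[r$q <= fdr, , drop = FALSE]
    if (nrow(sig) == 0L) next
    ord <- order(sig$q, -abs(sig$log2_fc), sig$mature_id)
    top <- sig$mature_id[ord][seq_len(min(k, nrow(sig)))]
    picks[[lbl]] <- top
  }
  if (length(picks) == 0L) {
    out <- data.frame(mature_id = character(), contrasts = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("mir_signature", "data.frame")
    return(out)
  }
  long <- data.frame(
    mature_id = unlist(picks, use.names = FALSE),
    contrast = rep(names(picks), lengths(picks)),
    stringsAsFactors = FALSE
  )
  prov <- tapply(long$contrast, long$mature_id,
                 function(x) paste(sort(unique(x)), collapse = ","))
  out <- data.frame(mature_id = sort(names(prov)),
                    contrasts = unname(prov[sort(names(prov))]),
                    stringsAsFactors = FALSE)
  class(out) <- c("mir_signature", "data.frame")
  out
}
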