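# Reference-centered nearest-centroid intrinsic-subtype classification.

#' Center expression against a fixed reference cohort
#'
#' Subtracts from every test sample each gene's mean over the reference
#' cohort only. Because the reference is fixed, adding test samples never
#' changes previously centered values — the property that removes cohort
#' -composition bias from nearest-centroid subtyping. Genes absent from
#' the reference are dropped (logged via message).
#'
#' @param expr gene x sample matrix of test expression.
#' @param reference gene x sample matrix of reference expression (>= 2
#'   samples).
#' @return centered gene x sample matrix over genes present in both.
#' @export
center_to_reference <- function(expr, reference) {
  expr <- as.matrix(expr)
  reference <- as.matrix(reference)
  if (ncol(reference) < 2L) stop("reference needs at least 2 samples")
  shared <- intersect(rownames(expr), rownames(reference))
  if (length(shared) == 0L) stop("no genes shared with the reference")
  dropped <- setdiff(rownames(expr), shared)
  if (length(dropped)) {
    message(length(dropped), " gene(s) absent from reference, excluded: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  ref_means <- rowMeans(reference[shared, , drop = FALSE])
  expr[shared, , drop = FALSE] - ref_means
}

#' Nearest-centroid subtype call for one sample
#'
#' Correlates a reference-centered sample vector with each subtype
#' centroid over their shared genes (Spearman by default, the customary
#' metric for this classifier family; Pearson by flag). The call is the
#' highest-correlating subtype; samples whose best correlation falls
#' below `threshold` are left unassigned. Ties break alphabetically and
#' are flagged.
#'
#' @param sample named numeric vector (centered expression).
#' @param centroids gene x subtype centroid matrix.
#' @param metric `"spearman"` or `"pearson"`.
#' @param threshold minimum best correlation for assignment (default
#'   0.1).
#' @return list: `label` (NA when unassigned), `correlations`, `margin`
#'   (best minus second best), `assigned`, `tie`, `reason`.
#' @export
nearest_centroid <- function(sample, centroids,
                             metric = c("spearman", "pearson"),
                             threshold = 0.1) {
  metric <- match.arg(metric)
  centroids <- as.matrix(centroids)
  if (ncol(centroids) < 2L) stop("need at least 2 subtype centroids")
  shared <- intersect(names(sample), rownames(centroids))
  if (length(shared) < 10L) {
    stop("fewer than 10 genes shared between sample and centroids")
  }
  v <- sample[shared]
  if (stats::sd(v) == 0) {
    return(list(label = NA_character_,
                correlations = stats::setNames(rep(NA_real_, ncol(centroids)),
                                               colnames(centroids)),
                margin = NA_real_, assigned = FALSE, tie = FALSE,
                reason = "constant sample vector"))
  }
  cors <- apply(centroids[shared, , drop = FALSE], 2,
                function(ct) stats::cor(v, ct, method = metric))
  ord <- order(-cors, colnames(centroids))
  best <- cors[ord[1L]]
  margin <- best - cors[ord[2L]]
  tie <- margin == 0
  if (best < threshold) {
    list(label = NA_character_, correlations = cors, margin = margin,
         assigned = FALSE, tie = tie, reason = "low correlation to all centroids")
  } else {
    list(label = colnames(centroids)[ord[1L]], correlations = cors,
         margin = margin, assigned = TRUE, tie = tie,
         reason = if (tie) "correlation tie, alphabetical break" else NA_character_)
  }
}

#' Classify a cohort by reference-centered nearest centroid
#'
#' @param expr gene x sample test expression matrix.
#' @param centroids gene x subtype centroid matrix.
#' @param reference optional gene x sample reference matrix for
#'   [center_to_reference()]; when `NULL` the matrix is used uncentered
#'   (assume caller centered it).
#' @param ... passed to [nearest_centroid()].
#' @return data.frame: `sample_id`, `label`, `assigned`, `margin`, one
#'   correlation column per subtype.
#' @export
classify_cohort <- function(expr, centroids, reference = NULL, ...) {
  expr <- as.matrix(expr)
  centered <- if (is.null(reference)) expr else center_to_reference(expr, reference)
  calls <- lapply(colnames(centered), function(s) {
    nearest_centroid(centered[, s], centroids, ...)
  })
  cors <- do.call(rbind, lapply(calls, `[[`, "correlations"))
  out <- data.frame(
    sample_id = colnames(centered),
    label = vapply(calls, `[[`, character(1), "label"),
    assigned = vapply(calls, `[[`, logical(1), "assigned"),
    margin = vapply(calls, `[[`, numeric(1), "margin"),
    stringsAsFactors = FALSE
  )
  cbind(out, cors)
}
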