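# Consensus clustering (subsampling scheme of Monti et al.) with item
# consensus and delta-area model selection; supervised Ward clustering;
# chi-square enrichment of clinical labels in clusters.

# 1 - Pearson correlation distance between columns of x
pearson_dist <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample vector(s), correlation undefined: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(x))
}

# area under the empirical CDF of consensus entries, integrated over the
# full [0, 1] consensus range (Monti et al.); grows as more entries sit at 0
cdf_area <- function(vals) {
  vals <- sort(vals[!is.na(vals)])
  if (length(vals) == 0L) return(0)
  n <- length(vals)
  g <- c(0, unique(vals), 1)
  cdf_left <- findInterval(g[-length(g)], vals) / n
  sum(diff(g) * cdf_left)
}

#' Consensus clustering over item subsamples
#'
#' For each k in `2..maxK`, repeatedly subsamples `ceiling(pItem * n)`
#' items (columns; and `ceiling(pFeature * m)` features), clusters each
#' subsample by hierarchical agglomeration on the chosen distance, and
#' records how often each item pair lands in the same cluster relative
#' to how often it was sampled together. Final per-k labels come from
#' hierarchical clustering of `1 - consensus`. Also computes per-item
#' consensus scores, the empirical CDF of consensus entries and the
#' relative delta-area curve used to choose k.
#'
#' @param x numeric matrix, features x items (samples are items).
#' @param maxK largest number of clusters considered (default 6).
#' @param reps number of subsampling repetitions (default 1000).
#' @param pItem,pFeature subsampling proportions (defaults 0.8, 1).
#' @param inner_linkage,final_linkage hclust linkage for subsample and
#'   consensus clustering (defaults `"average"`).
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param seed RNG seed; mandatory so runs are reproducible.
#' @return Object of class `mir_consensus`: per-k consensus matrices,
#'   labels, item consensus, CDF areas, `delta_area`, parameters.
#' @export
consensus_cluster <- function(x, maxK = 6L, reps = 1000L, pItem = 0.8,
                              pFeature = 1.0,
                              inner_linkage = "average",
                              final_linkage = "average",
                              distance = c("pearson", "euclidean"),
                              seed) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  n <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(n))
  if (n < maxK + 1L) stop("need at least maxK + 1 items")
  if (missing(seed)) stop("a seed is required for reproducible consensus runs")
  if (distance == "pearson") pearson_dist(x)  # fail fast on constant items
  set.seed(seed)

  ks <- 2:maxK
  n_item <- ceiling(pItem * n)
  n_feat <- ceiling(pFeature * nrow(x))
  M <- lapply(ks, function(k) matrix(0, n, n))
  names(M) <- as.character(ks)
  I <- matrix(0, n, n)

  for (r in seq_len(reps)) {
    items <- sort(sample.int(n, n_item))
    feats <- if (n_feat < nrow(x)) sort(sample.int(nrow(x), n_feat)) else seq_len(nrow(x))
    sub <- x[feats, items, drop = FALSE]
    d <- if (distance == "pearson") pearson_dist(sub) else stats::dist(t(sub))
    hc <- stats::hclust(d, method = inner_linkage)
    I[items, items] <- I[items, items] + 1
    for (k in ks) {
      lab <- stats::cutree(hc, k = k)
      co <- outer(lab, lab, `==`) * 1
      key <- as.character(k)
      M[[key]][items, items] <- M[[key]][items, items] + co
    }
  }

  never <- I == 0 & upper.tri(I)
  if (any(never)) {
    warning(sum(never), " item pair(s) never co-sampled; consensus NA, ",
            "imputed for final clustering")
  }
  consensus <- lapply(M, function(mk) {
    cm <- mk / I
    cm[I == 0] <- NA
    diag(cm) <- 1
    dimnames(cm) <- list(colnames(x), colnames(x))
    cm
  })

  labels <- list()
  item_consensus <- list()
  areas <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    cm <- consensus[[as.character(k)]]
    cmi <- cm
    if (anyNA(cmi)) {  # impute never-co-sampled pairs with column means
      col_means <- colMeans(cmi, na.rm = TRUE)
      idx <- which(is.na(cmi), arr.ind = TRUE)
      cmi[idx] <- col_means[idx[, 2]]
    }
    hc <- stats::hclust(stats::as.dist(1 - cmi), method = final_linkage)
    lab <- stats::cutree(hc, k = k)
    labels[[as.character(k)]] <- lab
    item_consensus[[as.character(k)]] <- item_consensus_scores(cmi, lab)
    areas[i] <- cdf_area(cm[upper.tri(cm)])
  }

  delta <- numeric(length(ks))
  delta[1] <- areas[1]
  if (length(ks) > 1L) {
    for (i in 2:length(ks)) {
      delta[i] <- if (areas[i - 1] > 0) {
        (areas[i] - areas[i - 1]) / areas[i - 1]
      } else {
        areas[i]
      }
    }
  }

  structure(list(
    consensus = consensus,
    labels = labels,
    item_consensus = item_consensus,
    cdf_area = stats::setNames(areas, ks),
    delta_area = stats::setNames(delta, ks),
    params = list(maxK = maxK, reps = reps, pItem = pItem,
                  pFeature = pFeature, inner_linkage = inner_linkage,
                  final_linkage = final_linkage, distance = distance,
                  seed = seed)
  ), class = "mir_consensus")
}

# item consensus: mean consensus of item i with the members of cluster c,
# excluding the i-i entry when i belongs to c (Monti et al. definition);
# returned for each item's assigned cluster
item_consensus_scores <- function(cm, labels) {
  vapply(seq_along(labels), function(i) {
    members <- which(labels == labels[i])
    members <- setdiff(members, i)
    if (length(members) == 0L) return(1)
    mean(cm[i, members])
  }, numeric(1))
}

#' @export
print.mir_consensus <- function(x, ...) {
  cat("mir_consensus: k = 2..", x$params$maxK, ", reps = ", x$params$reps,
      ", pItem = ", x$params$pItem, "\n", sep = "")
  cat("delta area:", paste(sprintf("k%s=%.3f", names(x$delta_area),
                                   x$delta_area), collapse = " "), "\n")
  invisible(x)
}

#' Choose the number of clusters from the delta-area curve
#'
#' Returns the largest k whose relative delta-area (increase in the area
#' under the consensus CDF, relative to the previous k) is at least
#' `threshold` — the point past which adding clusters no longer
#' increases consensus appreciably. The selection is advisory: the full
#' curve is attached, and a selection resting on near-zero areas is
#' flagged low-confidence.
#'
#' @param result a [consensus_cluster()] result.
#' @param threshold relative delta-area cutoff (default 0.1).
#' @return integer k, with attributes `delta_area` (the curve) and
#'   `low_confidence`.
#' @export
select_k <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "mir_consensus"))
  delta <- result$delta_area
  ks <- as.integer(names(delta))
  keep <- which(delta >= threshold)
  k <- if (length(keep)) ks[max(keep)] else ks[1L]
  low_conf <- length(keep) == 0L || max(result$cdf_area) < 0.01
  structure(k, delta_area = delta, low_confidence = low_conf)
}

#' Chi-square enrichment of clinical labels within clusters
#'
#' Pearson chi-square test (no continuity correction) on the
#' cluster-by-clinical contingency table.
#'
#' @param cluster_labels,clinical_labels equal-length label vectors.
#' @return list: `statistic`, `df`, `p`, `observed`, `expected`;
#'   warns when any expected count is below 5.
#' @export
chi2_enrichment <- function(cluster_labels, clinical_labels) {
  stopifnot(length(cluster_labels) == length(clinical_labels))
  tab <- table(cluster_labels, clinical_labels)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("both label vectors need at least 2 levels")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("expected count(s) below 5; chi-square approximation is rough")
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, observed = tab, expected = ht$expected)
}

#' Euclidean/Ward clustering of a row-standardized matrix
#'
#' Agglomerative clustering of rows and columns with Euclidean distance
#' and Ward linkage in the variance-minimizing (squared-distance)
#' formulation (`ward.D2`), as used for supervised signature heatmaps.
#'
#' @param m numeric matrix (typically [standardize_rows()] output), no
#'   NAs.
#' @param k_rows,k_cols optional cluster counts at which to cut the row
#'   and column dendrograms.
#' @return list: `row_hclust`, `col_hclust`, `row_labels`, `col_labels`
#'   (NULL when no cut requested), and merge heights.
#' @export
ward_cluster <- function(m, k_rows = NULL, k_cols = NULL) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix contains NA entries")
  rh <- stats::hclust(stats::dist(m), method = "ward.D2")
  ch <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  list(
    row_hclust = rh,
    col_hclust = ch,
    row_labels = if (!is.null(k_rows)) stats::cutree(rh, k = k_rows) else NULL,
    col_labels = if (!is.null(k_cols)) stats::cutree(ch, k = k_cols) else NULL,
    row_heights = rh$height,
    col_heights = ch$height
  )
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted-for-chance agreement between two clusterings;
#' 1 for identical partitions (up to label names), ~0 for independent
#' ones.
#'
#' @param a,b equal-length label vectors.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
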