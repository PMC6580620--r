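# Median-split stratified survival analysis: expression scores,
# Kaplan-Meier estimation and log-rank testing per subtype stratum.

#' Average expression score over a miRNA set
#'
#' Per-sample arithmetic mean of the log2-CPM values of the given
#' matures — e.g. all mature arms of the miR-99a/let-7c/miR-125b
#' polycistron, the Luminal-A stratifier. Members missing from the
#' matrix are reported via message and skipped.
#'
#' @param expr a [log2_cpm()] result or log2-CPM matrix.
#' @param members character vector of mature IDs.
#' @return named numeric vector of per-sample scores.
#' @export
cluster_score <- function(expr, members) {
  values <- if (inherits(expr, "mir_expression")) expr$values else as.matrix(expr)
  present <- intersect(members, rownames(values))
  if (length(present) == 0L) stop("no score members present in the matrix")
  missing <- setdiff(members, present)
  if (length(missing)) {
    message("score member(s) absent from matrix, skipped: ",
            paste(missing, collapse = ", "))
  }
  colMeans(values[present, , drop = FALSE])
}

#' Split samples at the median of a score
#'
#' Samples strictly above the median are `high`; samples at or below it
#' are `low` (the median sample of an odd-sized cohort goes low).
#'
#' @param scores named numeric vector.
#' @return factor (`low`/`high`) named by sample; attribute `sizes`
#'   carries the group sizes and the cutpoint.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples to split")
  med <- stats::median(scores)
  if (all(scores == med)) stop("all scores identical; no median split exists")
  grp <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  names(grp) <- names(scores)
  attr(grp, "sizes") <- c(low = sum(grp == "low"), high = sum(grp == "high"))
  attr(grp, "cutpoint") <- med
  grp
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function
#' as a table: the curve starts at 1, is non-increasing, and censored
#' times do not drop it.
#'
#' @param time non-negative event/censoring times.
#' @param event 1 = event (death), 0 = censored.
#' @return data.frame: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Observed-vs-expected events under the hypergeometric null summed over
#' event times, via [survival::survdiff()].
#'
#' @param time,event as in [km_estimate()].
#' @param groups group labels (>= 2 levels).
#' @return list: `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (sum(event) == 0) stop("no events observed; log-rank undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Median-split survival analysis stratified by subtype
#'
#' Within each stratum (independently: the median cutpoint uses only the
#' stratum's own samples), splits patients into high/low expression at
#' the median of `scores`, estimates both Kaplan-Meier curves and tests
#' the split with the log-rank statistic. An optional `subgroup_filter`
#' (a predicate on the records data.frame, e.g. the focused
#' ER+/HER2-/node-negative/endocrine-only Luminal-A selection) is
#' applied before splitting. Strata left empty by the filter are
#' reported, not errors.
#'
#' @param records data.frame with `sample_id`, `time`, `event`,
#'   `stratum` and any covariate columns the filter needs.
#' @param scores named numeric vector of per-sample scores (names match
#'   `sample_id`).
#' @param subgroup_filter optional function(records) -> logical vector.
#' @return named list per stratum: `n`, `split` sizes, `km` (list of
#'   low/high curves), `logrank` (or a reason when not computable).
#' @export
stratified_analysis <- function(records, scores, subgroup_filter = NULL) {
  records <- as.data.frame(records)
  stopifnot(all(c("sample_id", "time", "event", "stratum") %in% names(records)))
  strata <- sort(unique(as.character(records$stratum)))
  if (!is.null(subgroup_filter)) {
    keep <- subgroup_filter(records)
    records <- records[keep, , drop = FALSE]
  }
  out <- list()
  for (st in strata) {
    rec <- records[records$stratum == st, , drop = FALSE]
    sc <- scores[rec$sample_id]
    if (nrow(rec) == 0L) {
      out[[st]] <- list(n = 0L, note = "empty stratum after filtering")
      next
    }
    if (nrow(rec) < 2L || anyNA(sc) || all(sc == stats::median(sc))) {
      out[[st]] <- list(n = nrow(rec), note = "stratum too small or unsplittable")
      next
    }
    grp <- median_split(sc)
    km <- lapply(levels(grp), function(g) {
      sel <- grp == g
      if (!any(sel)) return(NULL)
      km_estimate(rec$time[sel], rec$event[sel])
    })
    names(km) <- levels(grp)
    lr <- if (sum(rec$event) > 0 && nlevels(droplevels(grp)) == 2L) {
      logrank_test(rec$time, rec$event, grp)
    } else {
      list(note = "log-rank not computable (no events or one group)")
    }
    out[[st]] <- list(n = nrow(rec), split = attr(grp, "sizes"),
                      cutpoint = attr(grp, "cutpoint"),
                      groups = grp, km = km, logrank = lr)
  }
  out
}

#' Focused Luminal-A style subgroup filter
#'
#' Builds the predicate selecting ER-positive, HER2-negative,
#' node-negative patients who received endocrine treatment but neither
#' chemotherapy nor anti-HER2 therapy (optionally also filtered on
#' radiotherapy), for use with [stratified_analysis()].
#'
#' @param radiotherapy `NA` (ignore, default), `TRUE` or `FALSE`.
#' @return function(records) -> logical vector.
#' @export
luminal_a_filter <- function(radiotherapy = NA) {
  function(records) {
    keep <- records$er == "+" & records$her2 == "-" &
      records$node == 0 & records$endocrine == 1 &
      records$chemo == 0 & records$anti_her2 == 0
    if (!is.na(radiotherapy)) {
      keep <- keep & (records$radiotherapy == as.integer(radiotherapy))
    }
    keep & !is.na(keep)
  }
}
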