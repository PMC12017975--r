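#' Pooled group comparison across cases
#'
#' Pools the per-contour metric records of the two radiation-oncologist arms
#' across all (non-excluded) cases and compares them per metric with a
#' two-sided Mann-Whitney U test. Pooling is per contour: every returned
#' delineation contributes one value per metric.
#'
#' @param records metric records \code{data.frame} from
#'   [compute_case_metrics()] (possibly row-bound over cases).
#' @param exclude_cases optional character vector of case ids to drop before
#'   pooling (e.g. cases with large radiologist variation). An error is
#'   raised if a compared group is emptied by the exclusion.
#' @param groups the two group labels to compare
#'   (default \code{c("GTV-", "GTV+")}).
#' @param metrics metrics to compare (default SDSC, DSC, HD98).
#' @param alpha significance level (default 0.05; significant iff
#'   p <= alpha).
#' @return A \code{data.frame} with one row per metric: group sizes, medians
#'   and IQRs for both groups, the signed median difference
#'   (second group minus first), its relevance category, the Mann-Whitney
#'   p-value and a significance flag. The per-metric [group_summary()]
#'   objects are attached as attribute \code{"summaries"}.
#' @export
pooled_comparison <- function(records, exclude_cases = NULL,
                              groups = c("GTV-", "GTV+"),
                              metrics = iov_metrics(), alpha = 0.05) {
  stopifnot(is.data.frame(records), length(groups) == 2)
  if (!is.null(exclude_cases)) {
    unknown <- setdiff(exclude_cases, unique(records$case_id))
    if (length(unknown))
      stop("exclude_cases contains unknown case ids: ",
           paste(unknown, collapse = ", "))
    records <- records[!(records$case_id %in% exclude_cases), , drop = FALSE]
  }
  rows <- list()
  summaries <- list()
  for (metric in metrics) {
    col <- metric_column(metric)
    a <- records[[col]][records$group == groups[1]]
    b <- records[[col]][records$group == groups[2]]
    if (length(a) == 0 || length(b) == 0)
      stop(sprintf("group '%s' has no records for metric %s after exclusion",
                   groups[if (length(a) == 0) 1 else 2], metric))
    ga <- group_summary(a)
    gb <- group_summary(b)
    mw <- mann_whitney_u(a, b)
    da <- median_difference(ga, gb, metric)
    rows[[metric]] <- data.frame(
      metric = metric,
      n_1 = ga$n, median_1 = ga$median,
      iqr_lo_1 = ga$iqr[["lower"]], iqr_hi_1 = ga$iqr[["upper"]],
      n_2 = gb$n, median_2 = gb$median,
      iqr_lo_2 = gb$iqr[["lower"]], iqr_hi_2 = gb$iqr[["upper"]],
      difference = da$difference, difference_category = da$category,
      U = mw$U, p = mw$p, significant = mw$p <= alpha,
      stringsAsFactors = FALSE
    )
    summaries[[metric]] <- list(ga, gb)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  attr(out, "summaries") <- summaries
  out
}

#' Define a recurrence-subtype case grouping
#'
#' Cases may belong to several subtypes (e.g. a recurrence can be both
#' multifocal and fibrotic), so subtype memberships are allowed to overlap.
#'
#' @param subtype subtype label.
#' @param case_ids non-empty character vector of member case ids.
#' @return An object of class \code{subtype_definition}.
#' @export
subtype_definition <- function(subtype, case_ids) {
  stopifnot(is.character(subtype), length(subtype) == 1)
  case_ids <- as.character(case_ids)
  if (length(case_ids) == 0) stop("subtype must contain at least one case")
  structure(list(subtype = subtype, case_ids = unique(case_ids)),
            class = "subtype_definition")
}

#' Per-subtype group comparison
#'
#' Runs the pooled GTV- versus GTV+ comparison restricted to each subtype's
#' member cases. A case contributes to every subtype it belongs to, so
#' record counts across overlapping subtypes need not sum to the total.
#'
#' @param records metric records \code{data.frame}.
#' @param subtypes list of [subtype_definition()] objects.
#' @inheritParams pooled_comparison
#' @return A \code{data.frame} like [pooled_comparison()] with additional
#'   leading columns \code{subtype} and \code{n_cases}.
#' @export
subtype_comparison <- function(records, subtypes, groups = c("GTV-", "GTV+"),
                               metrics = iov_metrics(), alpha = 0.05) {
  stopifnot(is.list(subtypes))
  known <- unique(records$case_id)
  out <- list()
  for (sd in subtypes) {
    stopifnot(inherits(sd, "subtype_definition"))
    unknown <- setdiff(sd$case_ids, known)
    if (length(unknown))
      stop(sprintf("subtype '%s' references unknown case ids: %s",
                   sd$subtype, paste(unknown, collapse = ", ")))
    sub <- records[records$case_id %in% sd$case_ids, , drop = FALSE]
    tab <- pooled_comparison(sub, groups = groups, metrics = metrics,
                             alpha = alpha)
    out[[sd$subtype]] <- cbind(
      data.frame(subtype = sd$subtype, n_cases = length(sd$case_ids),
                 stringsAsFactors = FALSE),
      tab)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cases with large radiologist variation
#'
#' Identifies cases whose radiologist-group per-case medians fall in the
#' "large variation" category; used for the sensitivity re-analysis that
#' excludes such cases from the pooled comparison. By default a case
#' qualifies only when all three metrics (SDSC, DSC, HD98) are large;
#' \code{rule = "any"} flags a case when any metric is.
#'
#' @param records metric records \code{data.frame}.
#' @param rule \code{"all"} (default) or \code{"any"}.
#' @param group group whose variation is screened (default \code{"RAD"}).
#' @return Character vector of case ids.
#' @export
large_variation_cases <- function(records, rule = c("all", "any"),
                                  group = "RAD") {
  rule <- match.arg(rule)
  recs <- records[records$group == group, , drop = FALSE]
  if (nrow(recs) == 0) stop(sprintf("no records for group '%s'", group))
  flagged <- character()
  for (cid in unique(recs$case_id)) {
    sub <- recs[recs$case_id == cid, , drop = FALSE]
    cats <- vapply(iov_metrics(), function(m) {
      categorize(m, stats::median(sub[[metric_column(m)]]))
    }, character(1))
    hit <- if (rule == "all") all(cats == "large") else any(cats == "large")
    if (hit) flagged <- c(flagged, cid)
  }
  flagged
}

#' Per-case agreement report
#'
#' The per-case summary row: for each group (RAD, GTV-, GTV+) and each
#' metric, the group median and its variation category; for each metric the
#' GTV+ minus GTV- median difference with its relevance category; and the
#' overall consistency label for the case.
#'
#' @param case a [case_study()] containing the RAD, GTV- and GTV+ groups, or
#'   a precomputed metric records \code{data.frame} for one case.
#' @param cfg a [tolerance_config()] (used only when metrics must be
#'   computed).
#' @param reference_rule consensus rule passed to [compute_case_metrics()].
#' @return A list of class \code{case_report}: \code{case_id},
#'   \code{medians} (metric x group matrix), \code{categories} (same shape),
#'   \code{differences} (list of difference assessments per metric),
#'   \code{consistency}, and the underlying \code{records}.
#' @export
case_report <- function(case, cfg = tolerance_config(),
                        reference_rule = "majority") {
  if (inherits(case, "case_study")) {
    missing <- setdiff(iov_groups(), names(case$groups))
    if (length(missing))
      stop(sprintf("case '%s' is missing group(s): %s", case$case_id,
                   paste(missing, collapse = ", ")))
    records <- compute_case_metrics(case, reference_rule = reference_rule,
                                    cfg = cfg)
  } else {
    records <- case
    stopifnot(is.data.frame(records))
    if (length(unique(records$case_id)) != 1)
      stop("case_report expects records from exactly one case")
    missing <- setdiff(iov_groups(), unique(records$group))
    if (length(missing))
      stop(sprintf("case '%s' is missing group(s): %s",
                   records$case_id[1], paste(missing, collapse = ", ")))
  }
  metrics <- iov_metrics()
  groups <- iov_groups()
  med <- matrix(NA_real_, length(metrics), length(groups),
                dimnames = list(metrics, groups))
  cat_m <- matrix(NA_character_, length(metrics), length(groups),
                  dimnames = list(metrics, groups))
  for (m in metrics) for (g in groups) {
    v <- records[[metric_column(m)]][records$group == g]
    med[m, g] <- stats::median(v)
    cat_m[m, g] <- categorize(m, med[m, g])
  }
  diffs <- lapply(metrics, function(m)
    median_difference(med[m, "GTV-"], med[m, "GTV+"], m))
  names(diffs) <- metrics
  structure(list(case_id = records$case_id[1],
                 medians = med, categories = cat_m,
                 differences = diffs,
                 consistency = consistency_assessment(diffs),
                 records = records),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("case_report ", x$case_id, "\n", sep = "")
  tab <- cbind(as.data.frame(round(x$medians, 3)),
               difference = vapply(x$differences,
                                   function(d) d$difference, numeric(1)),
               assessment = vapply(x$differences,
                                   function(d) d$category, character(1)))
  print(tab)
  cat("consistency:", x$consistency, "\n")
  invisible(x)
}

# flat one-row-per-case data.frame used by the pipeline report
case_report_row <- function(rep) {
  row <- data.frame(case_id = rep$case_id, stringsAsFactors = FALSE)
  for (m in iov_metrics()) {
    for (g in iov_groups()) {
      tag <- tolower(chartr("-+", "mp", g))  # RAD -> rad, GTV- -> gtvm, GTV+ -> gtvp
      row[[paste0(tolower(m), "_", tag)]] <- rep$medians[m, g]
      row[[paste0(tolower(m), "_", tag, "_cat")]] <- rep$categories[m, g]
    }
    row[[paste0(tolower(m), "_diff")]] <- rep$differences[[m]]$difference
    row[[paste0(tolower(m), "_diff_cat")]] <- rep$differences[[m]]$category
  }
  row$consistency <- rep$consistency
  row
}
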