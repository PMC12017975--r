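#' Metric improvement directions and relevance thresholds
#'
#' Central registry preventing sign errors: for DSC and SDSC larger is
#' better and the relevance threshold for an absolute change is 0.1; for
#' HD98 smaller is better and the threshold is 3 mm. Thresholds are
#' exclusive: an absolute difference must strictly exceed the threshold to
#' count as relevant.
#' @keywords internal
metric_info <- function(metric) {
  switch(metric,
         DSC = list(higher_better = TRUE, threshold = 0.1),
         SDSC = list(higher_better = TRUE, threshold = 0.1),
         HD98 = list(higher_better = FALSE, threshold = 3),
         stop(sprintf("unknown metric '%s' (expected DSC, SDSC or HD98)",
                      metric)))
}

iov_metrics <- function() c("SDSC", "DSC", "HD98")

# metric column in a records data.frame
metric_column <- function(metric) {
  switch(metric, DSC = "dsc", SDSC = "sdsc", HD98 = "hd98",
         stop(sprintf("unknown metric '%s'", metric)))
}

#' Categorize a metric value as little / average / large variation
#'
#' Cut-offs: SDSC or DSC below 0.6 is large variation, 0.6 up to (but
#' excluding) 0.8 is average, and 0.8 or above is little variation. HD98
#' below 10 mm is little variation, 10 up to (but excluding) 20 mm is
#' average, and 20 mm or above is large.
#'
#' @param metric one of \code{"DSC"}, \code{"SDSC"}, \code{"HD98"}.
#' @param value numeric metric value (vectorized).
#' @return Character vector in \code{c("little", "average", "large")}.
#' @export
categorize <- function(metric, value) {
  metric <- match.arg(metric, iov_metrics())
  stopifnot(is.numeric(value), all(is.finite(value)))
  if (metric %in% c("DSC", "SDSC")) {
    if (any(value < 0 | value > 1))
      stop(sprintf("%s values must lie in [0, 1]", metric))
    ifelse(value < 0.6, "large", ifelse(value < 0.8, "average", "little"))
  } else {
    if (any(value < 0)) stop("HD98 values must be non-negative")
    ifelse(value < 10, "little", ifelse(value < 20, "average", "large"))
  }
}

#' Assess the difference between two group medians
#'
#' The signed difference is median(GTV+) minus median(GTV-). For DSC/SDSC a
#' positive difference is an improvement; for HD98 a negative one is. The
#' change is relevant only if its magnitude strictly exceeds the metric's
#' threshold (0.1 for DSC/SDSC, 3 mm for HD98).
#'
#' @param gtv_minus,gtv_plus group medians (numeric scalars) or
#'   [group_summary()] objects, in which case their medians are used.
#' @param metric one of \code{"DSC"}, \code{"SDSC"}, \code{"HD98"}.
#' @return A list of class \code{difference_assessment} with fields
#'   \code{metric}, \code{difference} (signed, GTV+ minus GTV-) and
#'   \code{category} in \code{c("relevant improvement",
#'   "no relevant difference", "relevant deterioration")}.
#' @export
median_difference <- function(gtv_minus, gtv_plus, metric) {
  info <- metric_info(metric)
  med <- function(x) if (inherits(x, "group_summary")) x$median else x
  diff <- med(gtv_plus) - med(gtv_minus)
  category <- if (abs(diff) <= info$threshold) {
    "no relevant difference"
  } else if ((diff > 0) == info$higher_better) {
    "relevant improvement"
  } else {
    "relevant deterioration"
  }
  structure(list(metric = metric, difference = diff, category = category),
            class = "difference_assessment")
}

#' @export
print.difference_assessment <- function(x, ...) {
  cat(x$metric, ": difference ", format(x$difference), " -> ", x$category,
      "\n", sep = "")
  invisible(x)
}

#' Consistency of per-metric differences within a case
#'
#' A case shows a consistent improvement iff all three metrics (SDSC, DSC,
#' HD98) are assessed as relevant improvements; analogously for consistent
#' deterioration; any other combination is \code{"mixed/none"}.
#'
#' @param case_differences list of \code{difference_assessment} objects,
#'   exactly one per metric in SDSC, DSC, HD98.
#' @return One of \code{"consistent improvement"},
#'   \code{"consistent deterioration"}, \code{"mixed/none"}.
#' @export
consistency_assessment <- function(case_differences) {
  stopifnot(is.list(case_differences))
  metrics <- vapply(case_differences, function(d) d$metric, character(1))
  if (!setequal(metrics, iov_metrics()) ||
      length(metrics) != length(iov_metrics()))
    stop("need exactly one difference assessment per metric (SDSC, DSC, HD98)")
  cats <- vapply(case_differences, function(d) d$category, character(1))
  if (all(cats == "relevant improvement")) return("consistent improvement")
  if (all(cats == "relevant deterioration")) return("consistent deterioration")
  "mixed/none"
}

#' Median, IQR and range of a group of metric values
#'
#' Quartiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7); this convention is echoed in all report
#' metadata.
#'
#' @param values numeric vector with at least one finite value.
#' @return An object of class \code{group_summary}: list with \code{n},
#'   \code{median}, \code{iqr} (named lower/upper) and \code{range}
#'   (named min/max).
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("group_summary requires at least one value")
  if (anyNA(values)) stop("group_summary values must not contain NA")
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  structure(list(n = length(values), median = q[2],
                 iqr = c(lower = q[1], upper = q[3]),
                 range = c(min = min(values), max = max(values))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("n = ", x$n, ", median ", format(x$median), " (IQR ",
      format(x$iqr[["lower"]]), "-", format(x$iqr[["upper"]]), ", range ",
      format(x$range[["min"]]), "-", format(x$range[["max"]]), ")\n",
      sep = "")
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples with midranks for ties.
#' The p-value is exact (from the null rank-sum distribution, equivalent to
#' exhaustive permutation enumeration) whenever there are no ties and both
#' samples have fewer than 50 observations; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided throughout. The U statistic counts pairs (x, y) with x > y,
#' plus half of the tied pairs.
#'
#' @param x,y numeric samples, each non-empty.
#' @return List with \code{U} and \code{p}.
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && length(x) < 50 && length(y) < 50
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = min(1, unname(wt$p.value)))
}
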