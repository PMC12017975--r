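#' Run the full interobserver-variation analysis
#'
#' Orchestrates the per-case and pooled analysis end to end: per case and
#' group, the strict-majority consensus contour; per observer contour, the
#' agreement metrics against the observer's own group consensus; per case,
#' the summary report (medians, variation categories, GTV+ minus GTV-
#' differences, consistency); pooled GTV- versus GTV+ comparison across all
#' cases; the same comparison excluding cases with large radiologist
#' variation; and, when subtype definitions are supplied, the per-subtype
#' comparison. Deterministic given its inputs.
#'
#' @param cases list of [case_study()] objects (e.g. from
#'   [simulate_study()] or [read_study_manifest()]), or a manifest path.
#' @param cfg a [tolerance_config()].
#' @param reference_rule consensus rule for [compute_case_metrics()].
#' @param subtypes optional list of [subtype_definition()] objects; defaults
#'   to the tags carried by the cases (when any).
#' @param exclusion_rule rule for [large_variation_cases()]: \code{"all"}
#'   (default) or \code{"any"}; the exclusion re-analysis is skipped when no
#'   case qualifies or when the cases carry no RAD group.
#' @param alpha significance level for the rank-sum comparisons.
#' @param verbose log per-case observer counts and warnings via
#'   \code{message()}.
#' @return A list of class \code{iov_report}: \code{records} (per-contour
#'   metrics), \code{case_reports} (list of [case_report()] objects),
#'   \code{case_table} (one row per case), \code{pooled},
#'   \code{excluded_cases}, \code{pooled_excluding}, \code{subtype_table},
#'   and \code{config} (tolerances and conventions echoed for
#'   self-description).
#' @export
run_pipeline <- function(cases, cfg = tolerance_config(),
                         reference_rule = "majority", subtypes = NULL,
                         exclusion_rule = "all", alpha = 0.05,
                         verbose = FALSE) {
  if (is.character(cases) && length(cases) == 1)
    cases <- read_study_manifest(cases)
  stopifnot(is.list(cases), length(cases) >= 1)
  recs <- list()
  reports <- list()
  for (case in cases) {
    stopifnot(inherits(case, "case_study"))
    if (verbose)
      message(sprintf("case %s: %s", case$case_id,
                      paste(sprintf("%s n=%d", names(case$groups),
                                    vapply(case$groups,
                                           function(g) length(g$masks), 1L)),
                            collapse = ", ")))
    rep <- case_report(case, cfg = cfg, reference_rule = reference_rule)
    reports[[case$case_id]] <- rep
    recs[[case$case_id]] <- rep$records
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  case_table <- do.call(rbind, lapply(reports, case_report_row))
  rownames(case_table) <- NULL

  pooled <- pooled_comparison(records, alpha = alpha)

  has_rad <- "RAD" %in% records$group
  excluded <- if (has_rad) large_variation_cases(records,
                                                 rule = exclusion_rule)
              else character()
  pooled_excluding <- if (length(excluded) &&
                          length(excluded) < length(unique(records$case_id)))
    pooled_comparison(records, exclude_cases = excluded, alpha = alpha)
  else NULL

  if (is.null(subtypes)) {
    tags <- lapply(cases, function(cs) cs$subtypes)
    all_tags <- unique(unlist(tags))
    if (length(all_tags)) {
      subtypes <- lapply(all_tags, function(tg)
        subtype_definition(tg, names(cases)[vapply(tags, function(x)
          tg %in% x, logical(1))]))
    }
  }
  subtype_table <- if (!is.null(subtypes) && length(subtypes))
    subtype_comparison(records, subtypes, alpha = alpha)
  else NULL

  structure(list(
    records = records,
    case_reports = reports,
    case_table = case_table,
    pooled = pooled,
    excluded_cases = excluded,
    pooled_excluding = pooled_excluding,
    subtype_table = subtype_table,
    config = list(sdsc_tolerance_mm = cfg$sdsc_tolerance,
                  hd_percentile = cfg$hd_percentile,
                  reference_rule = reference_rule,
                  exclusion_rule = exclusion_rule,
                  alpha = alpha,
                  percentile_convention =
                    "linear interpolation between order statistics (type 7)",
                  mda_sd = "population (divisor n)",
                  relevance_thresholds =
                    "exclusive; |diff| > 0.1 (DSC/SDSC), > 3 mm (HD98)")
  ), class = "iov_report")
}

#' @export
print.iov_report <- function(x, ...) {
  cat("iov_report: ", length(x$case_reports), " cases, ",
      nrow(x$records), " contours\n", sep = "")
  cat("\nPooled GTV- vs GTV+ comparison:\n")
  print(x$pooled[, c("metric", "n_1", "median_1", "n_2", "median_2",
                     "difference", "difference_category", "p")],
        row.names = FALSE)
  if (length(x$excluded_cases))
    cat("\ncases with large RAD variation (excluded in re-analysis): ",
        paste(x$excluded_cases, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an analysis report bundle to disk
#'
#' Emits the per-case table, the per-contour metric records, the pooled and
#' exclusion comparisons and the subtype table as CSV, plus a JSON summary
#' embedding the configuration metadata.
#'
#' @param report an \code{iov_report} from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "iov_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "metric_records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$case_table, file.path(dir, "per_case_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pooled, file.path(dir, "pooled_comparison.csv"),
                   row.names = FALSE)
  if (!is.null(report$pooled_excluding))
    utils::write.csv(report$pooled_excluding,
                     file.path(dir, "pooled_comparison_excluding.csv"),
                     row.names = FALSE)
  if (!is.null(report$subtype_table))
    utils::write.csv(report$subtype_table,
                     file.path(dir, "subtype_comparison.csv"),
                     row.names = FALSE)
  summary <- list(
    config = report$config,
    n_cases = length(report$case_reports),
    n_contours = nrow(report$records),
    excluded_cases = report$excluded_cases,
    pooled = report$pooled,
    consistency = lapply(report$case_reports, function(r) r$consistency)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
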