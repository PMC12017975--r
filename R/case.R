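#' Group label constants
#'
#' The three observer groups of a multidisciplinary delineation study:
#' radiologists (\code{"RAD"}), radiation oncologists contouring without
#' access to the radiology consensus (\code{"GTV-"}), and radiation
#' oncologists contouring with it (\code{"GTV+"}).
#' @export
iov_groups <- function() c("RAD", "GTV-", "GTV+")

#' One case of a multi-observer delineation study
#'
#' The unit of the per-case analysis: a case id, optional subtype tags
#' (e.g. recurrence morphology labels; a case may carry several), and the
#' per-group observer delineation sets, all on one shared grid.
#'
#' @param case_id character scalar, unique within a study.
#' @param groups named list of [observer_set()] objects; names are the group
#'   labels.
#' @param subtypes character vector of subtype tags (may be empty).
#' @param truth optional ground-truth [binary_mask()] (known for synthetic
#'   cases only).
#' @param metadata optional list of extra per-case information (e.g. the true
#'   simulation parameters, kept for parameter-recovery tests).
#' @return An object of class \code{case_study}.
#' @export
case_study <- function(case_id, groups, subtypes = character(),
                       truth = NULL, metadata = list()) {
  stopifnot(is.character(case_id), length(case_id) == 1,
            is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list of observer sets")
  if (!all(vapply(groups, inherits, logical(1), "observer_set")))
    stop("all elements of `groups` must be observer_set objects")
  ref <- groups[[1]]$masks[[1]]
  for (g in groups) for (m in g$masks) stop_if_incompatible(ref, m)
  structure(list(case_id = case_id, groups = groups,
                 subtypes = as.character(subtypes), truth = truth,
                 metadata = metadata),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat("case_study ", x$case_id, ": ",
      paste(sprintf("%s(n=%d)", names(x$groups),
                    vapply(x$groups, function(g) length(g$masks), 1L)),
            collapse = ", "),
      if (length(x$subtypes)) paste0(" [", paste(x$subtypes, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Per-observer agreement metrics for a case
#'
#' Evaluates every observer contour against the consensus reference of that
#' observer's own group: radiologist IOV is measured against the radiology
#' median contour, and each radiation-oncologist arm against the median of
#' its own group. The default reference rule is the strict-majority contour
#' of the full group (leave-one-in: the observer's own contour participates
#' in the vote it is compared against). \code{"majority_loo"} instead
#' rebuilds the majority vote without the observer under evaluation;
#' \code{"union"} uses the union contour.
#'
#' @param case a [case_study()].
#' @param reference_rule \code{"majority"} (default), \code{"majority_loo"}
#'   or \code{"union"}.
#' @param cfg a [tolerance_config()].
#' @return A \code{data.frame} with one row per observer contour: columns
#'   \code{case_id}, \code{observer_id}, \code{group}, \code{dsc},
#'   \code{sdsc}, \code{hd98}, \code{mda_mean}, \code{mda_sd},
#'   \code{observer_volume}, \code{reference_volume}.
#' @export
compute_case_metrics <- function(case,
                                 reference_rule = c("majority",
                                                    "majority_loo", "union"),
                                 cfg = tolerance_config()) {
  stopifnot(inherits(case, "case_study"))
  reference_rule <- match.arg(reference_rule)
  out <- list()
  for (gname in names(case$groups)) {
    set <- case$groups[[gname]]
    n <- length(set$masks)
    if (reference_rule != "majority_loo") {
      ref <- switch(reference_rule,
                    majority = majority_contour(set),
                    union = union_contour(set))
      if (is_empty_mask(ref))
        stop(sprintf("empty %s reference for group '%s' in case '%s'",
                     reference_rule, gname, case$case_id))
    }
    for (i in seq_len(n)) {
      if (reference_rule == "majority_loo") {
        if (n == 1L) {
          ref <- set$masks[[1]]
        } else {
          ref <- majority_contour(observer_set(set$masks[-i],
                                               set$observer_ids[-i],
                                               set$group))
        }
        if (is_empty_mask(ref))
          stop(sprintf(
            "empty leave-one-out reference for group '%s' in case '%s'",
            gname, case$case_id))
      }
      rec <- pair_metrics(set$masks[[i]], ref, cfg)
      rec <- cbind(data.frame(case_id = case$case_id,
                              observer_id = set$observer_ids[i],
                              group = gname,
                              stringsAsFactors = FALSE),
                   rec)
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
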