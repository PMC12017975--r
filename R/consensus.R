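#' Set of observer delineations of one structure
#'
#' Bundles the masks one observer group returned for a case (e.g. all
#' radiologists, or one radiation-oncologist arm). All masks must live on the
#' same voxel grid; observer ids must be unique.
#'
#' @param masks list of [binary_mask()] objects on one shared grid.
#' @param observer_ids character vector of unique labels, one per mask.
#' @param group group label, conventionally one of \code{"RAD"},
#'   \code{"GTV-"}, \code{"GTV+"}.
#' @return An object of class \code{observer_set}.
#' @export
observer_set <- function(masks, observer_ids = NULL, group = NA_character_) {
  stopifnot(is.list(masks), length(masks) >= 1)
  if (!all(vapply(masks, inherits, logical(1), "binary_mask")))
    stop("all elements of `masks` must be binary_mask objects")
  if (is.null(observer_ids))
    observer_ids <- sprintf("obs%02d", seq_along(masks))
  observer_ids <- as.character(observer_ids)
  stopifnot(length(observer_ids) == length(masks))
  if (anyDuplicated(observer_ids))
    stop("observer_ids must be unique")
  for (m in masks[-1]) stop_if_incompatible(masks[[1]], m)
  structure(list(masks = masks, observer_ids = observer_ids,
                 group = as.character(group)),
            class = "observer_set")
}

#' @export
print.observer_set <- function(x, ...) {
  cat("observer_set: ", length(x$masks), " observers",
      if (!is.na(x$group)) paste0(" (group ", x$group, ")"), "\n", sep = "")
  invisible(x)
}

#' Per-voxel agreement fraction
#'
#' For each voxel, the fraction of observers in the set that marked it as
#' foreground. This is the vote map underlying the majority ("median")
#' consensus contour.
#'
#' @param s an [observer_set()].
#' @return A numeric 3-d array in \[0, 1\] with the grid's dimensions.
#' @export
agreement_fraction_map <- function(s) {
  stopifnot(inherits(s, "observer_set"))
  acc <- Reduce(`+`, lapply(s$masks, function(m) m$occupancy * 1))
  acc / length(s$masks)
}

#' Strict-majority ("median") consensus contour
#'
#' A voxel belongs to the consensus iff strictly more than 50\% of the
#' observers marked it. The inequality is strict: with 8 observers a voxel
#' marked by exactly 4 is excluded; 5 of 8 is required. The result may
#' legitimately be empty for highly discordant observers; this raises a
#' warning, not an error (downstream metrics against an empty reference then
#' error explicitly).
#'
#' @param s an [observer_set()].
#' @return A [binary_mask()] on the shared grid.
#' @export
majority_contour <- function(s) {
  frac <- agreement_fraction_map(s)
  occ <- frac > 0.5
  if (!any(occ))
    warning("majority contour is empty (no voxel exceeds the 50% vote)")
  binary_mask(s$masks[[1]]$grid, occ)
}

#' Union ("total") consensus contour
#'
#' A voxel belongs to the union contour iff at least one observer marked it.
#'
#' @param s an [observer_set()].
#' @return A [binary_mask()] on the shared grid.
#' @export
union_contour <- function(s) {
  stopifnot(inherits(s, "observer_set"))
  occ <- Reduce(`|`, lapply(s$masks, function(m) m$occupancy))
  binary_mask(s$masks[[1]]$grid, occ)
}
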