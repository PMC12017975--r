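#' Tolerance and percentile configuration for surface metrics
#'
#' @param sdsc_tolerance distance tolerance in mm for the surface Dice
#'   similarity coefficient (default 3 mm). Distances exactly at the
#'   tolerance count as agreeing (comparison uses \code{<=}).
#' @param hd_percentile percentile (in percent, 0 < p <= 100) of the directed
#'   nearest-surface distances used as the robust Hausdorff distance
#'   (default 98, i.e. HD98).
#' @return An object of class \code{tolerance_config}.
#' @export
tolerance_config <- function(sdsc_tolerance = 3, hd_percentile = 98) {
  stopifnot(is.numeric(sdsc_tolerance), length(sdsc_tolerance) == 1,
            sdsc_tolerance >= 0,
            is.numeric(hd_percentile), length(hd_percentile) == 1,
            hd_percentile > 0, hd_percentile <= 100)
  structure(list(sdsc_tolerance = as.numeric(sdsc_tolerance),
                 hd_percentile = as.numeric(hd_percentile)),
            class = "tolerance_config")
}

as_surface <- function(x) {
  if (inherits(x, "surface_set")) return(x)
  if (inherits(x, "binary_mask")) return(extract_surface(x))
  stop("expected a binary_mask or surface_set")
}

#' Nearest-surface distances between two surfaces
#'
#' For each face element of \code{from}, the Euclidean distance (mm) from its
#' centre to the nearest face centre of \code{to}. This is the primitive
#' behind the surface Dice, percentile Hausdorff and mean
#' distance-to-agreement metrics. The search uses a kd-tree; distances are
#' exact (no grid approximation beyond the face-centre representation
#' itself).
#'
#' @param from,to \code{surface_set} objects (or masks, which are converted
#'   via [extract_surface()]); both must be non-empty.
#' @return Numeric vector of distances in mm, one per element of \code{from}.
#' @export
nearest_surface_distances <- function(from, to) {
  from <- as_surface(from)
  to <- as_surface(to)
  if (nrow(from$centers) == 0 || nrow(to$centers) == 0)
    stop("nearest_surface_distances requires non-empty surfaces")
  cpp_nn_dist(from$centers, to$centers)
}

#' Dice similarity coefficient (DSC)
#'
#' Volumetric overlap: twice the intersection of the two delineations divided
#' by the sum of their sizes, computed on voxel counts. In \[0, 1\];
#' symmetric. Undefined (error) when both masks are empty.
#'
#' @param a,b [binary_mask()] objects on compatible grids.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_if_incompatible(a, b)
  na <- sum(a$occupancy)
  nb <- sum(b$occupancy)
  if (na == 0 && nb == 0)
    stop("Dice coefficient is undefined for two empty masks")
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

#' Surface Dice similarity coefficient (SDSC) at a distance tolerance
#'
#' The area fraction of the two delineation surfaces that lies within the
#' distance tolerance of the other surface: the area of \code{a}'s face
#' elements whose nearest distance to \code{b}'s surface is at most the
#' tolerance, plus the corresponding area of \code{b}'s elements within
#' tolerance of \code{a}, divided by the total area of both surfaces.
#' Area-weighted (on isotropic grids this reduces to face counting);
#' symmetric; in \[0, 1\]. The default 3 mm tolerance follows the surface
#' Dice formulation of Nikolov and colleagues.
#'
#' @param a,b non-empty [binary_mask()] objects on compatible grids.
#' @param cfg a [tolerance_config()].
#' @return SDSC in \[0, 1\].
#' @export
surface_dice <- function(a, b, cfg = tolerance_config()) {
  stop_if_incompatible(a, b)
  if (is_empty_mask(a) || is_empty_mask(b))
    stop("surface Dice requires two non-empty masks")
  sa <- extract_surface(a)
  sb <- extract_surface(b)
  tol <- cfg$sdsc_tolerance
  dab <- cpp_nn_dist(sa$centers, sb$centers)
  dba <- cpp_nn_dist(sb$centers, sa$centers)
  (sum(sa$areas[dab <= tol]) + sum(sb$areas[dba <= tol])) /
    (sum(sa$areas) + sum(sb$areas))
}

#' Directed percentile Hausdorff distance (HD98)
#'
#' The given percentile (default 98th) of all smallest distances from each
#' surface point of the observer's delineation to the reference surface.
#' Directed observer -> reference; at percentile 100 this equals the directed
#' Hausdorff maximum. The percentile is computed over the unweighted
#' per-element distances with linear interpolation between order statistics.
#' Set \code{symmetric = TRUE} for the maximum of both directions.
#'
#' @param observer,reference non-empty [binary_mask()] objects.
#' @param cfg a [tolerance_config()]; \code{hd_percentile} is used.
#' @param symmetric take the maximum of the two directed values
#'   (default \code{FALSE}: directed observer -> reference).
#' @return Distance in mm.
#' @export
directed_percentile_hd <- function(observer, reference,
                                   cfg = tolerance_config(),
                                   symmetric = FALSE) {
  stop_if_incompatible(observer, reference)
  if (is_empty_mask(observer) || is_empty_mask(reference))
    stop("percentile Hausdorff distance requires two non-empty masks")
  so <- extract_surface(observer)
  sr <- extract_surface(reference)
  d <- cpp_nn_dist(so$centers, sr$centers)
  v <- stats::quantile(d, probs = cfg$hd_percentile / 100, names = FALSE,
                       type = 7)
  if (symmetric) {
    d2 <- cpp_nn_dist(sr$centers, so$centers)
    v <- max(v, stats::quantile(d2, probs = cfg$hd_percentile / 100,
                                names = FALSE, type = 7))
  }
  v
}

#' Mean distance to agreement (MDA)
#'
#' Mean and population standard deviation (divisor n) of the nearest-surface
#' distances from the observer's delineation surface to the reference
#' surface.
#'
#' @param observer,reference non-empty [binary_mask()] objects.
#' @return Named numeric vector \code{c(mean = , sd = )} in mm.
#' @export
mean_distance_to_agreement <- function(observer, reference) {
  stop_if_incompatible(observer, reference)
  if (is_empty_mask(observer) || is_empty_mask(reference))
    stop("mean distance to agreement requires two non-empty masks")
  d <- nearest_surface_distances(extract_surface(observer),
                                 extract_surface(reference))
  m <- mean(d)
  c(mean = m, sd = sqrt(mean((d - m)^2)))
}

#' All agreement metrics for one observer-reference pair
#'
#' Convenience wrapper computing DSC, SDSC, HD98, MDA (mean and SD) and both
#' volumes in one call, sharing the surface extraction and distance queries.
#'
#' @param observer,reference non-empty [binary_mask()] objects.
#' @param cfg a [tolerance_config()].
#' @return One-row \code{data.frame} with columns \code{dsc}, \code{sdsc},
#'   \code{hd98}, \code{mda_mean}, \code{mda_sd}, \code{observer_volume},
#'   \code{reference_volume}.
#' @export
pair_metrics <- function(observer, reference, cfg = tolerance_config()) {
  stop_if_incompatible(observer, reference)
  if (is_empty_mask(observer) || is_empty_mask(reference))
    stop("agreement metrics require two non-empty masks")
  so <- extract_surface(observer)
  sr <- extract_surface(reference)
  dor <- cpp_nn_dist(so$centers, sr$centers)
  dro <- cpp_nn_dist(sr$centers, so$centers)
  tol <- cfg$sdsc_tolerance
  mda <- mean(dor)
  data.frame(
    dsc = dice(observer, reference),
    sdsc = (sum(so$areas[dor <= tol]) + sum(sr$areas[dro <= tol])) /
      (sum(so$areas) + sum(sr$areas)),
    hd98 = stats::quantile(dor, probs = cfg$hd_percentile / 100,
                           names = FALSE, type = 7),
    mda_mean = mda,
    mda_sd = sqrt(mean((dor - mda)^2)),
    observer_volume = mask_volume(observer),
    reference_volume = mask_volume(reference)
  )
}
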