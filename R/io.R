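# Reading and writing delineations and study manifests.
#
# Masks travel as NIfTI volumes (values > 0.5 are foreground) on an
# axis-aligned grid; planar contours travel as JSON polygon sets rasterized
# slice-wise at voxel centres. A study manifest (JSON) ties observer masks
# to cases, groups and subtype tags.

#' Write a binary mask as NIfTI
#'
#' The grid geometry is stored in the sform/qform as a diagonal affine
#' (spacing on the diagonal, origin in the translation column).
#'
#' @param m a [binary_mask()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_mask_nifti <- function(m, path) {
  stopifnot(inherits(m, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(m$occupancy), dim = m$grid$shape))
  RNifti::pixdim(img) <- m$grid$spacing
  aff <- diag(c(m$grid$spacing, 1))
  aff[1:3, 4] <- m$grid$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Voxel values strictly greater than 0.5 are treated as foreground. Only
#' axis-aligned geometries are supported: an oblique or rotated affine is
#' rejected, as is a negative-spacing (flipped) one. An all-zero volume
#' yields an empty mask with a warning.
#'
#' @param path NIfTI file path.
#' @param reference_grid optional [voxel_grid()]; if supplied, the file's
#'   geometry must match it within \code{tol} mm or an error is raised.
#' @param tol geometry tolerance in mm.
#' @return A [binary_mask()].
#' @export
read_mask_nifti <- function(path, reference_grid = NULL, tol = 1e-3) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    stop(sprintf("'%s': oblique or rotated grid orientation is unsupported",
                 path))
  if (any(diag(rot) <= 0))
    stop(sprintf("'%s': flipped (negative-spacing) orientation is unsupported",
                 path))
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    stop(sprintf("'%s': expected a 3-d volume", path))
  grid <- voxel_grid(dim(arr), spacing = diag(rot), origin = aff[1:3, 4])
  if (!is.null(reference_grid)) {
    ok <- all(grid$shape == reference_grid$shape) &&
      all(abs(grid$spacing - reference_grid$spacing) <= tol) &&
      all(abs(grid$origin - reference_grid$origin) <= tol)
    if (!ok)
      stop(sprintf("'%s': grid geometry does not match the reference grid",
                   path))
    grid <- reference_grid
  }
  occ <- arr > 0.5
  if (!any(occ))
    warning(sprintf("'%s': mask is empty", path))
  binary_mask(grid, occ)
}

#' Rasterize planar contour polygons onto a voxel grid
#'
#' Contours are given per axial slice as closed polygons in world
#' coordinates (mm). Each slice is rasterized by the even-odd rule evaluated
#' at voxel centres: a centre crossed by an odd number of polygon boundaries
#' is foreground, so nested polygons create holes. A voxel centre lying
#' exactly on a polygon edge counts as inside. Slices are matched to the
#' nearest grid slice; a slice farther than half the slice spacing from any
#' grid plane is an error.
#'
#' @param contours list of slices, each a list with \code{z} (mm) and
#'   \code{polygons} (list of n x 2 matrices of x, y vertices in mm).
#' @param grid the target [voxel_grid()].
#' @return A [binary_mask()].
#' @export
rasterize_contours <- function(contours, grid) {
  occ <- array(FALSE, grid$shape)
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  for (slice in contours) {
    k <- which.min(abs(zs - slice$z))
    if (abs(zs[k] - slice$z) > grid$spacing[3] / 2 + 1e-6)
      stop(sprintf("contour slice at z = %g mm has no matching grid plane",
                   slice$z))
    inside <- rep(FALSE, nrow(pts))
    for (poly in slice$polygons) {
      poly <- as.matrix(poly)
      if (nrow(poly) < 3) stop("polygons need at least 3 vertices")
      inside <- xor(inside, points_in_polygon(pts, poly))
    }
    occ[, , k] <- occ[, , k] | matrix(inside, grid$shape[1], grid$shape[2])
  }
  binary_mask(grid, occ)
}

# even-odd (ray crossing) test, vectorized over points; points exactly on an
# edge count as inside
points_in_polygon <- function(pts, poly, eps = 1e-9) {
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # on-segment check
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (xi + t * dx - px)^2 + (yi + t * dy - py)^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 <= eps^2)
    }
    j <- i
  }
  inside | on_edge
}

#' Read one observer delineation (NIfTI mask or JSON contour set)
#'
#' Dispatches on the file extension: \code{.nii}/\code{.nii.gz} volumes are
#' thresholded at 0.5 via [read_mask_nifti()]; \code{.json} planar contour
#' sets (fields \code{slices: [{z, polygons}]}) are rasterized by the
#' even-odd rule via [rasterize_contours()] onto the reference grid.
#'
#' @param path input file.
#' @param reference_grid the shared planning-CT [voxel_grid()]; required for
#'   contour sets, used as a geometry check for NIfTI.
#' @return A [binary_mask()].
#' @export
read_structure_set <- function(path, reference_grid = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    read_mask_nifti(path, reference_grid)
  } else if (grepl("\\.json$", path)) {
    if (is.null(reference_grid))
      stop("a reference grid is required to rasterize contour sets")
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$slices)) stop(sprintf("'%s': no 'slices' field", path))
    contours <- lapply(obj$slices, function(s) {
      list(z = as.numeric(s$z),
           polygons = lapply(s$polygons, function(p)
             matrix(unlist(p), ncol = 2, byrow = TRUE)))
    })
    rasterize_contours(contours, reference_grid)
  } else {
    stop(sprintf("unsupported delineation format: '%s'", path))
  }
}

#' Write a simulated or assembled study to disk
#'
#' Writes one NIfTI mask per observer (and per-case truth masks when
#' present) plus a JSON manifest tying masks to cases, groups and subtype
#' tags; the manifest is what [read_study_manifest()] and the command-line
#' \code{analyze} step consume.
#'
#' @param cases list of [case_study()] objects.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(cases = list())
  for (case in cases) {
    stopifnot(inherits(case, "case_study"))
    entry <- list(case_id = case$case_id,
                  subtypes = as.list(case$subtypes), observers = list())
    for (g in names(case$groups)) {
      set <- case$groups[[g]]
      for (i in seq_along(set$masks)) {
        fn <- sprintf("%s_%s.nii.gz", case$case_id, set$observer_ids[i])
        write_mask_nifti(set$masks[[i]], file.path(dir, fn))
        entry$observers[[length(entry$observers) + 1L]] <-
          list(observer_id = set$observer_ids[i], group = g, path = fn)
      }
    }
    if (!is.null(case$truth)) {
      fn <- sprintf("%s_truth.nii.gz", case$case_id)
      write_mask_nifti(case$truth, file.path(dir, fn))
      entry$truth_path <- fn
    }
    manifest$cases[[length(manifest$cases) + 1L]] <- entry
  }
  g <- cases[[1]]$groups[[1]]$masks[[1]]$grid
  manifest$grid <- list(shape = g$shape, spacing = g$spacing,
                        origin = g$origin)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a study manifest and its delineations
#'
#' @param path manifest JSON path; observer mask paths are resolved relative
#'   to the manifest's directory.
#' @return List of [case_study()] objects.
#' @export
read_study_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$cases)) stop("manifest has no 'cases' field")
  base <- dirname(path)
  grid <- if (!is.null(obj$grid)) {
    voxel_grid(unlist(obj$grid$shape), unlist(obj$grid$spacing),
               unlist(obj$grid$origin))
  } else NULL
  cases <- list()
  for (entry in obj$cases) {
    cid <- entry$case_id
    if (is.null(cid)) stop("manifest case without case_id")
    obs <- entry$observers
    if (is.null(obs) || !length(obs))
      stop(sprintf("case '%s' has no observers", cid))
    groups <- list()
    for (o in obs) {
      g <- o$group
      if (!is.character(g) || !nzchar(g))
        stop(sprintf("case '%s': observer without group label", cid))
      m <- read_structure_set(file.path(base, o$path), grid)
      groups[[g]]$masks <- c(groups[[g]]$masks, list(m))
      groups[[g]]$ids <- c(groups[[g]]$ids, o$observer_id)
    }
    sets <- lapply(names(groups), function(g)
      observer_set(groups[[g]]$masks, groups[[g]]$ids, g))
    names(sets) <- names(groups)
    truth <- if (!is.null(entry$truth_path))
      read_structure_set(file.path(base, entry$truth_path), grid)
    cases[[cid]] <- case_study(cid, sets,
                               subtypes = unlist(entry$subtypes) %||%
                                 character(),
                               truth = truth)
  }
  cases
}
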