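#' Voxel grid geometry
#'
#' Describes the axis-aligned voxel lattice of a planning CT: the world
#' coordinate (mm) of the centre of voxel (0,0,0), the per-axis voxel edge
#' lengths (mm; anisotropy such as a 3 mm slice thickness is allowed), and the
#' voxel counts per axis. Voxel indices are 0-based and cell-centred: the world
#' position of voxel (i,j,k) is \code{origin + c(i,j,k) * spacing}. Oblique or
#' rotated grids are not representable; loaders reject them.
#'
#' @param shape integer vector of length 3, voxel counts per axis (all > 0).
#' @param spacing numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param origin numeric vector of length 3, world coordinate (mm) of the
#'   centre of voxel (0,0,0).
#' @return An object of class \code{voxel_grid}.
#' @examples
#' voxel_grid(c(64, 64, 32), spacing = c(1, 1, 3))
#' @export
voxel_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(is.na(shape)) || any(shape <= 0L))
    stop("grid shape must be strictly positive on all axes")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be strictly positive on all axes")
  if (any(!is.finite(origin)))
    stop("grid origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid: ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' Binary delineation mask on a voxel grid
#'
#' One observer's delineation (e.g. a gross tumour volume, GTV) rasterized on
#' a shared [voxel_grid()]. Occupancy is stored as a logical 3-d array whose
#' dimensions equal the grid shape.
#'
#' @param grid a [voxel_grid()].
#' @param occupancy logical (or coercible) array with \code{dim} equal to
#'   \code{grid$shape}.
#' @return An object of class \code{binary_mask} with fields \code{grid} and
#'   \code{occupancy}.
#' @export
binary_mask <- function(grid, occupancy) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- array(as.logical(occupancy), dim = dim(occupancy))
  if (is.null(dim(occ)) || length(dim(occ)) != 3L ||
      !all(dim(occ) == grid$shape))
    stop("occupancy array shape must equal grid shape")
  if (anyNA(occ)) stop("occupancy must not contain NA")
  structure(list(grid = grid, occupancy = occ), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask: ", sum(x$occupancy), " / ", prod(x$grid$shape),
      " voxels set, volume ", format(mask_volume(x)), " mm^3\n", sep = "")
  invisible(x)
}

is_empty_mask <- function(m) !any(m$occupancy)

#' Do two masks share the same grid geometry?
#'
#' @param a,b [binary_mask()] objects.
#' @param tol absolute tolerance in mm for origin/spacing comparison.
#' @return \code{TRUE} iff origin, spacing and shape agree within \code{tol};
#'   occupancy is not compared.
#' @export
grids_compatible <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  all(a$grid$shape == b$grid$shape) &&
    all(abs(a$grid$spacing - b$grid$spacing) <= tol) &&
    all(abs(a$grid$origin - b$grid$origin) <= tol)
}

stop_if_incompatible <- function(a, b) {
  if (!grids_compatible(a, b))
    stop("masks are defined on incompatible voxel grids")
  invisible(TRUE)
}

#' Mask volume in cubic millimetres
#'
#' @param m a [binary_mask()].
#' @return Count of foreground voxels times the voxel volume (mm^3).
#' @export
mask_volume <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  sum(m$occupancy) * prod(m$grid$spacing)
}

# World coordinates (mm) of the centres of all foreground voxels, n x 3.
voxel_centers <- function(m) {
  idx <- which(m$occupancy, arr.ind = TRUE) - 1L
  sweep(sweep(idx, 2, m$grid$spacing, `*`), 2, m$grid$origin, `+`)
}
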