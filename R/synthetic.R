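# Synthetic phantoms and simulated observer delineations.
#
# The generator emulates the statistical structure of a multidisciplinary
# delineation study: per-case ground-truth lesions of several morphologies,
# observer groups with different boundary concordance, a systematic volume
# bias for one group, and secondary lesions that some observers omit.

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Deterministic child-seed derivation
#'
#' Mixes a master seed with integer keys (case index, group code, observer
#' index) through repeated Lehmer steps modulo 2^31 - 1, so any single
#' observer's delineation is regenerable in isolation. Pure arithmetic on
#' doubles below 2^53, hence platform-independent.
#'
#' @param master_seed integer master seed.
#' @param ... integer keys.
#' @return Integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(master_seed, ...) {
  m <- 2147483647
  h <- (abs(as.numeric(master_seed)) %% m)
  for (k in c(...)) {
    h <- ((h + as.numeric(k) + 1) * 48271) %% m
  }
  as.integer(max(1, h))
}

group_code <- function(group) {
  match(group, c("TRUTH", iov_groups())) - 1L
}

# world coordinates of every voxel centre, n x 3 (column-major voxel order)
grid_all_centers <- function(grid) {
  sh <- grid$shape; sp <- grid$spacing; or <- grid$origin
  x <- or[1] + (seq_len(sh[1]) - 1) * sp[1]
  y <- or[2] + (seq_len(sh[2]) - 1) * sp[2]
  z <- or[3] + (seq_len(sh[3]) - 1) * sp[3]
  cbind(rep(x, times = sh[2] * sh[3]),
        rep(rep(y, each = sh[1]), times = sh[3]),
        rep(z, each = sh[1] * sh[2]))
}

#' Signed distance to a mask boundary, sampled at voxel centres
#'
#' Euclidean distance (mm) from every voxel centre to the nearest surface
#' face centre of the mask, negative inside the mask and positive outside.
#' Because face centres are offset half a voxel from voxel centres, the value
#' is never exactly zero; thresholding at 0 reproduces the mask.
#'
#' @param m a non-empty [binary_mask()].
#' @return Numeric 3-d array with the grid's dimensions.
#' @export
signed_distance <- function(m) {
  surf <- extract_surface(m)
  d <- cpp_nn_dist(grid_all_centers(m$grid), surf$centers)
  sdf <- array(d, dim = m$grid$shape)
  sdf[m$occupancy] <- -sdf[m$occupancy]
  sdf
}

# spatially correlated Gaussian field, unit marginal SD, mean 0.
# correlation length is the Gaussian smoothing sigma in mm per axis.
gaussian_random_field <- function(grid, correlation_mm) {
  f <- array(stats::rnorm(prod(grid$shape)), dim = grid$shape)
  for (a in 1:3) {
    sigma_vox <- correlation_mm / grid$spacing[a]
    if (sigma_vox <= 0) next
    n <- grid$shape[a]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma_vox^2))
    K <- K / rowSums(K)
    perm <- c(a, setdiff(1:3, a))
    ap <- aperm(f, perm)
    dms <- dim(ap)
    sm <- K %*% matrix(ap, nrow = n)
    f <- aperm(array(sm, dms), order(perm))
  }
  (f - mean(f)) / stats::sd(f)
}

#' Specification of a synthetic ground-truth lesion
#'
#' Supported morphologies: \code{sphere} (radius \code{r} mm),
#' \code{ellipsoid} (semi-axes \code{semi_axes} mm), \code{blob} (a sphere of
#' radius \code{r} whose boundary is deformed by a smoothed random field of
#' amplitude \code{blob_amplitude} mm; the largest connected component is
#' kept so the lesion is connected), and \code{two_lesion} (a primary sphere
#' of radius \code{r} plus a disjoint secondary sphere of radius \code{r2}
#' displaced by \code{separation} mm along the first axis).
#'
#' @param shape one of \code{"sphere"}, \code{"ellipsoid"}, \code{"blob"},
#'   \code{"two_lesion"}.
#' @param grid the [voxel_grid()] to rasterize on.
#' @param r primary radius in mm.
#' @param semi_axes length-3 semi-axes in mm (ellipsoid only).
#' @param r2 secondary-lesion radius in mm (two_lesion only).
#' @param separation centre-to-centre distance in mm between primary and
#'   secondary lesion (two_lesion only; must exceed \code{r + r2}).
#' @param center world coordinate (mm) of the lesion centre; default is the
#'   grid centre.
#' @param blob_amplitude boundary deformation amplitude in mm (blob only).
#' @param blob_correlation_mm deformation field correlation length in mm.
#' @param seed integer; fixes the blob realization exactly.
#' @param fit_margin_mm required clearance (mm) between the lesion and the
#'   grid edge; rasterization errors if violated.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c("sphere", "ellipsoid", "blob",
                                   "two_lesion"),
                         grid, r = 15, semi_axes = c(15, 10, 12), r2 = 7,
                         separation = NULL, center = NULL,
                         blob_amplitude = 4, blob_correlation_mm = 10,
                         seed = 1L, fit_margin_mm = 6) {
  shape <- match.arg(shape)
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(center))
    center <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  if (is.null(separation)) separation <- r + r2 + 10
  if (shape == "two_lesion" && separation <= r + r2)
    stop("two_lesion separation must exceed the sum of the radii")
  structure(list(shape = shape, grid = grid, r = r, semi_axes = semi_axes,
                 r2 = r2, separation = separation, center = center,
                 blob_amplitude = blob_amplitude,
                 blob_correlation_mm = blob_correlation_mm,
                 seed = as.integer(seed), fit_margin_mm = fit_margin_mm),
            class = "phantom_spec")
}

#' Rasterize a ground-truth phantom lesion
#'
#' Deterministic given the spec (including its seed). The result is
#' non-empty, connected per lesion, and errors if the lesion comes closer to
#' the grid edge than the spec's fit margin (surface metrics need room
#' around the lesion).
#'
#' @param spec a [phantom_spec()].
#' @return A [binary_mask()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  pts <- grid_all_centers(grid)
  ctr <- spec$center
  occ <- switch(
    spec$shape,
    sphere = {
      d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
        (pts[, 3] - ctr[3])^2
      d2 <= spec$r^2
    },
    ellipsoid = {
      a <- spec$semi_axes
      ((pts[, 1] - ctr[1]) / a[1])^2 + ((pts[, 2] - ctr[2]) / a[2])^2 +
        ((pts[, 3] - ctr[3]) / a[3])^2 <= 1
    },
    blob = {
      d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
                  (pts[, 3] - ctr[3])^2)
      field <- with_seed(spec$seed,
                         gaussian_random_field(grid,
                                               spec$blob_correlation_mm))
      # clamp the deformation so the lesion keeps a solid core
      field <- pmin(pmax(field, -2), 2)
      d - spec$r + spec$blob_amplitude * as.vector(field) <= 0
    },
    two_lesion = {
      # primary and secondary sphere centred symmetrically about `center`,
      # displaced along the first axis
      c1 <- ctr - c(spec$separation / 2, 0, 0)
      c2 <- ctr + c(spec$separation / 2, 0, 0)
      d1 <- (pts[, 1] - c1[1])^2 + (pts[, 2] - c1[2])^2 +
        (pts[, 3] - c1[3])^2
      d2 <- (pts[, 1] - c2[1])^2 + (pts[, 2] - c2[2])^2 +
        (pts[, 3] - c2[3])^2
      d1 <= spec$r^2 | d2 <= spec$r2^2
    })
  occ <- array(occ, dim = grid$shape)
  if (!any(occ)) stop("phantom rasterized to an empty mask")
  if (spec$shape == "blob") {
    lab <- cpp_label_components(occ, grid$shape)
    sizes <- tabulate(lab[lab > 0])
    occ <- array(lab == which.max(sizes), dim = grid$shape)
  }
  m <- binary_mask(grid, occ)
  check_fit(m, spec$fit_margin_mm)
  ncomp <- attr(cpp_label_components(m$occupancy, grid$shape),
                "n_components")
  expected <- if (spec$shape == "two_lesion") 2L else 1L
  if (ncomp != expected)
    stop(sprintf("phantom has %d connected component(s), expected %d",
                 ncomp, expected))
  m
}

check_fit <- function(m, margin_mm) {
  idx <- which(m$occupancy, arr.ind = TRUE)
  sp <- m$grid$spacing
  sh <- m$grid$shape
  lo <- (apply(idx, 2, min) - 1) * sp          # mm clearance below
  hi <- (sh - apply(idx, 2, max)) * sp         # mm clearance above
  if (any(c(lo, hi) < margin_mm))
    stop(sprintf("lesion violates the %g mm grid-fit margin", margin_mm))
  invisible(TRUE)
}

#' Stochastic model of one observer group's delineation behaviour
#'
#' @param boundary_noise_sd SD (mm) of the spatially correlated radial
#'   perturbation of the truth boundary.
#' @param systematic_margin signed uniform margin in mm: positive dilates,
#'   negative erodes (a negative margin emulates a group that consistently
#'   delineates smaller volumes).
#' @param offset length-3 systematic translation in mm (applied as the
#'   nearest voxel-aligned shift).
#' @param second_lesion_inclusion_prob probability in \[0, 1\] that the
#'   observer includes the secondary lesion when the truth has one
#'   (emulates lesions interpreted as tumour by some observers and benign
#'   by others).
#' @param noise_correlation_mm correlation length (Gaussian sigma, mm) of
#'   the boundary-noise field; default 5 mm gives spatially coherent over-
#'   and under-contouring rather than voxel-level speckle.
#' @return An object of class \code{observer_model}.
#' @export
observer_model <- function(boundary_noise_sd = 0, systematic_margin = 0,
                           offset = c(0, 0, 0),
                           second_lesion_inclusion_prob = 1,
                           noise_correlation_mm = 5) {
  stopifnot(boundary_noise_sd >= 0,
            second_lesion_inclusion_prob >= 0,
            second_lesion_inclusion_prob <= 1,
            length(offset) == 3, noise_correlation_mm > 0)
  structure(list(boundary_noise_sd = boundary_noise_sd,
                 systematic_margin = systematic_margin,
                 offset = as.numeric(offset),
                 second_lesion_inclusion_prob = second_lesion_inclusion_prob,
                 noise_correlation_mm = noise_correlation_mm),
            class = "observer_model")
}

#' Simulate one observer's delineation of a known truth
#'
#' The observer mask is built by thresholding the truth's signed distance
#' function: a voxel is included when
#' \code{sdf - margin + noise <= 0}, where \code{noise} is a smoothed
#' Gaussian random field scaled to the model's boundary-noise SD. The mask
#' is then translated by the model offset (rounded to whole voxels), and, if
#' the truth has a secondary lesion, that lesion is dropped with probability
#' \code{1 - second_lesion_inclusion_prob}. Deterministic given
#' \code{draw_seed}. With an all-zero model the output equals the truth.
#'
#' @param truth non-empty ground-truth [binary_mask()].
#' @param model an [observer_model()].
#' @param draw_seed integer seed for this observer's random draws.
#' @param sdf optional precomputed [signed_distance()] of the truth (a
#'   per-case cache; recomputed when absent).
#' @return A [binary_mask()] on the truth's grid.
#' @export
simulate_observer <- function(truth, model, draw_seed, sdf = NULL) {
  stopifnot(inherits(truth, "binary_mask"), inherits(model, "observer_model"))
  if (is_empty_mask(truth)) stop("truth mask is empty")
  grid <- truth$grid
  if (is.null(sdf)) sdf <- signed_distance(truth)
  with_seed(draw_seed, {
    include_secondary <- stats::runif(1) < model$second_lesion_inclusion_prob
    level <- sdf - model$systematic_margin
    if (model$boundary_noise_sd > 0) {
      # winsorize at 3 SD: a human observer's boundary displacement is
      # bounded; also keeps extreme draws from swallowing small lesions
      field <- pmin(pmax(gaussian_random_field(grid,
                                               model$noise_correlation_mm),
                         -3), 3)
      level <- level + model$boundary_noise_sd * field
    }
    occ <- level <= 0
    lab <- cpp_label_components(truth$occupancy, grid$shape)
    if (attr(lab, "n_components") >= 2L && !include_secondary)
      occ <- keep_primary_component(occ, truth, lab, grid)
    shift_vox <- round(model$offset / grid$spacing)
    if (any(shift_vox != 0)) occ <- translate_occupancy(occ, shift_vox)
    if (!any(occ))
      stop(sprintf(
        "perturbation emptied the mask (noise_sd=%g, margin=%g mm)",
        model$boundary_noise_sd, model$systematic_margin))
    binary_mask(grid, occ)
  })
}

# drop every observer voxel nearer to a non-primary truth component than to
# the primary one (primary = largest truth component)
keep_primary_component <- function(occ, truth, lab, grid) {
  sizes <- tabulate(lab[lab > 0])
  primary <- which.max(sizes)
  on_idx <- which(occ)
  if (!length(on_idx)) return(occ)
  pts <- grid_all_centers(grid)[on_idx, , drop = FALSE]
  dmat <- vapply(seq_along(sizes), function(comp) {
    comp_mask <- binary_mask(grid, array(lab == comp, grid$shape))
    cpp_nn_dist(pts, voxel_centers(comp_mask))
  }, numeric(nrow(pts)))
  nearest <- max.col(-dmat, ties.method = "first")
  occ[on_idx[nearest != primary]] <- FALSE
  occ
}

translate_occupancy <- function(occ, shift_vox) {
  out <- array(FALSE, dim(occ))
  dm <- dim(occ)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift_vox[a]
    if (abs(s) >= dm[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):dm[a]; src[[a]] <- 1:(dm[a] - s) }
    else { dst[[a]] <- 1:(dm[a] + s); src[[a]] <- (1 - s):dm[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  out
}
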