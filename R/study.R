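#' Specification of a full synthetic delineation study
#'
#' Bundles the per-case phantom specifications, the per-group observer
#' counts and behaviour models, and a master seed from which every random
#' draw is derived. The whole simulated study is a pure function of this
#' object.
#'
#' @param phantoms named list of [phantom_spec()] objects; names are the
#'   case ids.
#' @param group_models named list (one entry per group label) of
#'   [observer_model()] objects.
#' @param group_sizes named integer vector of observer counts per group
#'   (all >= 1).
#' @param subtype_tags optional named list mapping case ids to character
#'   vectors of subtype tags.
#' @param master_seed integer master seed.
#' @return An object of class \code{study_spec}.
#' @export
study_spec <- function(phantoms, group_models, group_sizes,
                       subtype_tags = list(), master_seed = 1L) {
  stopifnot(is.list(phantoms), length(phantoms) >= 1,
            !is.null(names(phantoms)),
            is.list(group_models),
            setequal(names(group_models), names(group_sizes)),
            all(group_sizes >= 1))
  if (anyDuplicated(names(phantoms))) stop("case ids must be unique")
  structure(list(phantoms = phantoms, group_models = group_models,
                 group_sizes = group_sizes, subtype_tags = subtype_tags,
                 master_seed = as.integer(master_seed)),
            class = "study_spec")
}

#' Default synthetic study: 14 cases, 8 + 6 + 6 observers
#'
#' Emulates the structure of a multidisciplinary delineation study of
#' locally recurrent rectal cancer: 14 cases on a 1 x 1 x 3 mm planning-CT
#' grid, delineated by 8 radiologists (RAD) and two radiation-oncologist
#' arms of 6 (GTV-, contouring unaided, and GTV+, contouring with the
#' radiology consensus available). Group behaviour defaults:
#' \itemize{
#'   \item RAD: boundary noise SD 3 mm and a systematic -3 mm margin, so
#'     radiologist volumes are consistently smaller than the truth;
#'     secondary lesions included with probability 0.5.
#'   \item GTV-: boundary noise SD 4 mm, no systematic margin, secondary
#'     lesions included with probability 0.9.
#'   \item GTV+: boundary noise SD 2 mm (half the unaided arm, encoding the
#'     higher concordance of the radiology-aided arm), secondary lesions
#'     included with probability 0.7.
#' }
#' Case morphologies follow the recurrence-subtype memberships of
#' [lrrc_subtypes()]: multifocal cases are two-lesion phantoms, fibrotic
#' cases irregular blobs, solitary-node cases small spheres, the remaining
#' lateral/intraluminal cases ellipsoids or spheres.
#'
#' @param master_seed integer master seed.
#' @param grid the shared [voxel_grid()] (default 72 x 72 x 36 voxels at
#'   1 x 1 x 3 mm).
#' @return A [study_spec()].
#' @export
default_study_spec <- function(master_seed = 1L,
                               grid = voxel_grid(c(72, 72, 36),
                                                 spacing = c(1, 1, 3))) {
  subtypes <- lrrc_subtypes()
  tags <- list()
  for (sd in subtypes)
    for (cid in sd$case_ids)
      tags[[cid]] <- c(tags[[cid]], sd$subtype)

  case_ids <- sprintf("case%02d", 1:14)
  phantoms <- list()
  for (i in seq_along(case_ids)) {
    cid <- case_ids[i]
    tg <- tags[[cid]]
    seed <- child_seed(master_seed, i, 99L)
    phantoms[[cid]] <-
      if ("multifocal" %in% tg || cid == "case01") {
        # case01 is the lateral case with a second lesion that observers
        # may consider benign
        phantom_spec("two_lesion", grid, r = 12, r2 = 7, separation = 32,
                     seed = seed)
      } else if ("fibrotic" %in% tg) {
        phantom_spec("blob", grid, r = 13, blob_amplitude = 4,
                     blob_correlation_mm = 10, seed = seed)
      } else if ("solitary lymph node" %in% tg) {
        phantom_spec("sphere", grid, r = 8, seed = seed)
      } else if (i %% 2 == 0) {
        phantom_spec("ellipsoid", grid, semi_axes = c(16, 11, 13),
                     seed = seed)
      } else {
        phantom_spec("sphere", grid, r = 14, seed = seed)
      }
  }

  group_models <- list(
    "RAD" = observer_model(boundary_noise_sd = 3, systematic_margin = -3,
                           second_lesion_inclusion_prob = 0.5),
    "GTV-" = observer_model(boundary_noise_sd = 4,
                            second_lesion_inclusion_prob = 0.9),
    "GTV+" = observer_model(boundary_noise_sd = 2,
                            second_lesion_inclusion_prob = 0.7)
  )
  study_spec(phantoms, group_models,
             group_sizes = c("RAD" = 8L, "GTV-" = 6L, "GTV+" = 6L),
             subtype_tags = tags, master_seed = master_seed)
}

#' Recurrence-subtype case groupings of the default study
#'
#' The five (overlapping) morphology subtypes and their member cases used by
#' the subtype analysis of the default 14-case study: lateral (cases 1, 7,
#' 8, 10), solitary lymph node (7, 10), multifocal (2, 4, 5, 6, 13),
#' anastomotic/intraluminal (3, 6, 9, 14) and fibrotic (2, 3, 11, 12).
#'
#' @return List of [subtype_definition()] objects.
#' @export
lrrc_subtypes <- function() {
  cid <- function(i) sprintf("case%02d", i)
  list(
    subtype_definition("lateral", cid(c(1, 7, 8, 10))),
    subtype_definition("solitary lymph node", cid(c(7, 10))),
    subtype_definition("multifocal", cid(c(2, 4, 5, 6, 13))),
    subtype_definition("anastomotic/intraluminal", cid(c(3, 6, 9, 14))),
    subtype_definition("fibrotic", cid(c(2, 3, 11, 12)))
  )
}

#' Simulate a full multi-observer study
#'
#' For each case, rasterizes the ground-truth phantom, caches its signed
#' distance function, and draws every observer's delineation with a child
#' seed derived from the master seed via [child_seed()] (keys: case index,
#' group code, observer index). The result is a pure function of the spec:
#' the same spec yields a byte-identical study.
#'
#' @param spec a [study_spec()].
#' @return List of [case_study()] objects; each carries the truth mask and
#'   the generating models in its metadata.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  cases <- vector("list", length(spec$phantoms))
  names(cases) <- names(spec$phantoms)
  for (ci in seq_along(spec$phantoms)) {
    cid <- names(spec$phantoms)[ci]
    truth <- make_phantom(spec$phantoms[[cid]])
    sdf <- signed_distance(truth)
    groups <- list()
    for (g in names(spec$group_models)) {
      model <- spec$group_models[[g]]
      n <- spec$group_sizes[[g]]
      masks <- vector("list", n)
      for (oi in seq_len(n)) {
        seed <- child_seed(spec$master_seed, ci, group_code(g), oi)
        masks[[oi]] <- draw_nonempty_observer(truth, model, seed, sdf)
      }
      groups[[g]] <- observer_set(
        masks, sprintf("%s_%02d", chartr("-+", "mp", g), seq_len(n)), g)
    }
    cases[[cid]] <- case_study(
      cid, groups,
      subtypes = spec$subtype_tags[[cid]] %||% character(),
      truth = truth,
      metadata = list(models = spec$group_models,
                      phantom = spec$phantoms[[cid]],
                      master_seed = spec$master_seed, case_index = ci))
  }
  cases
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An observer never submits an empty contour: if a draw's perturbation
# swallows the whole lesion (possible for strong erosion/noise on a small
# lesion), redraw with a deterministically derived retry seed. Conditioning
# on non-emptiness is part of the study generator's definition.
draw_nonempty_observer <- function(truth, model, seed, sdf,
                                   max_attempts = 25L) {
  for (attempt in seq_len(max_attempts)) {
    s <- if (attempt == 1L) seed else child_seed(seed, 7919L, attempt)
    m <- tryCatch(simulate_observer(truth, model, s, sdf = sdf),
                  error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
  stop(sprintf(
    "could not draw a non-empty observer mask in %d attempts (noise_sd=%g, margin=%g mm)",
    max_attempts, model$boundary_noise_sd, model$systematic_margin))
}
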