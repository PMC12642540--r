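## Counterfactual prediction modes. All modes are pure functions over
## the trained model: labels are edited on a copy, the generative path
## is fully re-run (kernel dispatch sees the edited labels, so effects
## propagate spatially), and identity edits reproduce the unedited
## reconstruction exactly.

edited_labels <- function(model, target_spots, edits) {
  ds <- model$ds
  labels <- list(perturbation = ds$perturbation, disease = ds$disease,
                 slide = ds$slide, continuous = ds$continuous)
  for (nm in names(edits)) {
    if (nm %in% c("perturbation", "disease", "slide")) {
      lv <- as.character(edits[[nm]])
      if (!lv %in% levels(ds[[nm]]))
        stop(sprintf("unknown %s level '%s'", nm, lv))
      labels[[nm]][target_spots] <- lv
    } else if (!is.null(ds$continuous) && nm %in% names(ds$continuous)) {
      rng <- model$cb$continuous[[nm]]$range
      v <- edits[[nm]]
      if (v < rng[1] || v > rng[2])
        warning(sprintf("continuous edit '%s'=%g outside the trained range [%g, %g]: extrapolating",
                        nm, v, rng[1], rng[2]))
      labels$continuous[[nm]][target_spots] <- v
    } else {
      stop(sprintf("unknown attribute '%s' in edit", nm))
    }
  }
  labels
}

#' Counterfactual perturbation swap for observed spots
#'
#' Replaces the perturbation (and optionally disease/slide/continuous)
#' embedding blocks of the target spots with the target state's codebook
#' rows, keeps their basal block, and re-runs the full generative path
#' with the edited labels so effects propagate through the spatial
#' kernel to unedited neighbors (but never across slides).
#'
#' @param model a trained `nichegp_model`.
#' @param target_spots integer indices of the spots to edit.
#' @param edits named list of attribute edits, e.g.
#'   `list(perturbation = "KO")`, or `list(day = 50)` for a continuous
#'   attribute.
#' @param predict_spots spot indices to return predictions for (default
#'   all spots, so propagated effects are visible).
#' @param g,seed,intervals,level as in [predict_mean()].
#' @return a `nichegp_prediction`.
#' @export
swap_perturbation <- function(model, target_spots, edits,
                              predict_spots = NULL,
                              g = model$cfg$g_infer, seed = 1,
                              intervals = FALSE, level = 0.95) {
  labels <- edited_labels(model, target_spots, edits)
  ngp_infer(model, labels = labels, predict_idx = predict_spots,
            g = g, seed = seed, intervals = intervals, level = level,
            provenance = list(mode = "swap", edits = edits,
                              target_spots = target_spots))
}

#' Impute unseen spots with known attributes, then (optionally) perturb
#'
#' The basal embedding of each new spot is the mean of the basal
#' embeddings of its k nearest observed neighbors on the same slide;
#' attribute blocks come from the codebooks for the supplied labels; the
#' GP latent is the sparse posterior evaluated at the new coordinates.
#'
#' @param model a trained `nichegp_model`.
#' @param new_coords matrix of new locations (same dimensionality and
#'   rescaled range as the training coordinates).
#' @param labels named list with `perturbation` (required) and optional
#'   `disease`, `slide`, `continuous` per new spot.
#' @param k number of spatial neighbors for the basal average, default 6.
#' @param g,seed,intervals,level as in [predict_mean()].
#' @return a `nichegp_prediction`.
#' @export
impute_with_attributes <- function(model, new_coords, labels, k = 6,
                                   g = model$cfg$g_infer, seed = 1,
                                   intervals = FALSE, level = 0.95) {
  ngp_infer(model, new_coords = new_coords, new_labels = labels,
            k_neighbors = k, g = g, seed = seed,
            intervals = intervals, level = level,
            provenance = list(mode = "impute_with_attributes",
                              labels = labels))
}

#' Impute unseen spots with no known attributes
#'
#' Gaussian latents are neighbor means (means of the neighbors'
#' posterior means and standard deviations); the GP latent comes from
#' the sparse posterior at the new coordinates; the kernel label (and
#' slide) is copied from the nearest observed neighbor.
#'
#' @inheritParams impute_with_attributes
#' @param slide optional slide level for the new spots (multi-slide
#'   data: per-slide coordinate systems overlap, so the slide must be
#'   named; single-slide data needs nothing).
#' @return a `nichegp_prediction`.
#' @export
impute_blind <- function(model, new_coords, k = 6, slide = NULL,
                         g = model$cfg$g_infer, seed = 1,
                         intervals = FALSE, level = 0.95) {
  labels <- if (!is.null(slide)) {
    list(slide = rep(slide, length.out = nrow(as.matrix(new_coords))))
  }
  ngp_infer(model, new_coords = new_coords, new_labels = labels,
            k_neighbors = k, g = g, seed = seed,
            intervals = intervals, level = level,
            provenance = list(mode = "impute_blind"))
}

lattice_spacing <- function(coords) {
  n <- nrow(coords)
  sub <- if (n > 400) sample.int(n, 400) else seq_len(n)
  d <- as.matrix(stats::dist(coords[sub, , drop = FALSE]))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' Resolution enhancement by virtual midpoints
#'
#' Places virtual spots at midpoints of adjacent observed spot pairs
#' (pairs closer than 1.5x the native lattice spacing), deduplicates
#' coincident midpoints, and imputes them (blind by default, or with
#' supplied attribute labels); a subsequent perturbation edit can be
#' expressed through `labels`.
#'
#' @param model a trained `nichegp_model`.
#' @param slide optional slide level to enhance (default first slide).
#' @param virtual_coords optional explicit virtual locations (skips
#'   midpoint construction).
#' @param labels optional attribute labels for the virtual spots (one
#'   value each, recycled), switching to attribute-aware imputation.
#' @param k,g,seed as in [impute_blind()].
#' @return a `nichegp_prediction` at the virtual spots.
#' @export
enhance_resolution <- function(model, slide = NULL, virtual_coords = NULL,
                               labels = NULL, k = 6,
                               g = model$cfg$g_infer, seed = 1) {
  ds <- model$ds
  if (is.null(virtual_coords)) {
    if (is.null(slide)) slide <- levels(ds$slide)[1]
    idx <- which(ds$slide == slide)
    co <- ds$coords[idx, , drop = FALSE]
    sp <- lattice_spacing(co)
    d <- as.matrix(stats::dist(co))
    pairs <- which(d > 0 & d <= 1.5 * sp & upper.tri(d), arr.ind = TRUE)
    if (nrow(pairs) == 0) stop("no adjacent pairs found on the slide")
    mid <- (co[pairs[, 1], , drop = FALSE] + co[pairs[, 2], , drop = FALSE]) / 2
    key <- apply(round(mid, 8), 1, paste, collapse = "_")
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sprintf("deduplicated %d coincident virtual spots", sum(dup)))
      mid <- mid[!dup, , drop = FALSE]
    }
    obs_key <- apply(round(co, 8), 1, paste, collapse = "_")
    mid <- mid[!apply(round(mid, 8), 1, paste, collapse = "_") %in% obs_key, ,
               drop = FALSE]
    virtual_coords <- mid
  }
  if (is.null(labels)) {
    impute_blind(model, virtual_coords, k = k, g = g, seed = seed)
  } else {
    M <- nrow(virtual_coords)
    labels <- lapply(labels, function(v) rep(v, length.out = M))
    impute_with_attributes(model, virtual_coords, labels, k = k, g = g,
                           seed = seed)
  }
}

#' Fill a tissue region with virtual spots and impute them
#'
#' Generates a lattice at the slide's native spacing inside a polygonal
#' region (or at explicitly supplied target coordinates), removes
#' locations coinciding with observed spots, and imputes expression
#' (blind, or with attributes for a subsequent in-silico perturbation).
#'
#' @param model a trained `nichegp_model`.
#' @param polygon two-column matrix of polygon vertices (region
#'   boundary) in rescaled coordinates.
#' @param slide slide level the region belongs to (default first).
#' @param labels optional attribute labels for the filled spots.
#' @param k,g,seed as in [impute_blind()].
#' @return a `nichegp_prediction` at the filled spots; provenance
#'   records the region and any edit.
#' @export
fill_region <- function(model, polygon, slide = NULL, labels = NULL,
                        k = 6, g = model$cfg$g_infer, seed = 1) {
  ds <- model$ds
  if (is.null(slide)) slide <- levels(ds$slide)[1]
  idx <- which(ds$slide == slide)
  co <- ds$coords[idx, 1:2, drop = FALSE]
  sp <- lattice_spacing(co)
  polygon <- as.matrix(polygon)
  gx <- seq(min(polygon[, 1]), max(polygon[, 1]), by = sp)
  gy <- seq(min(polygon[, 2]), max(polygon[, 2]), by = sp)
  cand <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- mgcv::in.out(rbind(polygon, polygon[1, ]), cand)
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) > 0) {
    obs_key <- apply(round(co, 6), 1, paste, collapse = "_")
    cand <- cand[!apply(round(cand, 6), 1, paste, collapse = "_") %in% obs_key, ,
                 drop = FALSE]
  }
  if (nrow(cand) == 0) stop("empty region: no virtual spots inside the polygon")
  if (ncol(ds$coords) == 3) {
    z <- stats::median(ds$coords[idx, 3])
    cand <- cbind(cand, z)
  }
  pred <- if (is.null(labels)) {
    impute_blind(model, cand, k = k, g = g, seed = seed)
  } else {
    M <- nrow(cand)
    labels <- lapply(labels, function(v) rep(v, length.out = M))
    impute_with_attributes(model, cand, labels, k = k, g = g, seed = seed)
  }
  pred$provenance$mode <- "fill_region"
  pred$provenance$polygon <- polygon
  if (!is.null(labels)) pred$provenance$edits <- labels
  pred
}

#' Perturb the surrounding niche and predict the (unedited) center
#'
#' Edits the attributes of the surround set only and returns predictions
#' for the center set, capturing influence propagated through the GP.
#'
#' @param model a trained `nichegp_model`.
#' @param center_spots,surround_spots disjoint integer index sets.
#' @param surround_edits named list of edits applied to the surround.
#' @param g,seed as in [predict_mean()].
#' @return a `nichegp_prediction` for the center spots.
#' @export
edit_niche <- function(model, center_spots, surround_spots, surround_edits,
                       g = model$cfg$g_infer, seed = 1) {
  if (length(intersect(center_spots, surround_spots)) > 0)
    stop("center and surround sets must be disjoint")
  labels <- edited_labels(model, surround_spots, surround_edits)
  ngp_infer(model, labels = labels, predict_idx = center_spots,
            g = g, seed = seed,
            provenance = list(mode = "edit_niche", edits = surround_edits,
                              surround = surround_spots))
}

#' Counterfactual prediction on 3D serial-section data
#'
#' Identical pipeline with 3D Cauchy kernels: edits on one section
#' produce predicted effects on adjacent sections that decay with the
#' learned z scale. Requires a model trained on 3D coordinates.
#'
#' @param model a `nichegp_model` trained with D = 3.
#' @param target_spots,edits,predict_spots,g,seed as in
#'   [swap_perturbation()]; with no edits the reconstruction is
#'   returned.
#' @return a `nichegp_prediction`.
#' @export
predict_3d <- function(model, target_spots = NULL, edits = NULL,
                       predict_spots = NULL, g = model$cfg$g_infer,
                       seed = 1) {
  if (ncol(model$ds$coords) != 3)
    stop("model was trained on 2D coordinates; predict_3d needs a 3D checkpoint")
  if (is.null(edits)) {
    predict_mean(model, spots = predict_spots, g = g, seed = seed)
  } else {
    swap_perturbation(model, target_spots, edits,
                      predict_spots = predict_spots, g = g, seed = seed)
  }
}
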