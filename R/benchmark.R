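## Benchmark harness: task samplers mirroring the patch / border /
## niche / cross-niche evaluation designs, kNN baselines, masking-based
## imputation evaluation, and predictive-interval coverage.

## k nearest neighbors of every spot within its own slide
spot_knn <- function(ds, k = 6) {
  n <- n_spots(ds)
  out <- matrix(NA_integer_, n, k)
  for (sl in levels(ds$slide)) {
    idx <- which(ds$slide == sl)
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(ds$coords[idx, , drop = FALSE]))
    diag(d) <- Inf
    kk <- min(k, length(idx) - 1)
    for (i in seq_along(idx)) {
      out[idx[i], seq_len(kk)] <- idx[order(d[i, ], seq_along(idx))[seq_len(kk)]]
    }
  }
  out
}

#' Border-spot predicate
#'
#' A spot lies on a border when the most dominant spot type among its 6
#' nearest neighbors constitutes less than 50% of them. Spot types are
#' taken from the `disease` attribute (the spot-type annotation).
#'
#' @param ds a `spatial_dataset`.
#' @param k neighborhood size, default 6.
#' @return logical vector per spot.
#' @export
is_border_spot <- function(ds, k = 6) {
  nn <- spot_knn(ds, k)
  types <- as.integer(ds$disease)
  vapply(seq_len(n_spots(ds)), function(i) {
    nb <- nn[i, !is.na(nn[i, ])]
    if (length(nb) == 0) return(FALSE)
    max(table(types[nb])) / length(nb) < 0.5
  }, logical(1))
}

## composition of spot types among neighbors within a radius
niche_composition <- function(ds, radius) {
  n <- n_spots(ds)
  types <- as.integer(ds$disease)
  nt <- nlevels(ds$disease)
  comp <- matrix(0, n, nt)
  for (sl in levels(ds$slide)) {
    idx <- which(ds$slide == sl)
    d <- as.matrix(stats::dist(ds$coords[idx, , drop = FALSE]))
    for (i in seq_along(idx)) {
      nb <- idx[d[i, ] > 0 & d[i, ] <= radius]
      if (length(nb) > 0) comp[idx[i], ] <- tabulate(types[nb], nt) / length(nb)
    }
  }
  comp
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Sample benchmark task instances
#'
#' Task designs:
#' \describe{
#'   \item{patch_within}{a contiguous patch of `source_state` spots to
#'     be edited to `target_state`, with truth spots (observed
#'     `target_state`) nearby (within `radius_near`) in the same niche.}
#'   \item{border}{the patch is drawn from border spots (6-neighbor
#'     dominance < 50%); truth spots are border `target_state` spots
#'     within `radius_near`.}
#'   \item{patch_cross}{truth spots are not in proximity (farther than
#'     `radius_far`) but sit in a similar niche: cosine similarity of
#'     surrounding-type composition >= 0.8.}
#'   \item{niche}{a center patch of `source_state` plus its surrounding
#'     ring; truth is a `source_state` patch whose niche composition is
#'     dominated by `target_niche`.}
#' }
#' Samplers are deterministic under `seed`; instances re-check their
#' defining predicate and error naming the failed constraint when the
#' dataset admits no valid configuration.
#'
#' @param ds a `spatial_dataset` (with the `disease` spot-type
#'   annotation for border/niche tasks).
#' @param task task name.
#' @param source_state,target_state perturbation levels (edit from/to).
#' @param target_niche disease level (niche task only).
#' @param patch_size spots per patch (1, 4 or 8 in the standard design).
#' @param n_repeats number of instances to sample.
#' @param seed RNG seed.
#' @param radius_near,radius_far proximity thresholds in coordinate
#'   units (defaults 5 and 8 lattice spacings).
#' @return list of `task_instance` objects with `perturb_spots`,
#'   `predict_spots`, `truth_spots`, states and the task name.
#' @export
sample_tasks <- function(ds, task = c("patch_within", "border", "patch_cross", "niche"),
                         source_state, target_state = NULL,
                         target_niche = NULL,
                         patch_size = 4, n_repeats = 10, seed = 1,
                         radius_near = NULL, radius_far = NULL) {
  task <- match.arg(task)
  set.seed(seed)
  sp <- lattice_spacing(ds$coords)
  if (is.null(radius_near)) radius_near <- 5 * sp
  if (is.null(radius_far)) radius_far <- 8 * sp
  src <- which(ds$perturbation == source_state)
  if (length(src) == 0) stop(sprintf("no spots in source state '%s'", source_state))
  tgt <- if (!is.null(target_state)) which(ds$perturbation == target_state) else integer(0)
  if (task != "niche" && length(tgt) == 0)
    stop(sprintf("no spots in target state '%s'", target_state))
  border <- if (task == "border") is_border_spot(ds) else NULL
  comp <- if (task %in% c("patch_cross", "niche")) niche_composition(ds, 2 * sp) else NULL

  dist_to <- function(i, set) {
    if (length(set) == 0) return(numeric(0))
    sqrt(colSums((t(ds$coords[set, , drop = FALSE]) - ds$coords[i, ])^2))
  }
  grow_patch <- function(seed_spot, pool) {
    if (patch_size == 1) return(seed_spot)
    d <- dist_to(seed_spot, pool)
    pool[order(d, pool)][seq_len(min(patch_size, length(pool)))]
  }

  instances <- list()
  cand <- switch(task,
    patch_within = src[vapply(src, function(i) {
      near <- tgt[dist_to(i, tgt) <= radius_near]
      any(ds$disease[near] == ds$disease[i])
    }, logical(1))],
    border = {
      bs <- src[border[src]]
      bs[vapply(bs, function(i) {
        near <- tgt[dist_to(i, tgt) <= radius_near]
        any(border[near])
      }, logical(1))]
    },
    patch_cross = src[vapply(src, function(i) {
      far <- tgt[dist_to(i, tgt) > radius_far]
      any(vapply(far, function(j) cosine_sim(comp[i, ], comp[j, ]) >= 0.8,
                 logical(1)))
    }, logical(1))],
    niche = {
      if (is.null(target_niche)) stop("niche task needs a target_niche")
      src[vapply(src, function(i) {
        ok <- src[ds$disease[src] == target_niche |
                    comp[src, match(target_niche, levels(ds$disease))] >= 0.5]
        length(setdiff(ok, i)) > 0
      }, logical(1))]
    })
  if (length(cand) == 0)
    stop(sprintf("no valid configuration for task '%s': no candidate seed satisfies the %s constraint",
                 task, if (task == "border") "border-with-border-truth"
                       else if (task == "patch_cross") "similar-niche-at-distance"
                       else "same-niche-truth-nearby"))
  seeds <- cand[sample.int(length(cand), n_repeats,
                           replace = length(cand) < n_repeats)]
  for (r in seq_len(n_repeats)) {
    i <- seeds[r]
    patch <- grow_patch(i, if (task == "border") src[border[src]] else src)
    inst <- switch(task,
      patch_within = {
        near <- tgt[dist_to(i, tgt) <= radius_near]
        truth <- near[ds$disease[near] == ds$disease[i]]
        list(perturb_spots = patch, predict_spots = patch, truth_spots = truth)
      },
      border = {
        near <- tgt[dist_to(i, tgt) <= radius_near]
        truth <- near[border[near]]
        list(perturb_spots = patch, predict_spots = patch, truth_spots = truth)
      },
      patch_cross = {
        far <- tgt[dist_to(i, tgt) > radius_far]
        sim <- vapply(far, function(j) cosine_sim(comp[i, ], comp[j, ]), numeric(1))
        truth <- far[sim >= 0.8]
        list(perturb_spots = patch, predict_spots = patch, truth_spots = truth)
      },
      niche = {
        ring <- setdiff(which(dist_to(i, seq_len(n_spots(ds))) <= 1.5 * sp), patch)
        nt <- match(target_niche, levels(ds$disease))
        pool <- setdiff(src[ds$disease[src] == target_niche |
                              comp[src, nt] >= 0.5], patch)
        truth <- grow_patch(pool[1], pool)
        list(perturb_spots = ring, predict_spots = patch, truth_spots = truth)
      })
    inst$task <- task
    inst$patch_size <- patch_size
    inst$source_state <- source_state
    inst$target_state <- target_state
    inst$target_niche <- target_niche
    if (length(inst$truth_spots) == 0)
      stop(sprintf("task '%s': sampled instance has empty truth set", task))
    instances[[r]] <- structure(inst, class = "task_instance")
  }
  instances
}

#' kNN counterfactual baselines
#'
#' Predicts each spot's post-edit profile as the mean normalized
#' expression of its k nearest spots *within the target state*, nearest
#' by spatial distance (`kNN-SP`) or by normalized-expression Euclidean
#' distance (`kNN-GEX`).
#'
#' @param ds a normalized `spatial_dataset`.
#' @param task a `task_instance` (supplies `predict_spots` and
#'   `target_state`).
#' @param space `"spatial"` or `"expression"`.
#' @param k neighbors, default 6 (all target-state spots, with a
#'   warning, when fewer exist).
#' @return matrix predictions (predict spots x genes, NEX scale).
#' @export
knn_baseline <- function(ds, task, space = c("spatial", "expression"), k = 6) {
  space <- match.arg(space)
  if (is.null(ds$normalized)) ds <- normalize_counts(ds)
  tgt <- which(ds$perturbation == task$target_state)
  if (length(tgt) == 0) stop("no spots in the target state")
  if (length(tgt) < k) {
    warning(sprintf("only %d target-state spots; using all", length(tgt)))
    k <- length(tgt)
  }
  feats <- if (space == "spatial") ds$coords else ds$normalized
  pred <- t(vapply(task$predict_spots, function(i) {
    d <- sqrt(colSums((t(feats[tgt, , drop = FALSE]) - feats[i, ])^2))
    nb <- tgt[order(d, tgt)[seq_len(k)]]
    colMeans(ds$normalized[nb, , drop = FALSE])
  }, numeric(n_genes(ds))))
  rownames(pred) <- ds$spot_ids[task$predict_spots]
  pred
}

#' Masking-based imputation evaluation
#'
#' Masks spots (random, or restricted to border spots), retrains the
#' model on the remaining spots, imputes the masked locations blind,
#' and reports the R2 between imputed and held-out normalized
#' expression (pooled over spots and genes) together with a global-mean
#' baseline R2.
#'
#' @param ds a `spatial_dataset`.
#' @param cfg a [nichegp_config()] used for the retrain.
#' @param n_masked number of masked spots (10/20/40/80 in the standard
#'   design); 0 is skipped with a notice.
#' @param strategy `"stochastic"` or `"border"`.
#' @param seed RNG seed (mask sampling and training).
#' @return list with `r2`, `baseline_r2` (global-mean imputation),
#'   `masked` indices and the strategy.
#' @export
masking_eval <- function(ds, cfg = nichegp_config(), n_masked = 20,
                         strategy = c("stochastic", "border"), seed = 1) {
  strategy <- match.arg(strategy)
  if (n_masked == 0) {
    message("n_masked = 0: nothing to evaluate, skipping")
    return(list(r2 = NA_real_, baseline_r2 = NA_real_, masked = integer(0),
                strategy = strategy))
  }
  n <- n_spots(ds)
  if (n_masked >= n) stop("cannot mask every spot")
  if (is.null(ds$normalized)) ds <- normalize_counts(ds)
  set.seed(seed)
  pool <- if (strategy == "border") which(is_border_spot(ds)) else seq_len(n)
  if (length(pool) < n_masked)
    stop(sprintf("only %d spots satisfy the %s predicate", length(pool), strategy))
  masked <- sort(sample(pool, n_masked))
  keep <- setdiff(seq_len(n), masked)
  cfg$seed <- seed
  model <- train_nichegp(subset_spots(ds, keep), cfg)
  pred <- impute_blind(model, ds$coords[masked, , drop = FALSE], seed = seed)
  truth <- ds$normalized[masked, , drop = FALSE]
  imputed <- predicted_nex(pred)
  r2 <- score_r2(as.numeric(imputed), as.numeric(truth))
  gm <- colMeans(ds$normalized[keep, , drop = FALSE])
  base <- matrix(gm, n_masked, length(gm), byrow = TRUE)
  baseline_r2 <- score_r2(as.numeric(base), as.numeric(truth))
  list(r2 = r2, baseline_r2 = baseline_r2, masked = masked,
       strategy = strategy)
}

#' Predictive-interval coverage on held-out spots
#'
#' Imputes held-out spots blind, builds nominal-level NB predictive
#' intervals from `g` posterior draws (size factors taken from the
#' held-out libraries relative to the training median library), and
#' reports the fraction of held-out raw counts inside their interval.
#'
#' @param model a trained `nichegp_model`.
#' @param holdout a `spatial_dataset` of held-out spots (same genes).
#' @param level nominal level, default 0.95.
#' @param g posterior draws, default 20.
#' @param seed RNG seed for the draws.
#' @return list with `coverage` (fraction in \[0,1\]), `n` evaluated
#'   entries, and the prediction object.
#' @export
coverage_eval <- function(model, holdout, level = 0.95, g = 20, seed = 1) {
  if (n_genes(holdout) != n_genes(model$ds))
    stop("holdout genes do not match the trained model")
  med_lib <- stats::median(library_sizes(model$ds))
  sf_hold <- library_sizes(holdout) / med_lib
  pred <- ngp_infer(model, new_coords = holdout$coords, new_labels = NULL,
                    g = g, seed = seed, intervals = TRUE, level = level,
                    sf_out = sf_hold,
                    provenance = list(mode = "coverage_eval"))
  x <- holdout$counts
  inside <- x >= pred$lower & x <= pred$upper
  list(coverage = mean(inside), n = length(inside), prediction = pred)
}
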