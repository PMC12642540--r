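#' Simulation configuration
#'
#' Study conditions for the synthetic generator. The generative process
#' mirrors the model family: two spatially correlated latent fields with
#' anisotropic Cauchy covariance plus iid Gaussian latents drive per-gene
#' log-means through random loadings; niche labels add niche-specific
#' offsets; perturbation effects enter as additive log-fold changes
#' weighted by a Cauchy-shaped spatial decay centred on perturbed
#' patches; counts are negative binomial with log-normal library sizes.
#'
#' @param n_spots spots per slide (square or hex lattice), default 500.
#' @param n_genes genes, default 200.
#' @param lattice `"square"` or `"hex"`.
#' @param n_slides number of slides (slides get independent latent
#'   fields and optional batch offsets), default 1.
#' @param D spatial dimensionality (2, or 3 for serial-section stacks).
#' @param perturbations named list, one entry per non-control state:
#'   `list(n_affected, lfc, decay_scale, patch_center, patch_radius)`.
#'   `lfc` is the log-fold-change magnitude (signs drawn at random);
#'   `patch_center` in rescaled coordinates (defaults to the domain
#'   centre) and `patch_radius` (default 2.5) define the perturbed patch.
#' @param gp_scale true Cauchy kernel scale per axis (recycled), default 10.
#' @param gp_dim,gaussian_dim latent dimensionalities (2 and 8).
#' @param gp_loading_sd,gaussian_loading_sd sd of the random per-gene
#'   loadings of the spatial and iid latent factors (defaults 0.3 and
#'   0.1); larger spatial loadings give smoother, stronger spatial
#'   expression fields.
#' @param niche_layout `"rings"` (core / periphery / normal discs) or
#'   `"halves"` (two lateral niches).
#' @param ring_radii fractions of `range_max` bounding the core and the
#'   periphery ring (rings layout); a thin periphery (e.g.
#'   `c(0.25, 0.3)`) creates three-type junctions and hence border
#'   spots under the 6-neighbor dominance predicate.
#' @param niche_effect magnitude of per-niche log-mean offsets, default 0.5.
#' @param niche_raggedness probability that a spot adopts the niche
#'   label of a random lattice neighbour (applied once), emulating the
#'   ragged annotation boundaries of real tissue; ragged interfaces are
#'   what create border spots under the 6-neighbor dominance predicate.
#'   Default 0 (clean boundaries).
#' @param library_meanlog,library_sdlog log-normal library-size
#'   parameters (defaults log(2000) and 0.3).
#' @param nb_dispersion NB dispersion theta, default 2.
#' @param batch_effect sd of per-slide gene offsets, default 0.
#' @param time_points optional numeric vector assigning one time value
#'   per slide (a continuous covariate named "day").
#' @param time_effect per-unit-time log-fold slope applied to 10% of
#'   genes (declining markers), default 0.
#' @param z_spacing section distances used as the z axis when `D = 3`
#'   (defaults to the serial-section design 0.4, 0.8, 2.0, 3.2).
#' @param range_max spatial domain size after rescaling, default 20.
#' @param seed mandatory RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_spots = 500, n_genes = 200,
                       lattice = c("square", "hex"),
                       n_slides = 1, D = 2,
                       perturbations = list(KO = list(n_affected = 20, lfc = 1,
                                                      decay_scale = 4,
                                                      patch_center = NULL,
                                                      patch_radius = 2.5)),
                       gp_scale = 10, gp_dim = 2, gaussian_dim = 8,
                       gp_loading_sd = 0.3, gaussian_loading_sd = 0.1,
                       niche_layout = c("rings", "halves"),
                       ring_radii = c(0.25, 0.4),
                       niche_effect = 0.5, niche_raggedness = 0,
                       library_meanlog = log(2000), library_sdlog = 0.3,
                       nb_dispersion = 2, batch_effect = 0,
                       time_points = NULL, time_effect = 0,
                       z_spacing = c(0.4, 0.8, 2.0, 3.2),
                       range_max = 20, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_spots > 0, n_genes > 0, n_slides > 0, D %in% c(2, 3),
            nb_dispersion > 0)
  structure(list(n_spots = n_spots, n_genes = n_genes,
                 lattice = match.arg(lattice), n_slides = n_slides, D = D,
                 perturbations = perturbations, gp_scale = gp_scale,
                 gp_dim = gp_dim, gaussian_dim = gaussian_dim,
                 gp_loading_sd = gp_loading_sd,
                 gaussian_loading_sd = gaussian_loading_sd,
                 niche_layout = match.arg(niche_layout),
                 ring_radii = ring_radii,
                 niche_effect = niche_effect,
                 niche_raggedness = niche_raggedness,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 nb_dispersion = nb_dispersion, batch_effect = batch_effect,
                 time_points = time_points, time_effect = time_effect,
                 z_spacing = z_spacing, range_max = range_max, seed = seed),
            class = "sim_config")
}

lattice_coords <- function(n, lattice, range_max) {
  side <- ceiling(sqrt(n))
  if (lattice == "square") {
    g <- expand.grid(x = seq_len(side), y = seq_len(ceiling(n / side)))
  } else {
    rows <- ceiling(n / side)
    g <- expand.grid(col = seq_len(side), row = seq_len(rows))
    g <- data.frame(x = g$col + 0.5 * (g$row %% 2), y = g$row * sqrt(3) / 2)
  }
  g <- as.matrix(g[seq_len(n), c(1, 2)])
  colnames(g) <- c("x", "y")
  ## isotropic rescale into [0, range_max] so lattice geometry is kept
  ext <- apply(g, 2, function(v) diff(range(v)))
  sc <- range_max / max(ext)
  sweep(g, 2, apply(g, 2, min), "-") * sc
}

niche_labels <- function(coords, layout, range_max, ring_radii = c(0.25, 0.4)) {
  ctr <- rep(range_max / 2, 2)
  if (layout == "rings") {
    r <- sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2)
    factor(ifelse(r < ring_radii[1] * range_max, "core",
                  ifelse(r < ring_radii[2] * range_max, "periphery", "normal")),
           levels = c("core", "periphery", "normal"))
  } else {
    factor(ifelse(coords[, 1] < range_max / 2, "nicheA", "nicheB"),
           levels = c("nicheA", "nicheB"))
  }
}

#' Simulate a spatial perturbation dataset with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a [spatial_dataset()], raw counts and
#'   labels) and `truth`: noiseless NB means (`mean`), log-means
#'   (`log_mean`), GP fields, Gaussian latents, per-perturbation effect
#'   vectors (`effects`, log-fold change per gene at full weight) and
#'   spatial decay weights (`decay`, spots x perturbations), size
#'   factors, niche labels, and the generating config.
#' @export
simulate_spatial <- function(cfg) {
  set.seed(cfg$seed)
  P <- names(cfg$perturbations)
  n <- cfg$n_spots; G <- cfg$n_genes
  gp_scale <- rep(cfg$gp_scale, length.out = cfg$D)

  coords_l <- list(); slide_l <- list(); niche_l <- list()
  gp_fields_l <- list(); zg_l <- list()
  for (sl in seq_len(cfg$n_slides)) {
    xy <- lattice_coords(n, cfg$lattice, cfg$range_max)
    co <- if (cfg$D == 3) {
      z <- cfg$z_spacing[((sl - 1) %% length(cfg$z_spacing)) + 1]
      cbind(xy, z = rep(z, n))
    } else xy
    coords_l[[sl]] <- co
    ## serial sections of a 3D stack form one volume (one slide): the
    ## kernel must couple sections through z, never be blocked by a
    ## per-section batch indicator
    slide_l[[sl]] <- rep(if (cfg$D == 3) "slide1" else paste0("slide", sl), n)
    nl <- niche_labels(xy, cfg$niche_layout, cfg$range_max, cfg$ring_radii)
    if (cfg$niche_raggedness > 0) {
      d <- as.matrix(stats::dist(xy)); diag(d) <- Inf
      spacing <- stats::median(apply(d, 1, min))
      flip <- which(stats::runif(n) < cfg$niche_raggedness)
      for (i in flip) {
        nb <- which(d[i, ] <= 1.6 * spacing)
        if (length(nb) > 0) nl[i] <- nl[nb[sample.int(length(nb), 1)]]
      }
    }
    niche_l[[sl]] <- nl
  }
  coords <- do.call(rbind, coords_l)
  slide <- factor(unlist(slide_l))
  niche <- factor(unlist(lapply(niche_l, as.character)),
                  levels = levels(niche_l[[1]]))
  N <- nrow(coords)

  ## latent fields: per 3D stack the field spans sections jointly so
  ## effects and covariance decay in z; per 2D slide fields independent
  draw_field <- function(co) {
    K <- kernel_matrix(co, co, kernel_params(gp_scale)) + diag(1e-6, nrow(co))
    t(MASS::mvrnorm(cfg$gp_dim, mu = rep(0, nrow(co)), Sigma = K))
  }
  if (cfg$D == 3) {
    gp_fields <- draw_field(coords)
  } else {
    gp_fields <- do.call(rbind, lapply(coords_l, draw_field))
  }
  z_gauss <- matrix(stats::rnorm(N * cfg$gaussian_dim), N, cfg$gaussian_dim)

  ## gene model
  rel <- stats::rgamma(G, shape = 2)
  rel <- rel / sum(rel)
  base <- log(rel * exp(cfg$library_meanlog))
  L_gp <- matrix(stats::rnorm(cfg$gp_dim * G, sd = cfg$gp_loading_sd),
                 cfg$gp_dim, G)
  L_g <- matrix(stats::rnorm(cfg$gaussian_dim * G, sd = cfg$gaussian_loading_sd),
                cfg$gaussian_dim, G)
  log_mean <- sweep(gp_fields %*% L_gp + z_gauss %*% L_g, 2, base, "+")

  niche_off <- matrix(0, nlevels(niche), G,
                      dimnames = list(levels(niche), NULL))
  for (nl in levels(niche)) {
    sel <- sample.int(G, max(1, round(0.15 * G)))
    niche_off[nl, sel] <- stats::rnorm(length(sel), sd = cfg$niche_effect)
  }
  log_mean <- log_mean + niche_off[as.integer(niche), , drop = FALSE]

  if (cfg$batch_effect > 0 && cfg$n_slides > 1) {
    b_off <- matrix(stats::rnorm(cfg$n_slides * G, sd = cfg$batch_effect),
                    cfg$n_slides, G)
    log_mean <- log_mean + b_off[as.integer(slide), , drop = FALSE]
  }

  continuous <- NULL
  if (!is.null(cfg$time_points)) {
    day <- cfg$time_points[as.integer(slide)]
    continuous <- list(day = day)
    if (cfg$time_effect != 0) {
      tg <- sample.int(G, max(1, round(0.1 * G)))
      slope <- rep(0, G); slope[tg] <- -abs(cfg$time_effect)
      log_mean <- log_mean + outer(day, slope)
      attr(continuous, "marker_genes") <- tg
    }
  }

  ## perturbation patches and spatially decaying effects
  pert <- factor(rep("control", N), levels = c("control", P))
  effects <- list(); decay <- matrix(0, N, length(P),
                                     dimnames = list(NULL, P))
  for (pi in seq_along(P)) {
    spec <- cfg$perturbations[[pi]]
    ctr <- spec$patch_center
    ## default placement straddles niche boundaries: a patch nested
    ## inside a single niche label would make perturbation and niche
    ## unidentifiable (the labels would be perfectly confounded)
    if (is.null(ctr)) ctr <- rep(0.75 * cfg$range_max, 2)
    rad <- if (is.null(spec$patch_radius)) 2.5 else spec$patch_radius
    dsc <- if (is.null(spec$decay_scale)) 4 else spec$decay_scale
    in_patch <- rep(FALSE, N)
    if (cfg$D == 3) {
      ## the perturbed patch lives in the first section of the stack
      ii <- which(coords[, 3] == min(coords[, 3]))
    } else {
      ii <- which(slide == levels(slide)[1])
    }
    d2 <- (coords[ii, 1] - ctr[1])^2 + (coords[ii, 2] - ctr[2])^2
    in_patch[ii[d2 <= rad^2]] <- TRUE
    pert[in_patch] <- P[pi]
    lfc <- rep(0, G)
    if (spec$n_affected > 0 && spec$lfc != 0) {
      sel <- sample.int(G, spec$n_affected)
      lfc[sel] <- spec$lfc * sample(c(-1, 1), spec$n_affected, replace = TRUE)
    }
    effects[[P[pi]]] <- lfc
    ## Cauchy-shaped weight from the nearest patch spot, full weight on
    ## the patch itself; zero on slides without the patch (2D multislide)
    w <- rep(0, N)
    src <- which(in_patch)
    if (length(src) > 0) {
      for (sl in unique(slide[src])) {
        ii <- which(slide == sl | cfg$D == 3)
        d2min <- apply(coords[ii, , drop = FALSE], 1, function(s) {
          min(colSums((t(coords[src, , drop = FALSE]) - s)^2))
        })
        w[ii] <- 1 / (1 + d2min / dsc)
      }
    }
    decay[, pi] <- w
    log_mean <- log_mean + outer(w, lfc)
  }

  lib <- stats::rlnorm(N, cfg$library_meanlog, cfg$library_sdlog)
  sf <- lib / stats::median(lib)
  mean_mat <- sf * exp(log_mean)
  counts <- matrix(stats::rnbinom(N * G, size = cfg$nb_dispersion,
                                  mu = as.numeric(mean_mat)), N, G)
  colnames(counts) <- paste0("g", seq_len(G))
  rownames(counts) <- paste0("spot", seq_len(N))

  ds <- spatial_dataset(counts, coords, pert, disease = niche,
                        slide = slide, continuous = continuous)
  truth <- list(mean = mean_mat, log_mean = log_mean,
                gp_fields = gp_fields, gaussian_latent = z_gauss,
                effects = effects, decay = decay, size_factors = sf,
                niche = niche, config = cfg,
                marker_genes = attr(continuous, "marker_genes"))
  list(dataset = ds, truth = truth)
}

#' Write a canonical small fixture to disk
#'
#' Fixtures are CSV triplets plus a `ground_truth.json` sidecar, small
#' enough for test suites and examples:
#' \describe{
#'   \item{tiny}{50 spots, 40 genes, 2 perturbation states + control.}
#'   \item{two_niche}{400 spots, two lateral niches, one perturbation.}
#'   \item{time_course}{3 slides at days 0/12/30 with declining markers.}
#'   \item{stack3d}{4 serial sections (z = 0.4/0.8/2.0/3.2) with the
#'     perturbation patch in section 1 and z-decaying effects.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory (created).
#' @param seed RNG seed, default 1.
#' @return the simulation list, invisibly; files written under `dir`.
#' @export
make_fixture <- function(name = c("tiny", "two_niche", "time_course", "stack3d"),
                         dir, seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(n_spots = 50, n_genes = 40,
                      perturbations = list(
                        KO1 = list(n_affected = 8, lfc = 1, decay_scale = 4,
                                   patch_center = c(5, 5), patch_radius = 4),
                        KO2 = list(n_affected = 8, lfc = 1, decay_scale = 4,
                                   patch_center = c(15, 15), patch_radius = 4)),
                      seed = seed),
    two_niche = sim_config(n_spots = 400, n_genes = 100,
                           niche_layout = "halves", niche_effect = 1,
                           perturbations = list(
                             KO = list(n_affected = 15, lfc = 1, decay_scale = 4,
                                       patch_center = c(5, 10), patch_radius = 3)),
                           seed = seed),
    time_course = sim_config(n_spots = 150, n_genes = 60, n_slides = 3,
                             time_points = c(0, 12, 30), time_effect = 0.05,
                             batch_effect = 0.1,
                             perturbations = list(
                               DSS = list(n_affected = 10, lfc = 1,
                                          decay_scale = 4,
                                          patch_center = c(10, 10),
                                          patch_radius = 20)),
                             seed = seed),
    stack3d = sim_config(n_spots = 150, n_genes = 60, n_slides = 4, D = 3,
                         perturbations = list(
                           PT = list(n_affected = 10, lfc = 1.5,
                                     decay_scale = 4,
                                     patch_center = c(10, 10),
                                     patch_radius = 3)),
                         seed = seed))
  sim <- simulate_spatial(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_dataset(sim$dataset, dir, format = "csv_triplet")
  gt <- sim$truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
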