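## Shared inference engine. Every prediction mode funnels through
## ngp_infer: embeddings (optionally edited) for all observed spots form
## the GP pseudo-observations; predictions are returned either at
## observed spots or at new coordinates (imputation). Edits never mutate
## the model.

nearest_neighbors <- function(coords, query, k, same_slide = NULL,
                              query_slide = NULL) {
  t(vapply(seq_len(nrow(query)), function(i) {
    cand <- seq_len(nrow(coords))
    if (!is.null(same_slide)) cand <- cand[same_slide == query_slide[i]]
    if (length(cand) == 0) stop("no observed spot on the query's slide")
    d <- sqrt(colSums((t(coords[cand, , drop = FALSE]) - query[i, ])^2))
    ## ties broken by spot index (order is stable on the index)
    cand[order(d, cand)[seq_len(min(k, length(cand)))]]
  }, integer(min(k, nrow(coords)))))
}

model_signature <- function(model) {
  sprintf("%.8e", sum(model$params$raw_scales^2) +
            sum(model$params$enc[[1]]$W[1, ]^2) + sum(model$basal[1, ]^2))
}

ngp_infer <- function(model, labels = NULL,
                      new_coords = NULL, new_labels = NULL,
                      predict_idx = NULL, k_neighbors = 6,
                      g = model$cfg$g_infer, seed = 1,
                      intervals = FALSE, level = 0.95, sf_out = NULL,
                      n_rep = 25, provenance = NULL) {
  cfg <- model$cfg
  ds <- model$ds
  N <- n_spots(ds)
  if (is.null(labels)) {
    labels <- list(perturbation = ds$perturbation,
                   disease = ds$disease, slide = ds$slide,
                   continuous = ds$continuous)
  }
  emb_all <- ngp_embeddings(model, seq_len(N), labels = labels)
  enc_all <- encode(model, emb_all$e)
  pert_vocab <- model$cb$vocab$perturbation
  obs_label_int <- match(as.character(labels$perturbation), pert_vocab)
  obs_slide_int <- slide_ints(ds)

  if (is.null(new_coords)) {
    if (is.null(predict_idx)) predict_idx <- seq_len(N)
    test_coords <- ds$coords[predict_idx, , drop = FALSE]
    test_label_int <- obs_label_int[predict_idx]
    test_slide_int <- if (!is.null(obs_slide_int)) obs_slide_int[predict_idx]
    muG <- enc_all$mu[predict_idx, enc_all$gauss_cols, drop = FALSE]
    varG <- enc_all$var[predict_idx, enc_all$gauss_cols, drop = FALSE]
    slide_dec <- if (!is.null(model$params$disp_off)) as.integer(ds$slide[predict_idx])
    out_ids <- ds$spot_ids[predict_idx]
  } else {
    new_coords <- as.matrix(new_coords)
    if (ncol(new_coords) != ncol(ds$coords))
      stop(sprintf("new coordinates are %dD but the model was trained on %dD",
                   ncol(new_coords), ncol(ds$coords)))
    M <- nrow(new_coords)
    q_slide <- if (!is.null(new_labels$slide)) {
      match(as.character(new_labels$slide), levels(ds$slide))
    } else NULL
    nn <- nearest_neighbors(ds$coords, new_coords, k_neighbors,
                            same_slide = if (!is.null(obs_slide_int) && !is.null(q_slide)) obs_slide_int,
                            query_slide = q_slide)
    nn1 <- nn[, 1]
    test_coords <- new_coords
    test_slide_int <- if (!is.null(obs_slide_int)) {
      if (!is.null(q_slide)) q_slide else obs_slide_int[nn1]
    }
    slide_fac <- if (!is.null(new_labels$slide)) factor(as.character(new_labels$slide), levels(ds$slide))
                 else ds$slide[nn1]
    if (!is.null(new_labels) && !is.null(new_labels$perturbation)) {
      ## attributes known: neighbor-averaged basal + codebook blocks
      basal_rows <- t(vapply(seq_len(M), function(i) {
        colMeans(model$basal[nn[i, ], , drop = FALSE])
      }, numeric(ncol(model$basal))))
      cb <- model_codebooks(model)
      embu <- embed_spots(cb, rep(NA_integer_, M),
                          perturbation = new_labels$perturbation,
                          disease = if (!is.null(new_labels$disease)) new_labels$disease
                                    else ds$disease[nn1],
                          slide = slide_fac,
                          continuous = new_labels$continuous,
                          basal_override = basal_rows)
      encu <- encode(model, embu$e)
      muG <- encu$mu[, enc_all$gauss_cols, drop = FALSE]
      varG <- encu$var[, enc_all$gauss_cols, drop = FALSE]
      test_label_int <- match(as.character(new_labels$perturbation), pert_vocab)
      if (anyNA(test_label_int))
        stop("unknown perturbation label in the edit specification")
    } else {
      ## blind imputation: Gaussian latents averaged over neighbors,
      ## kernel label copied from the nearest observed spot
      muG <- t(vapply(seq_len(M), function(i) {
        colMeans(enc_all$mu[nn[i, ], enc_all$gauss_cols, drop = FALSE])
      }, numeric(cfg$gaussian_dim)))
      sdG_bar <- t(vapply(seq_len(M), function(i) {
        colMeans(sqrt(enc_all$var[nn[i, ], enc_all$gauss_cols, drop = FALSE]))
      }, numeric(cfg$gaussian_dim)))
      varG <- sdG_bar^2
      test_label_int <- obs_label_int[nn1]
    }
    slide_dec <- if (!is.null(model$params$disp_off)) as.integer(slide_fac)
    out_ids <- paste0("virtual", seq_len(M))
  }

  gp <- ngp_gp_test(model, test_coords, test_label_int, test_slide_int,
                    obs_label_int, obs_slide_int,
                    enc_all$mu[, enc_all$gp_cols, drop = FALSE],
                    enc_all$var[, enc_all$gp_cols, drop = FALSE])

  M_out <- nrow(test_coords)
  G <- n_genes(ds)
  mu_acc <- matrix(0, M_out, G)
  th_acc <- matrix(0, M_out, G)
  samples <- if (intervals) vector("list", g)
  if (is.null(sf_out)) sf_out <- rep(1, M_out)
  set.seed(seed)
  for (r in seq_len(g)) {
    eps <- matrix(stats::rnorm(M_out * (cfg$gp_dim + cfg$gaussian_dim)),
                  M_out)
    z <- cbind(gp$mean + eps[, seq_len(cfg$gp_dim), drop = FALSE] * sqrt(gp$var),
               muG + eps[, cfg$gp_dim + seq_len(cfg$gaussian_dim), drop = FALSE] * sqrt(varG))
    dec <- decode(model, z, slide_dec)
    mu_acc <- mu_acc + dec$mu / g
    th_acc <- th_acc + dec$theta / g
    if (intervals) {
      m <- sf_out * dec$mu
      samples[[r]] <- matrix(stats::rnbinom(M_out * G * n_rep,
                                            size = rep(dec$theta, n_rep),
                                            mu = rep(m, n_rep)),
                             M_out * G, n_rep)
    }
  }
  lower <- upper <- NULL
  if (intervals) {
    pool <- do.call(cbind, samples)
    a <- (1 - level) / 2
    qs <- t(apply(pool, 1, stats::quantile, probs = c(a, 1 - a), type = 1))
    lower <- matrix(qs[, 1], M_out, G)
    upper <- matrix(qs[, 2], M_out, G)
  }
  structure(list(mean = mu_acc, dispersion = th_acc,
                 lower = lower, upper = upper, level = level,
                 gp_mean = gp$mean, gp_var = gp$var,
                 spot_ids = out_ids, gene_names = ds$gene_names,
                 coords = test_coords,
                 provenance = c(provenance,
                                list(g = g, seed = seed,
                                     checkpoint = model_signature(model)))),
            class = "nichegp_prediction")
}

## sparse GP posterior at arbitrary test points given ALL observed spots
## as pseudo-observations (full-batch scale s = 1)
ngp_gp_test <- function(model, test_coords, test_label_int, test_slide_int,
                        obs_label_int, obs_slide_int, mu_gp, var_gp) {
  cfg <- model$cfg
  kp <- model_kernel_params(model)
  use_labels <- cfg$kernel_mode == "per_perturbation"
  ind <- model$inducing
  ds <- model$ds
  KPP <- kernel_matrix(ind$locations, ind$locations, kp,
                       slides_a = ind$slides, slides_b = ind$slides)
  KPS <- kernel_matrix(ind$locations, ds$coords, kp,
                       labels_b = if (use_labels) obs_label_int,
                       slides_a = ind$slides, slides_b = obs_slide_int)
  KtP <- kernel_matrix(test_coords, ind$locations, kp,
                       labels_a = if (use_labels) test_label_int,
                       slides_a = test_slide_int, slides_b = ind$slides)
  fits <- lapply(seq_len(ncol(mu_gp)), function(d) {
    svgp_forward_dim(KPP, KPS, KtP, rep(1, nrow(test_coords)),
                     w = 1 / var_gp[, d], mu = mu_gp[, d],
                     s = 1, jitter = cfg$jitter)
  })
  list(mean = do.call(cbind, lapply(fits, `[[`, "mean")),
       var = do.call(cbind, lapply(fits, `[[`, "var")))
}

#' Posterior-mean expression with predictive intervals
#'
#' Reconstructs (or predicts) expression as the average decoded NB mean
#' over `g` latent draws; optional per-spot-per-gene predictive
#' intervals are empirical quantiles of NB samples pooled across the
#' draws.
#'
#' @param model a trained `nichegp_model`.
#' @param spots integer indices of spots to predict (default all).
#' @param g number of posterior draws (default 20 at inference).
#' @param seed RNG seed for the draws.
#' @param intervals compute predictive intervals?
#' @param level nominal interval level, default 0.95.
#' @param sf size factors applied inside the NB when sampling intervals
#'   (default 1: expression at the median library).
#' @return a `nichegp_prediction` with `mean` (spots x genes, count
#'   scale at the median library), optional `lower`/`upper`, latent GP
#'   posterior summaries and provenance.
#' @export
predict_mean <- function(model, spots = NULL, g = model$cfg$g_infer,
                         seed = 1, intervals = FALSE, level = 0.95,
                         sf = NULL) {
  ngp_infer(model, predict_idx = spots, g = g, seed = seed,
            intervals = intervals, level = level, sf_out = sf,
            provenance = list(mode = "reconstruction"))
}

#' @export
print.nichegp_prediction <- function(x, ...) {
  cat(sprintf("nichegp_prediction: %d spots x %d genes (g = %d draws)\n",
              nrow(x$mean), ncol(x$mean), x$provenance$g))
  if (!is.null(x$lower))
    cat(sprintf("  predictive intervals at level %.2f\n", x$level))
  if (!is.null(x$provenance$mode))
    cat(sprintf("  mode: %s\n", x$provenance$mode))
  invisible(x)
}

#' Normalized-expression view of a prediction
#'
#' Converts the posterior-mean count-scale output (at the median
#' library) to the log-normalized expression (NEX) scale used for
#' evaluation. Observed NEX is `log1p` of a *noisy* count, whose
#' expectation sits below `log1p` of its mean (Jensen's inequality), so
#' the comparable prediction is `E[log1p(X)]` under the model's NB law
#' (mean from the prediction, dispersion from the model), estimated by
#' Monte Carlo over NB draws (fixed internal seed; the caller's RNG
#' state is untouched).
#'
#' @param pred a `nichegp_prediction`.
#' @param jensen apply the correction (default TRUE); with FALSE the
#'   plain `log1p` of the predicted mean is returned.
#' @param n_mc Monte-Carlo draws per entry.
#' @return matrix of log-scale expression values.
#' @export
predicted_nex <- function(pred, jensen = TRUE, n_mc = 128) {
  m <- pred$mean
  if (!jensen || is.null(pred$dispersion)) return(log1p(m))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(830317L)
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(n_mc)) {
    out <- out + log1p(matrix(stats::rnbinom(length(m), size = pred$dispersion,
                                             mu = m), nrow(m))) / n_mc
  }
  out
}
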