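## Training internals: minibatch forward/backward with hand-derived
## gradients, finite-difference gradients for the (few) kernel scale
## scalars under common random numbers, AdamW updates, the beta
## controller, stratified validation split and early stopping.

## Assemble inference-mode embeddings for given spot indices and add the
## provided basal noise (training) so that forward passes are exactly
## repeatable under common random numbers.
ngp_embeddings <- function(model, idx, basal_noise = NULL,
                           labels = NULL) {
  ds <- model$ds
  cb <- model_codebooks(model)
  if (is.null(labels)) {
    labels <- list(perturbation = ds$perturbation[idx],
                   disease = ds$disease[idx],
                   slide = ds$slide[idx],
                   continuous = lapply(ds$continuous, `[`, idx))
  }
  emb <- embed_spots(cb, idx,
                     perturbation = labels$perturbation,
                     disease = labels$disease,
                     slide = labels$slide,
                     continuous = labels$continuous,
                     training = FALSE)
  if (!is.null(basal_noise)) {
    bc <- emb$blocks$basal
    emb$e[, bc] <- emb$e[, bc] + basal_noise
  }
  emb
}

## GP forward over a set of pseudo-observation spots (= test spots here)
ngp_gp_forward <- function(model, coords, labels_int, slides_int,
                           mu_gp, var_gp, s, raw_scales) {
  kp <- model_kernel_params(model, raw_scales)
  use_labels <- if (model$cfg$kernel_mode == "per_perturbation") labels_int else NULL
  ind <- model$inducing
  KPP <- kernel_matrix(ind$locations, ind$locations, kp,
                       slides_a = ind$slides, slides_b = ind$slides)
  KPS <- kernel_matrix(ind$locations, coords, kp,
                       labels_b = use_labels,
                       slides_a = ind$slides, slides_b = slides_int)
  fits <- lapply(seq_len(ncol(mu_gp)), function(d) {
    svgp_forward_dim(KPP, KPS, t(KPS), rep(1, nrow(coords)),
                     w = 1 / var_gp[, d], mu = mu_gp[, d],
                     s = s, jitter = model$cfg$jitter)
  })
  list(mean = do.call(cbind, lapply(fits, `[[`, "mean")),
       var = do.call(cbind, lapply(fits, `[[`, "var")),
       caches = lapply(fits, `[[`, "cache"))
}

## Full minibatch forward. `rand` carries the basal noise and the
## reparameterization draws so finite-difference re-evaluations see the
## same randomness. If `enc_out` is supplied the embedding/encoder stage
## is reused (kernel scales do not enter it).
ngp_batch_forward <- function(model, idx, rand,
                              raw_scales = model$params$raw_scales,
                              n_total, enc_out = NULL) {
  cfg <- model$cfg
  ds <- model$ds
  B <- length(idx)
  if (is.null(enc_out)) {
    emb <- ngp_embeddings(model, idx, basal_noise = rand$basal_noise)
    enc <- encode(model, emb$e)
    enc_out <- list(emb = emb, enc = enc)
  }
  enc <- enc_out$enc
  mu_gp <- enc$mu[, enc$gp_cols, drop = FALSE]
  var_gp <- enc$var[, enc$gp_cols, drop = FALSE]
  gp <- ngp_gp_forward(model, ds$coords[idx, , drop = FALSE],
                       label_ints(ds)[idx], slide_ints(ds)[idx],
                       mu_gp, var_gp, s = n_total / B, raw_scales)
  eps <- rand$eps
  sd_gp <- sqrt(gp$var)
  z_gp <- gp$mean + eps[, enc$gp_cols, drop = FALSE] * sd_gp
  muG <- enc$mu[, enc$gauss_cols, drop = FALSE]
  sdG <- sqrt(enc$var[, enc$gauss_cols, drop = FALSE])
  z_g <- muG + eps[, enc$gauss_cols, drop = FALSE] * sdG
  z <- cbind(z_gp, z_g)
  slide_idx <- if (!is.null(model$params$disp_off)) as.integer(ds$slide[idx]) else NULL
  dec <- decode(model, z, slide_idx)
  x <- ds$counts[idx, , drop = FALSE]
  sfb <- model$sf[idx]
  recon <- nb_loss(x, dec$mu, dec$theta, sfb)
  kl <- compute_kl(enc, gp$caches, n_total)
  basal_pen <- cfg$lambda_l2 * mean(rowSums(model$basal[idx, , drop = FALSE]^2))
  loss <- recon + model$beta * (kl$kl_gp + kl$kl_gauss) + basal_pen
  if (!is.finite(loss)) stop("non-finite training loss (diverged); lower the learning rate")
  list(loss = loss, recon = recon, kl = kl, basal_pen = basal_pen,
       enc_out = enc_out, gp = gp, z = z, dec = dec,
       sd_gp = sd_gp, sdG = sdG, x = x, sfb = sfb,
       slide_idx = slide_idx, idx = idx, B = B, n_total = n_total,
       rand = rand)
}

ngp_batch_backward <- function(model, fw) {
  cfg <- model$cfg
  p <- model$params
  enc <- fw$enc_out$enc
  emb <- fw$enc_out$emb
  B <- fw$B; beta <- model$beta
  dec <- fw$dec

  ## --- reconstruction loss -> decoder ---
  ng <- nb_loss_grad(fw$x, dec$mu, dec$theta, fw$sfb)
  ghmu <- (ng$gmu / B) * dec$mu * (abs(dec$hmu) < 30)
  sp <- softplus(dec$hth)
  gsp <- (ng$gth / B) * dec$theta * (sp < 30 & dec$theta < 1e6)
  ghth <- gsp * dsoftplus(dec$hth)
  H <- dec$cache$out
  g_dec_mu <- list(W = t(H) %*% ghmu, b = colSums(ghmu))
  g_dec_th <- list(W = t(H) %*% ghth, b = colSums(ghth))
  gH <- ghmu %*% t(p$dec_mu$W) + ghth %*% t(p$dec_th$W)
  bw_dec <- mlp_backward(p$dec, dec$cache, gH)
  gz <- bw_dec$gin
  g_disp <- NULL
  if (!is.null(p$disp_off)) {
    g_disp <- p$disp_off * 0
    agg <- rowsum(ghth, group = fw$slide_idx)
    g_disp[as.integer(rownames(agg)), ] <- agg
  }

  ## --- latent split ---
  gz_gp <- gz[, enc$gp_cols, drop = FALSE]
  gz_g <- gz[, enc$gauss_cols, drop = FALSE]
  eps <- fw$rand$eps
  gmu_q <- matrix(0, B, ncol(enc$mu))
  gvar_q <- matrix(0, B, ncol(enc$mu))

  ## GP dims: through the SVGP solve (mean and variance paths) + KL
  for (j in seq_along(enc$gp_cols)) {
    d <- enc$gp_cols[j]
    cache <- fw$gp$caches[[j]]
    gmean <- gz_gp[, j]
    gvar_post <- gz_gp[, j] * eps[, d] / (2 * fw$sd_gp[, j])
    bw <- svgp_backward_dim(cache, gmean, gvar_post)
    klb <- svgp_kl_backward_dim(cache)
    gmu_d <- bw$gmu + (beta / fw$n_total) * klb$gmu
    gw_d <- bw$gw + (beta / fw$n_total) * klb$gw
    gmu_q[, d] <- gmu_d
    gvar_q[, d] <- -(cache$w^2) * gw_d   # w = 1/sigma^2
  }

  ## Gaussian dims: reparameterized sample + closed-form KL
  muG <- enc$mu[, enc$gauss_cols, drop = FALSE]
  varG <- enc$var[, enc$gauss_cols, drop = FALSE]
  gmu_q[, enc$gauss_cols] <- gz_g + beta * muG / B
  gvar_q[, enc$gauss_cols] <- gz_g * eps[, enc$gauss_cols, drop = FALSE] / (2 * fw$sdG) +
    beta * 0.5 * (1 - 1 / varG) / B

  ## --- encoder heads and trunk ---
  gvraw <- gvar_q * dsoftplus(enc$vraw)
  Henc <- enc$cache$out
  g_enc_mu <- list(W = t(Henc) %*% gmu_q, b = colSums(gmu_q))
  g_enc_var <- list(W = t(Henc) %*% gvraw, b = colSums(gvraw))
  gHenc <- gmu_q %*% t(p$enc_mu$W) + gvraw %*% t(p$enc_var$W)
  bw_enc <- mlp_backward(p$enc, enc$cache, gHenc)
  ge <- bw_enc$gin

  ## --- scatter embedding gradient into codebooks ---
  ds <- model$ds
  idx <- fw$idx
  blocks <- emb$blocks
  g_basal_rows <- ge[, blocks$basal, drop = FALSE] +
    (2 * cfg$lambda_l2 / B) * model$basal[idx, , drop = FALSE]
  scatter_cb <- function(tbl, labels_int, gcols) {
    g <- tbl * 0
    agg <- rowsum(ge[, gcols, drop = FALSE], group = labels_int)
    g[as.integer(rownames(agg)), ] <- agg
    g
  }
  grads <- list(
    enc = bw_enc$grads, enc_mu = g_enc_mu, enc_var = g_enc_var,
    dec = bw_dec$grads, dec_mu = g_dec_mu, dec_th = g_dec_th,
    pert_cb = scatter_cb(p$pert_cb, as.integer(ds$perturbation[idx]),
                         blocks$perturbation),
    raw_scales = p$raw_scales * 0
  )
  if (!is.null(p$disease_cb))
    grads$disease_cb <- scatter_cb(p$disease_cb, as.integer(ds$disease[idx]),
                                   blocks$disease)
  if (!is.null(p$slide_cb))
    grads$slide_cb <- scatter_cb(p$slide_cb, as.integer(ds$slide[idx]),
                                 blocks$slide)
  if (!is.null(p$cont)) {
    grads$cont <- list()
    for (nm in names(p$cont)) {
      proj <- model$cb$continuous[[nm]]
      pr <- p$cont[[nm]]
      v <- (ds$continuous[[nm]][idx] - proj$center) / proj$scale
      Hc <- tanh(outer(v, pr$W1[1, ]) +
                   matrix(pr$b1, B, length(pr$b1), byrow = TRUE))
      gE <- ge[, blocks[[paste0("cont:", nm)]], drop = FALSE]
      gpre <- (gE %*% t(pr$W2)) * (1 - Hc^2)
      grads$cont[[nm]] <- list(W1 = matrix(colSums(gpre * v), 1),
                               b1 = colSums(gpre),
                               W2 = t(Hc) %*% gE,
                               b2 = colSums(gE))
    }
  }
  if (!is.null(p$disp_off)) grads$disp_off <- g_disp
  list(grads = grads, g_basal_rows = g_basal_rows)
}

## central finite differences for the kernel scale scalars, reusing the
## cached encoder outputs and the step's random draws
ngp_scale_fd <- function(model, fw, h = 1e-3) {
  rs <- model$params$raw_scales
  g <- rs * 0
  for (i in seq_along(rs)) {
    up <- rs; up[i] <- up[i] + h
    dn <- rs; dn[i] <- dn[i] - h
    lu <- ngp_batch_forward(model, fw$idx, fw$rand, raw_scales = up,
                            n_total = fw$n_total, enc_out = fw$enc_out)$loss
    ld <- ngp_batch_forward(model, fw$idx, fw$rand, raw_scales = dn,
                            n_total = fw$n_total, enc_out = fw$enc_out)$loss
    g[i] <- (lu - ld) / (2 * h)
  }
  g
}

## One optimization step on a minibatch; mutates and returns the model.
elbo_step <- function(model, idx, n_total, opt, lr = model$cfg$lr) {
  cfg <- model$cfg
  B <- length(idx)
  latent <- cfg$gp_dim + cfg$gaussian_dim
  rand <- list(
    basal_noise = matrix(stats::rnorm(B * ncol(model$basal),
                                      sd = cfg$noise_sigma), B),
    eps = matrix(stats::rnorm(B * latent), B, latent)
  )
  fw <- ngp_batch_forward(model, idx, rand, n_total = n_total)
  bw <- ngp_batch_backward(model, fw)
  ## kernel scales move slowly; their finite-difference gradient is the
  ## costly part of a step, so refresh it every few steps
  opt$fd_tick <- (opt$fd_tick %||% 0) + 1
  if (opt$fd_tick %% 5 == 1 || is.null(opt$fd_cache)) {
    opt$fd_cache <- ngp_scale_fd(model, fw)
  }
  bw$grads$raw_scales <- opt$fd_cache

  st <- adamw_step(model$params, bw$grads, opt$state,
                   lr = lr, weight_decay = cfg$weight_decay)
  model$params <- st$params
  opt$state <- st$state

  ## basal rows: latent optimization updates only the spots in the batch
  opt$basal_t[idx] <- opt$basal_t[idx] + 1
  b1 <- 0.9; b2 <- 0.999
  gb <- bw$g_basal_rows
  opt$basal_m[idx, ] <- b1 * opt$basal_m[idx, , drop = FALSE] + (1 - b1) * gb
  opt$basal_v[idx, ] <- b2 * opt$basal_v[idx, , drop = FALSE] + (1 - b2) * gb^2
  t_i <- opt$basal_t[idx]
  mhat <- opt$basal_m[idx, , drop = FALSE] / (1 - b1^t_i)
  vhat <- opt$basal_v[idx, , drop = FALSE] / (1 - b2^t_i)
  model$basal[idx, ] <- model$basal[idx, , drop = FALSE] -
    (lr * cfg$basal_lr_mult) * (mhat / (sqrt(vhat) + 1e-8) +
            cfg$weight_decay * model$basal[idx, , drop = FALSE])

  list(model = model, opt = opt,
       terms = list(loss = fw$loss, recon = fw$recon,
                    kl_gp = fw$kl$kl_gp, kl_gauss = fw$kl$kl_gauss,
                    basal_pen = fw$basal_pen, beta = model$beta))
}

## deterministic penalized-ELBO on the validation split. Validation
## spots' basal codes are never optimized, so they are imputed the way
## unseen spots are at prediction time: the mean basal of the k nearest
## training spots on the same slide.
ngp_val_loss <- function(model, train_idx, val_idx, k = 6) {
  cfg <- model$cfg
  ds <- model$ds
  emb_tr <- ngp_embeddings(model, train_idx)
  enc_tr <- encode(model, emb_tr$e)
  tr_slides <- if (nlevels(ds$slide) > 1) as.integer(ds$slide[train_idx])
  nn <- nearest_neighbors(ds$coords[train_idx, , drop = FALSE],
                          ds$coords[val_idx, , drop = FALSE], k,
                          same_slide = tr_slides,
                          query_slide = if (!is.null(tr_slides)) as.integer(ds$slide[val_idx]))
  basal_val <- t(vapply(seq_along(val_idx), function(i) {
    colMeans(model$basal[train_idx[nn[i, ]], , drop = FALSE])
  }, numeric(ncol(model$basal))))
  cb <- model_codebooks(model)
  emb_v <- embed_spots(cb, rep(NA_integer_, length(val_idx)),
                       perturbation = ds$perturbation[val_idx],
                       disease = ds$disease[val_idx],
                       slide = ds$slide[val_idx],
                       continuous = lapply(ds$continuous, `[`, val_idx),
                       basal_override = basal_val)
  enc_v <- encode(model, emb_v$e)
  kp <- model_kernel_params(model)
  use_labels <- cfg$kernel_mode == "per_perturbation"
  ind <- model$inducing
  KPP <- kernel_matrix(ind$locations, ind$locations, kp,
                       slides_a = ind$slides, slides_b = ind$slides)
  KPS <- kernel_matrix(ind$locations, ds$coords[train_idx, , drop = FALSE], kp,
                       labels_b = if (use_labels) label_ints(ds)[train_idx],
                       slides_a = ind$slides,
                       slides_b = slide_ints(ds)[train_idx])
  KtP <- kernel_matrix(ds$coords[val_idx, , drop = FALSE], ind$locations, kp,
                       labels_a = if (use_labels) label_ints(ds)[val_idx],
                       slides_a = slide_ints(ds)[val_idx],
                       slides_b = ind$slides)
  mu_gp <- enc_tr$mu[, enc_tr$gp_cols, drop = FALSE]
  var_gp <- enc_tr$var[, enc_tr$gp_cols, drop = FALSE]
  zmean <- matrix(0, length(val_idx), cfg$gp_dim)
  for (d in seq_len(cfg$gp_dim)) {
    fit <- svgp_forward_dim(KPP, KPS, KtP, rep(1, length(val_idx)),
                            w = 1 / var_gp[, d], mu = mu_gp[, d],
                            s = 1, jitter = cfg$jitter)
    zmean[, d] <- fit$mean
  }
  z <- cbind(zmean, enc_v$mu[, enc_v$gauss_cols, drop = FALSE])
  slide_idx <- if (!is.null(model$params$disp_off)) as.integer(ds$slide[val_idx]) else NULL
  dec <- decode(model, z, slide_idx)
  ## reconstruction only: the learnable beta makes the penalized
  ## objective non-stationary, which would confound the stopping signal
  nb_loss(ds$counts[val_idx, , drop = FALSE], dec$mu, dec$theta,
          model$sf[val_idx])
}

#' Train the niche-aware GP-VAE
#'
#' Optimizes codebooks (latent optimization for the basal table),
#' encoder/decoder networks and kernel scales with AdamW on the
#' NB-reconstruction + beta-weighted KL objective plus the basal L2
#' penalty. beta is steered toward the target KL multiplicatively after
#' each epoch. Early stopping monitors the penalized objective on a
#' stratified validation split. Training is deterministic under
#' `cfg$seed`.
#'
#' @param ds a `spatial_dataset` (raw counts required; coordinates are
#'   rescaled to the model's range if they exceed it).
#' @param cfg a [nichegp_config()].
#' @param verbose print per-epoch progress every 50 epochs.
#' @return a trained `nichegp_model` with a `history` data frame.
#' @export
train_nichegp <- function(ds, cfg = nichegp_config(), verbose = FALSE) {
  if (is.null(ds$normalized)) ds <- normalize_counts(ds)
  co <- ds$coords
  if (min(co) < 0 || max(co) > cfg$range_max) {
    ds <- rescale_coordinates(ds, cfg$range_max)
  }
  n <- n_spots(ds)
  n_val <- floor(cfg$val_fraction * n)
  if (n_val < 1) stop("dataset too small for a validation split")
  set.seed(cfg$seed)
  ## stratified by perturbation so rare states stay in both splits
  val_idx <- integer(0)
  for (lv in levels(ds$perturbation)) {
    sel <- which(ds$perturbation == lv)
    take <- floor(cfg$val_fraction * length(sel))
    if (take > 0) val_idx <- c(val_idx, sample(sel, take))
  }
  if (length(val_idx) < 1) val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)

  model <- init_nichegp(ds, cfg)
  opt <- list(state = adamw_init(model$params),
              basal_m = model$basal * 0, basal_v = model$basal * 0,
              basal_t = rep(0, n))
  n_total <- length(train_idx)
  best_val <- Inf; best_snapshot <- NULL; wait <- 0; steps_done <- 0
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ## cosine learning-rate decay to a tenth of the base rate: the late
    ## low-noise phase lets small shared signals (rare perturbation
    ## states) consolidate out of the per-spot latents
    lr_now <- cfg$lr * (0.1 + 0.9 * 0.5 *
                          (1 + cos(pi * (epoch - 1) / cfg$max_epochs)))
    perm <- sample(train_idx)
    nb <- max(1, ceiling(length(perm) / cfg$batch_size))
    ep <- c(loss = 0, recon = 0, kl_gp = 0, kl_gauss = 0)
    for (b in seq_len(nb)) {
      lo <- (b - 1) * cfg$batch_size + 1
      hi <- min(b * cfg$batch_size, length(perm))
      step <- elbo_step(model, perm[lo:hi], n_total, opt, lr = lr_now)
      model <- step$model; opt <- step$opt
      steps_done <- steps_done + 1
      ep <- ep + unlist(step$terms[c("loss", "recon", "kl_gp", "kl_gauss")]) / nb
    }
    ## beta controller: steer the per-gene KL toward the target (the
    ## reconstruction term sums over genes, so the commensurate KL
    ## scale is per spot per gene)
    kl_now <- (ep[["kl_gp"]] + ep[["kl_gauss"]]) / n_genes(ds)
    model$beta <- if (kl_now > cfg$kl_target) min(model$beta * 1.05, 1e3)
                  else max(model$beta * 0.95, 1e-3)
    vl <- ngp_val_loss(model, train_idx, val_idx)
    hist[[epoch]] <- c(epoch = epoch, ep, beta = model$beta, val_loss = vl)
    if (verbose && (epoch %% 50 == 0 || epoch == 1)) {
      message(sprintf("epoch %d: loss %.2f recon %.2f kl %.4f beta %.3f val %.2f",
                      epoch, ep[["loss"]], ep[["recon"]], kl_now, model$beta, vl))
    }
    if (steps_done < cfg$min_steps) next
    if (vl < best_val - cfg$min_delta) {
      best_val <- vl
      best_snapshot <- list(params = model$params, basal = model$basal,
                            beta = model$beta, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  if (!is.null(best_snapshot)) {
    model$params <- best_snapshot$params
    model$basal <- best_snapshot$basal
    model$beta <- best_snapshot$beta
  }
  model$history <- as.data.frame(do.call(rbind, hist))
  model$train_idx <- train_idx
  model$val_idx <- val_idx
  model
}

#' @export
print.nichegp_model <- function(x, ...) {
  cat(sprintf("nichegp_model: %d spots x %d genes, %s mode\n",
              n_spots(x$ds), n_genes(x$ds), x$cfg$kernel_mode))
  sc <- softplus(x$params$raw_scales)
  cat(sprintf("  kernel scales: %s\n",
              paste(apply(round(sc, 3), 1, paste, collapse = "/"), collapse = "; ")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best val loss %.3f, beta %.3f\n",
                nrow(x$history), min(x$history$val_loss), x$beta))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of the full model state with a
#' JSON metadata sidecar (`<path>.json`) recording the configuration,
#' vocabularies and embedding block order.
#'
#' @param model a `nichegp_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` invisibly (for `save_model`); the model (for
#'   `load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(config = unclass(model$cfg),
               vocab = model$cb$vocab,
               block_order = model$cb$block_order,
               kernel_scales = softplus(model$params$raw_scales),
               n_spots = n_spots(model$ds), n_genes = n_genes(model$ds))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "nichegp_model")) stop("not a nichegp checkpoint")
  m
}
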