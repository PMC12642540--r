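#' Training configuration
#'
#' Defaults follow the model's standard parameterization: AdamW with
#' learning rate 1e-3 and weight decay 1e-6, minibatches of 256, encoder
#' widths [128, 64] and decoder width [128], 256-dimensional attribute
#' embeddings, a 2-dimensional GP latent space and an 8-dimensional
#' Gaussian latent space, kernel scales initialized at 10, a learnable
#' KL weight beta (init 10) steered toward a target KL of 0.025, basal
#' noise sd 0.1, basal L2 weight 1, mask temperature 1, early stopping
#' on a 5% validation split with patience 200 and delta 0, one latent
#' draw during training and 20 at inference.
#'
#' @param lr,weight_decay AdamW settings.
#' @param batch_size minibatch size.
#' @param enc_widths,dec_widths hidden-layer widths.
#' @param embed_dim dimensionality of every codebook block.
#' @param gp_dim,gaussian_dim latent split sizes.
#' @param scale_init initial Cauchy kernel scale per axis.
#' @param kl_target,beta_init KL controller settings.
#' @param lambda_l2 basal embedding penalty weight.
#' @param noise_sigma basal regularization noise sd.
#' @param embed_init_sd codebook initialization sd (see
#'   [init_codebooks()]).
#' @param basal_lr_mult learning-rate multiplier for the basal latent
#'   codes (latent optimization converges far slower than the shared
#'   networks at a common rate; codes are conventionally driven
#'   faster).
#' @param tau kernel mask temperature.
#' @param patience,min_delta,val_fraction early-stopping settings.
#' @param min_steps optimizer steps that must elapse before early
#'   stopping activates. Epochs are a poor proxy for optimization
#'   budget when a dataset holds only a few minibatches, so the
#'   guarantee is expressed in parameter updates; at large spot counts
#'   this floor is reached within a few epochs and the patience rule is
#'   unchanged.
#' @param g_train,g_infer latent draws for training / inference.
#' @param max_epochs hard cap on epochs.
#' @param inducing_steps inducing-grid points per axis.
#' @param range_max spatial domain after rescaling.
#' @param kernel_mode `"single_kernel"` (shared scales; the benchmark
#'   default) or `"per_perturbation"` (one scale vector per state).
#' @param use_cutoffs enable the learnable per-spot kernel cutoff mask
#'   (disabled by default: the raw kernel is used).
#' @param jitter kernel matrix jitter.
#' @param var_floor lower bound on encoder variances.
#' @param seed RNG seed for training.
#' @return a `nichegp_config` list.
#' @export
nichegp_config <- function(lr = 1e-3, weight_decay = 1e-6, batch_size = 256,
                           enc_widths = c(128, 64), dec_widths = 128,
                           embed_dim = 256, gp_dim = 2, gaussian_dim = 8,
                           scale_init = 10, kl_target = 0.025, beta_init = 10,
                           lambda_l2 = 1, noise_sigma = 0.1,
                           embed_init_sd = 0.1, basal_lr_mult = 10, tau = 1,
                           patience = 200, min_delta = 0, min_steps = 2500,
                           val_fraction = 0.05,
                           g_train = 1, g_infer = 20, max_epochs = 1500,
                           inducing_steps = 6, range_max = 20,
                           kernel_mode = c("single_kernel", "per_perturbation"),
                           use_cutoffs = FALSE,
                           jitter = 1e-6, var_floor = 1e-4, seed = 1) {
  cfg <- list(lr = lr, weight_decay = weight_decay, batch_size = batch_size,
              enc_widths = enc_widths, dec_widths = dec_widths,
              embed_dim = embed_dim, gp_dim = gp_dim,
              gaussian_dim = gaussian_dim, scale_init = scale_init,
              kl_target = kl_target, beta_init = beta_init,
              lambda_l2 = lambda_l2, noise_sigma = noise_sigma,
              embed_init_sd = embed_init_sd,
              basal_lr_mult = basal_lr_mult, tau = tau,
              patience = patience, min_delta = min_delta,
              min_steps = min_steps,
              val_fraction = val_fraction, g_train = g_train,
              g_infer = g_infer, max_epochs = max_epochs,
              inducing_steps = inducing_steps, range_max = range_max,
              kernel_mode = match.arg(kernel_mode),
              use_cutoffs = use_cutoffs,
              jitter = jitter, var_floor = var_floor, seed = seed)
  stopifnot(all(unlist(cfg[c("lr", "batch_size", "embed_dim", "gp_dim",
                             "gaussian_dim", "scale_init", "kl_target",
                             "beta_init", "tau", "g_train", "g_infer",
                             "max_epochs", "inducing_steps",
                             "range_max")]) > 0))
  structure(cfg, class = "nichegp_config")
}

inv_softplus <- function(y) y + log(-expm1(-y))

## integer labels + slide ids for kernel calls
label_ints <- function(ds) as.integer(ds$perturbation)
slide_ints <- function(ds) {
  if (nlevels(ds$slide) > 1) as.integer(ds$slide) else NULL
}

model_kernel_params <- function(model, raw_scales = model$params$raw_scales) {
  kernel_params(softplus(raw_scales),
                mode = model$cfg$kernel_mode,
                cutoffs = NULL,
                tau = model$cfg$tau)
}

model_inducing <- function(cfg, D, slide_levels) {
  grid <- make_inducing_grid(cfg$range_max, cfg$inducing_steps, D)
  if (length(slide_levels) > 1) {
    locs <- do.call(rbind, rep(list(grid), length(slide_levels)))
    slides <- rep(seq_along(slide_levels), each = nrow(grid))
    list(locations = locs, slides = slides)
  } else {
    list(locations = grid, slides = NULL)
  }
}

init_nichegp <- function(ds, cfg) {
  set.seed(cfg$seed)
  n <- n_spots(ds); G <- n_genes(ds); D <- ncol(ds$coords)
  cb <- init_codebooks(ds, dims = list(), seed = cfg$seed,
                       default_dim = cfg$embed_dim,
                       noise_sigma = cfg$noise_sigma,
                       l2_weight = cfg$lambda_l2,
                       init_sd = cfg$embed_init_sd)
  emb0 <- embed_spots(cb, 1L, ds$perturbation[1], ds$disease[1], ds$slide[1],
                      continuous = lapply(ds$continuous, `[`, 1))
  e_dim <- ncol(emb0$e)
  latent <- cfg$gp_dim + cfg$gaussian_dim
  n_kernels <- if (cfg$kernel_mode == "per_perturbation")
    nlevels(ds$perturbation) else 1L
  params <- list(
    enc = mlp_init(e_dim, cfg$enc_widths),
    enc_mu = dense_init(utils::tail(cfg$enc_widths, 1), latent),
    enc_var = dense_init(utils::tail(cfg$enc_widths, 1), latent),
    dec = mlp_init(latent, cfg$dec_widths),
    dec_mu = dense_init(utils::tail(cfg$dec_widths, 1), G),
    dec_th = dense_init(utils::tail(cfg$dec_widths, 1), G),
    pert_cb = cb$perturbation,
    raw_scales = matrix(inv_softplus(cfg$scale_init), n_kernels, D)
  )
  ## mean-head bias starts at the log per-gene mean at unit size factor,
  ## so optimization targets deviations rather than per-gene baselines
  sf0 <- compute_size_factors(ds)
  params$dec_mu$b <- log(pmax(colMeans(ds$counts / sf0), 1e-3))
  if (!is.null(cb$disease)) params$disease_cb <- cb$disease
  if (!is.null(cb$slide)) params$slide_cb <- cb$slide
  if (!is.null(cb$continuous)) {
    params$cont <- lapply(cb$continuous, function(p) p[c("W1", "b1", "W2", "b2")])
  }
  if (nlevels(ds$slide) > 1) {
    params$disp_off <- matrix(0, nlevels(ds$slide), G)
  }
  sf <- compute_size_factors(ds)
  model <- structure(list(
    cfg = cfg, ds = ds, sf = sf, cb = cb, params = params,
    basal = cb$basal,
    inducing = model_inducing(cfg, D, if (nlevels(ds$slide) > 1) levels(ds$slide) else "s"),
    beta = cfg$beta_init,
    blocks = emb0$blocks,
    history = NULL
  ), class = "nichegp_model")
  model
}

## refresh the codebook object from current parameters (basal + tables)
model_codebooks <- function(model) {
  cb <- model$cb
  cb$basal <- model$basal
  cb$perturbation <- model$params$pert_cb
  if (!is.null(cb$disease)) cb$disease <- model$params$disease_cb
  if (!is.null(cb$slide)) cb$slide <- model$params$slide_cb
  if (!is.null(cb$continuous)) {
    for (nm in names(cb$continuous)) {
      cb$continuous[[nm]][c("W1", "b1", "W2", "b2")] <- model$params$cont[[nm]]
    }
  }
  cb
}

#' Encode spot embeddings into latent means and variances
#'
#' @param model a trained or initialized `nichegp_model`.
#' @param e embedding matrix (spots x embedding dim).
#' @return list with `mu`, `var` (spots x (gp_dim + gaussian_dim)),
#'   the GP/Gaussian column split, and the hidden-layer cache.
#' @export
encode <- function(model, e) {
  p <- model$params
  fw <- mlp_forward(p$enc, e)
  H <- fw$out
  mu <- H %*% p$enc_mu$W + matrix(p$enc_mu$b, nrow(H), length(p$enc_mu$b), byrow = TRUE)
  vraw <- H %*% p$enc_var$W + matrix(p$enc_var$b, nrow(H), length(p$enc_var$b), byrow = TRUE)
  var <- softplus(vraw) + model$cfg$var_floor
  gp_cols <- seq_len(model$cfg$gp_dim)
  list(mu = mu, var = var, vraw = vraw, cache = fw,
       gp_cols = gp_cols,
       gauss_cols = model$cfg$gp_dim + seq_len(model$cfg$gaussian_dim))
}

#' Decode latent draws into NB parameters
#'
#' `mu_d = exp(head_mu(h))`, `theta_d = exp(softplus(head_theta(h)))`,
#' with a per-slide learned dispersion offset added inside the softplus
#' in multi-slide mode.
#'
#' @param model a `nichegp_model`.
#' @param z latent matrix (spots x (gp_dim + gaussian_dim)).
#' @param slide_idx optional integer slide index per spot.
#' @return list with `mu` and `theta` (spots x genes), plus caches.
#' @export
decode <- function(model, z, slide_idx = NULL) {
  p <- model$params
  fw <- mlp_forward(p$dec, z)
  H <- fw$out
  hmu <- H %*% p$dec_mu$W + matrix(p$dec_mu$b, nrow(H), length(p$dec_mu$b), byrow = TRUE)
  hth <- H %*% p$dec_th$W + matrix(p$dec_th$b, nrow(H), length(p$dec_th$b), byrow = TRUE)
  if (!is.null(p$disp_off) && !is.null(slide_idx)) {
    hth <- hth + p$disp_off[slide_idx, , drop = FALSE]
  }
  hmu <- pmin(pmax(hmu, -30), 30)
  mu <- exp(hmu)
  sp <- softplus(hth)
  theta <- pmin(exp(pmin(sp, 30)), 1e6)
  if (any(!is.finite(mu)) || any(!is.finite(theta)))
    stop("decoder produced non-finite output (exploding logits)")
  list(mu = mu, theta = theta, hmu = hmu, hth = hth, cache = fw)
}

#' Reparameterized latent draws
#'
#' `z = mu + eps * sqrt(var)` with `eps ~ N(0, I)`, repeated `g` times;
#' the column layout is the model's `[GP | Gaussian]` concatenation
#' order. Zero variance collapses every draw onto the mean; draws are
#' reproducible under `seed`.
#'
#' @param mu,var posterior mean and variance matrices (spots x latent).
#' @param g number of draws.
#' @param seed RNG seed.
#' @return list of `g` latent matrices.
#' @export
sample_latent <- function(mu, var, g = 1, seed = 1) {
  mu <- as.matrix(mu); var <- as.matrix(var)
  if (any(var < 0)) stop("variances must be non-negative")
  set.seed(seed)
  lapply(seq_len(g), function(r) {
    mu + matrix(stats::rnorm(length(mu)), nrow(mu)) * sqrt(var)
  })
}

#' Negative binomial reconstruction loss
#'
#' Mean over spots of the summed per-gene negative NB log-likelihood,
#' with rate `sf * mu` and dispersion `theta` (log-gamma form).
#'
#' @param x raw count matrix (spots x genes).
#' @param mu,theta decoder outputs (spots x genes).
#' @param sf per-spot size factors.
#' @return scalar mean loss.
#' @export
nb_loss <- function(x, mu, theta, sf) {
  m <- sf * mu
  ll <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * log(theta / (theta + m)) + x * log(m / (theta + m))
  ll[x == 0 & m == 0] <- 0
  mean(rowSums(-ll))
}

## dNLL/dmu and dNLL/dtheta for the per-entry negative log-likelihood
nb_loss_grad <- function(x, mu, theta, sf) {
  m <- sf * mu
  gm <- (theta + x) / (theta + m) - x / pmax(m, 1e-12)
  gmu <- gm * sf
  gth <- -(digamma(x + theta) - digamma(theta) + log(theta / (theta + m)) +
             1 - (theta + x) / (theta + m))
  list(gmu = gmu, gth = gth)
}

#' Closed-form KL terms of the latent posterior
#'
#' `kl_gauss`: KL of the diagonal Gaussian posterior against N(0, I),
#' summed over Gaussian latent dimensions and averaged over spots.
#' `kl_gp`: the sparse-GP cross-entropy between the inducing-point
#' variational posterior and the GP prior, summed over GP dimensions and
#' scaled per spot (divided by the number of training spots).
#'
#' @param enc output of [encode()].
#' @param gp_caches list of per-dimension SVGP caches (from the forward
#'   pass), or `NULL` to skip the GP term.
#' @param n_total number of training spots (for per-spot scaling).
#' @return list with `kl_gauss` and `kl_gp`.
#' @export
compute_kl <- function(enc, gp_caches = NULL, n_total = 1) {
  muG <- enc$mu[, enc$gauss_cols, drop = FALSE]
  varG <- enc$var[, enc$gauss_cols, drop = FALSE]
  kl_gauss <- mean(rowSums(0.5 * (varG + muG^2 - 1 - log(varG))))
  kl_gp <- 0
  if (!is.null(gp_caches)) {
    kl_gp <- sum(vapply(gp_caches, svgp_kl_dim, numeric(1))) / n_total
  }
  list(kl_gauss = kl_gauss, kl_gp = kl_gp)
}
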