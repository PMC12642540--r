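## Sparse variational GP machinery, per latent dimension.
##
## Training spots carry heteroscedastic pseudo-observations (mu, sigma^2)
## produced by the encoder; inducing points on a fixed grid summarize the
## posterior. With w = 1/sigma^2 and minibatch scale s = N_total/N_batch:
##   Sigma_l = K_PP + s * K_PS diag(w) K_SP
##   mean(t) = s * K_tP Sigma_l^{-1} K_PS diag(w) mu
##   cov(t)  = K_tt - K_tP K_PP^{-1} K_Pt + K_tP Sigma_l^{-1} K_Pt
## Backward passes below are exact analytic gradients wrt mu and w; they
## are verified against central finite differences in the test suite.

chol_or_stop <- function(A, what) {
  tryCatch(chol(A), error = function(e) {
    stop(sprintf("%s is singular after jitter; use fewer inducing points or larger jitter (%s)",
                 what, conditionMessage(e)))
  })
}

svgp_forward_dim <- function(KPP, KPS, KtP, Ktt_diag, w, mu, s, jitter = 1e-6) {
  M <- nrow(KPP)
  KPPj <- KPP + diag(jitter, M)
  Sl <- KPPj + s * (KPS %*% (w * t(KPS)))
  cholSl <- chol_or_stop(Sl, "Sigma_l")
  B <- chol2inv(cholSl)                     # Sigma_l^{-1}
  cholP <- chol_or_stop(KPPj, "K_PP")
  KPPinv <- chol2inv(cholP)
  v <- KPS %*% (w * mu)                     # M x 1
  Bv <- B %*% v
  mean_t <- as.numeric(s * KtP %*% Bv)
  var_t <- Ktt_diag -
    rowSums((KtP %*% KPPinv) * KtP) +
    rowSums((KtP %*% B) * KtP)
  var_t <- pmax(var_t, 1e-10)
  list(mean = mean_t, var = var_t,
       cache = list(KPP = KPPj, KPS = KPS, KtP = KtP, B = B,
                    KPPinv = KPPinv, cholSl = cholSl, v = v, Bv = Bv,
                    w = w, mu = mu, s = s))
}

## gmean, gvar: dLoss/dmean, dLoss/dvar at the test points.
## Returns gradients wrt mu and w (training pseudo-observations).
svgp_backward_dim <- function(cache, gmean, gvar) {
  s <- cache$s; B <- cache$B; KPS <- cache$KPS; KtP <- cache$KtP
  a <- B %*% (t(KtP) %*% gmean)                       # M
  KSa <- as.numeric(t(KPS) %*% a)                     # N
  gmu <- s * cache$w * KSa
  gw <- s * KSa * cache$mu -
    s^2 * KSa * as.numeric(t(KPS) %*% cache$Bv)
  if (any(gvar != 0)) {
    Gt <- t(KtP) %*% (gvar * KtP)                     # M x M
    Q <- B %*% Gt %*% B
    gw <- gw - s * colSums(KPS * (Q %*% KPS))
  }
  list(gmu = as.numeric(gmu), gw = as.numeric(gw))
}

## KL( q(u) || N(0, K_PP) ) with the whitened optimal q(u) implied by the
## encoder pseudo-observations:
##   m = s K_PP Sigma_l^{-1} v,  S = K_PP Sigma_l^{-1} K_PP
##   KL = 0.5 [ tr(B K_PP) + s^2 v' B K_PP B v - M
##              + logdet Sigma_l - logdet K_PP ]
svgp_kl_dim <- function(cache) {
  B <- cache$B; KPP <- cache$KPP; v <- cache$v; s <- cache$s
  M <- nrow(KPP)
  cholP <- chol_or_stop(KPP, "K_PP")
  BK <- B %*% KPP
  quad <- as.numeric(s^2 * t(v) %*% (BK %*% (B %*% v)))
  logdetSl <- 2 * sum(log(diag(cache$cholSl)))
  logdetP <- 2 * sum(log(diag(cholP)))
  kl <- 0.5 * (sum(B * t(KPP)) + quad - M + logdetSl - logdetP)
  max(kl, 0)
}

svgp_kl_backward_dim <- function(cache) {
  B <- cache$B; KPP <- cache$KPP; KPS <- cache$KPS
  v <- cache$v; Bv <- cache$Bv; s <- cache$s; w <- cache$w; mu <- cache$mu
  P2 <- B %*% KPP %*% B                       # B K_PP B, symmetric
  u2 <- as.numeric(s^2 * P2 %*% v)            # dKL/dv
  KSu2 <- as.numeric(t(KPS) %*% u2)
  gmu <- w * KSu2
  gw <- KSu2 * mu -
    0.5 * s * colSums(KPS * (P2 %*% KPS)) -
    s^3 * as.numeric(t(KPS) %*% Bv) * as.numeric(t(KPS) %*% (P2 %*% v)) +
    0.5 * s * colSums(KPS * (B %*% KPS))
  list(gmu = as.numeric(gmu), gw = as.numeric(gw))
}

#' Sparse GP posterior at test locations
#'
#' Computes the inducing-point (sparse variational) GP posterior given
#' per-spot heteroscedastic pseudo-observations. With inducing points
#' equal to the training points and full batches this reduces exactly to
#' heteroscedastic GP regression.
#'
#' @param train_coords N x D matrix of training spot locations.
#' @param train_mu numeric N-vector or N x dims matrix of pseudo-
#'   observation means (one column per GP latent dimension).
#' @param train_var matching vector/matrix of positive variances.
#' @param test_coords T x D matrix of locations to predict at.
#' @param inducing M x D matrix of inducing locations (see
#'   [make_inducing_grid()]).
#' @param params a [kernel_params()].
#' @param batch_fraction fraction of the training set present in
#'   `train_mu` (the SVGP scale factor is its reciprocal); default 1.
#' @param train_labels,test_labels optional integer perturbation indices
#'   for per-perturbation kernel dispatch.
#' @param train_slides,test_slides,inducing_slides optional integer slide
#'   ids; kernel entries across slides are exactly zero.
#' @param jitter diagonal jitter added to inducing kernel matrices.
#' @return list with `mean` (T x dims), `var` (T x dims) and the kernel
#'   caches used (internal).
#' @export
sparse_gp_posterior <- function(train_coords, train_mu, train_var,
                                test_coords, inducing, params,
                                batch_fraction = 1,
                                train_labels = NULL, test_labels = NULL,
                                train_slides = NULL, test_slides = NULL,
                                inducing_slides = NULL,
                                jitter = 1e-6) {
  train_mu <- as.matrix(train_mu)
  train_var <- as.matrix(train_var)
  if (any(train_var <= 0)) stop("train_var must be strictly positive")
  s <- 1 / batch_fraction
  ## inducing points are perturbation-agnostic: spot-inducing kernels
  ## adopt the spot's per-perturbation scales, inducing-inducing kernels
  ## use the mean scale vector
  KPP <- kernel_matrix(inducing, inducing, params,
                       slides_a = inducing_slides, slides_b = inducing_slides)
  KPS <- kernel_matrix(inducing, train_coords, params,
                       labels_b = train_labels,
                       slides_a = inducing_slides, slides_b = train_slides)
  KtP <- kernel_matrix(test_coords, inducing, params,
                       labels_a = test_labels,
                       slides_a = test_slides, slides_b = inducing_slides)
  Ktt_diag <- rep(1, nrow(as.matrix(test_coords)))
  dims <- ncol(train_mu)
  mean_out <- matrix(0, nrow(as.matrix(test_coords)), dims)
  var_out <- matrix(0, nrow(as.matrix(test_coords)), dims)
  caches <- vector("list", dims)
  for (d in seq_len(dims)) {
    fit <- svgp_forward_dim(KPP, KPS, KtP, Ktt_diag,
                            w = 1 / train_var[, d], mu = train_mu[, d],
                            s = s, jitter = jitter)
    mean_out[, d] <- fit$mean
    var_out[, d] <- fit$var
    caches[[d]] <- fit$cache
  }
  structure(list(mean = mean_out, var = var_out, caches = caches),
            class = "gp_posterior")
}
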