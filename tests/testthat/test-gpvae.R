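test_that("NB loss matches the log-gamma oracle and hand values", {
  ## x = 0, mu = theta = sf = 1: -log((theta/(theta+mu))^theta) = log 2
  expect_equal(nb_loss(matrix(0), matrix(1), matrix(1), 1), log(2),
               tolerance = 1e-12)
  ## random grid vs dnbinom (independent log-pmf implementation)
  set.seed(30)
  n <- 25; g <- 40   # 1000 entries
  x <- matrix(rpois(n * g, 4), n, g)
  mu <- matrix(rgamma(n * g, 3, 1), n, g)
  th <- matrix(rgamma(n * g, 2, 0.5), n, g)
  sf <- runif(n, 0.5, 2)
  oracle <- mean(rowSums(-dnbinom(x, size = th, mu = sf * mu, log = TRUE)))
  expect_equal(nb_loss(x, mu, th, sf), oracle, tolerance = 1e-8)
})

test_that("NB loss approaches the Poisson limit for large dispersion", {
  set.seed(31)
  x <- matrix(rpois(200, 5), 10, 20)
  mu <- matrix(rgamma(200, 5, 1), 10, 20)
  sf <- rep(1, 10)
  nb <- nb_loss(x, mu, matrix(1e6, 10, 20), sf)
  pois <- mean(rowSums(-dpois(x, mu, log = TRUE)))
  expect_equal(nb, pois, tolerance = 1e-4)
})

test_that("decoder heads follow the stated closed forms", {
  sim <- tiny_dataset()
  cfg <- nichegp_config(embed_dim = 8, enc_widths = c(8, 6), dec_widths = 6,
                        gp_dim = 2, gaussian_dim = 3, seed = 2)
  model <- nichegp:::init_nichegp(normalize_counts(sim$dataset), cfg)
  ## zero heads: mu = exp(0) = 1, theta = exp(softplus(0)) = 2
  model$params$dec_mu$W[] <- 0; model$params$dec_mu$b[] <- 0
  model$params$dec_th$W[] <- 0; model$params$dec_th$b[] <- 0
  out <- decode(model, matrix(0, 4, 5))
  expect_equal(unname(out$mu), matrix(1, 4, nrow(out$mu) * 0 + ncol(out$mu)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(out$mu - 1) < 1e-12))
  expect_equal(out$theta[1, 1], 2, tolerance = 1e-12)
})

test_that("encoder is deterministic with softplus variances", {
  sim <- tiny_dataset()
  ds <- normalize_counts(sim$dataset)
  cfg <- nichegp_config(embed_dim = 8, enc_widths = c(8, 6), dec_widths = 6,
                        gp_dim = 2, gaussian_dim = 3, seed = 2)
  model <- nichegp:::init_nichegp(ds, cfg)
  emb <- nichegp:::ngp_embeddings(model, 1:10)
  e1 <- encode(model, emb$e)
  e2 <- encode(model, emb$e)
  expect_identical(e1$mu, e2$mu)
  expect_true(all(e1$var > 0))
  expect_equal(ncol(e1$mu), 5)
  expect_equal(e1$gp_cols, 1:2)
  ## zero-weight encoder: mu = bias, var = softplus(bias) + floor
  model$params$enc_mu$W[] <- 0; model$params$enc_mu$b[] <- 0.7
  model$params$enc_var$W[] <- 0; model$params$enc_var$b[] <- -0.3
  e3 <- encode(model, emb$e)
  expect_true(all(abs(e3$mu - 0.7) < 1e-12))
  expect_equal(e3$var[3, 4], log1p(exp(-0.3)) + cfg$var_floor,
               tolerance = 1e-10)
})

test_that("Gaussian KL closed form: zero at the prior, non-negative", {
  enc <- list(mu = cbind(0, 0, 0), var = cbind(1, 1, 1),
              gauss_cols = 1:3, gp_cols = integer(0))
  expect_equal(compute_kl(enc, NULL)$kl_gauss, 0)
  set.seed(33)
  for (r in 1:20) {
    enc <- list(mu = matrix(rnorm(15), 5), var = matrix(rgamma(15, 2, 2), 5),
                gauss_cols = 1:3)
    kl <- compute_kl(enc, NULL)$kl_gauss
    expect_true(kl >= 0)
    ## textbook closed form for diagonal Gaussians
    manual <- mean(rowSums(0.5 * (enc$var + enc$mu^2 - 1 - log(enc$var))))
    expect_equal(kl, manual, tolerance = 1e-12)
  }
})

test_that("minibatch gradients match central finite differences", {
  sim <- tiny_dataset()
  ds <- normalize_counts(sim$dataset)
  cfg <- nichegp_config(embed_dim = 6, enc_widths = c(8, 6), dec_widths = 8,
                        gp_dim = 2, gaussian_dim = 3, batch_size = 16,
                        inducing_steps = 3, seed = 5,
                        kernel_mode = "per_perturbation")
  model <- nichegp:::init_nichegp(ds, cfg)
  model$beta <- 2.5
  idx <- c(2, 5, 9, 14, 20, 28)
  latent <- cfg$gp_dim + cfg$gaussian_dim
  set.seed(99)
  rand <- list(basal_noise = matrix(rnorm(length(idx) * ncol(model$basal),
                                          sd = cfg$noise_sigma), length(idx)),
               eps = matrix(rnorm(length(idx) * latent), length(idx), latent))
  fw <- nichegp:::ngp_batch_forward(model, idx, rand, n_total = 28)
  bw <- nichegp:::ngp_batch_backward(model, fw)
  loss_of <- function(m) nichegp:::ngp_batch_forward(m, idx, rand,
                                                     n_total = 28)$loss
  h <- 1e-5
  fd_vs <- function(mutate, analytic) {
    mp <- mutate(model, h); mm <- mutate(model, -h)
    fd <- (loss_of(mp) - loss_of(mm)) / (2 * h)
    expect_equal(as.numeric(analytic), as.numeric(fd), tolerance = 1e-4)
  }
  fd_vs(function(m, d) { m$params$enc[[1]]$W[3, 2] <- m$params$enc[[1]]$W[3, 2] + d; m },
        bw$grads$enc[[1]]$W[3, 2])
  fd_vs(function(m, d) { m$params$enc_mu$W[2, 1] <- m$params$enc_mu$W[2, 1] + d; m },
        bw$grads$enc_mu$W[2, 1])   # GP column: through the SVGP solve
  fd_vs(function(m, d) { m$params$enc_var$W[3, 1] <- m$params$enc_var$W[3, 1] + d; m },
        bw$grads$enc_var$W[3, 1])  # GP variance path + KL
  fd_vs(function(m, d) { m$params$dec_mu$W[5, 7] <- m$params$dec_mu$W[5, 7] + d; m },
        bw$grads$dec_mu$W[5, 7])
  fd_vs(function(m, d) { m$params$dec_th$W[5, 3] <- m$params$dec_th$W[5, 3] + d; m },
        bw$grads$dec_th$W[5, 3])
  fd_vs(function(m, d) { m$params$pert_cb[1, 4] <- m$params$pert_cb[1, 4] + d; m },
        bw$grads$pert_cb[1, 4])
  fd_vs(function(m, d) { m$basal[idx[2], 3] <- m$basal[idx[2], 3] + d; m },
        bw$g_basal_rows[2, 3])
})

test_that("latent sampling is seeded and mean-consistent", {
  mu <- matrix(c(1, -2), 1)
  v <- matrix(c(0.25, 4), 1)
  ## zero variance collapses onto the mean for every draw
  z0 <- sample_latent(mu, mu * 0, g = 3, seed = 1)
  for (z in z0) expect_equal(z, mu)
  ## fixed seed reproduces draws exactly
  expect_identical(sample_latent(mu, v, g = 5, seed = 9),
                   sample_latent(mu, v, g = 5, seed = 9))
  ## Monte-Carlo mean within 3 standard errors
  draws <- sample_latent(mu, v, g = 1e5, seed = 4)
  m_hat <- colMeans(do.call(rbind, draws))
  se <- sqrt(as.numeric(v)) / sqrt(1e5)
  expect_true(all(abs(m_hat - as.numeric(mu)) < 3 * se))
  expect_error(sample_latent(mu, -v), "non-negative")
})

test_that("short training runs deterministically and checkpoints round-trip", {
  sim <- tiny_dataset(n = 50, g = 12, seed = 13)
  cfg <- nichegp_config(max_epochs = 3, embed_dim = 8, enc_widths = c(12, 8),
                        dec_widths = 8, batch_size = 32, patience = 10,
                        seed = 9)
  m1 <- train_nichegp(sim$dataset, cfg)
  m2 <- train_nichegp(sim$dataset, cfg)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$params$enc[[1]]$W, m2$params$enc[[1]]$W)
  path <- file.path(tempdir(), "ckpt.rds")
  save_model(m1, path)
  expect_true(file.exists(paste0(path, ".json")))
  m3 <- load_model(path)
  p1 <- predict_mean(m1, spots = 1:5, g = 2, seed = 3)
  p3 <- predict_mean(m3, spots = 1:5, g = 2, seed = 3)
  expect_identical(p1$mean, p3$mean)
  ## too-small datasets are rejected for the validation split
  smal <- subset_spots(sim$dataset, 1:10)
  expect_error(train_nichegp(smal, cfg), "validation")
})

test_that("training loss decreases on fixture data", {
  sim <- tiny_dataset(n = 60, g = 15, seed = 17)
  cfg <- nichegp_config(max_epochs = 50, embed_dim = 8, enc_widths = c(16, 8),
                        dec_widths = 12, batch_size = 64, patience = 10^6,
                        seed = 10)
  m <- train_nichegp(sim$dataset, cfg)
  ## running-min trend of the reconstruction term: the late best
  ## improves on the early best (the total is confounded by the moving
  ## beta weight, and the decoder bias init starts near baseline)
  expect_lt(min(m$history$recon[41:50]), min(m$history$recon[1:5]))
})

test_that("predictive interval endpoints are monotone in the level", {
  tm <- get_tiny_model()
  p90 <- predict_mean(tm$model, spots = 1:4, g = 4, seed = 2,
                      intervals = TRUE, level = 0.90)
  p99 <- predict_mean(tm$model, spots = 1:4, g = 4, seed = 2,
                      intervals = TRUE, level = 0.99)
  expect_true(all(p99$lower <= p90$lower))
  expect_true(all(p99$upper >= p90$upper))
  expect_true(all(p90$lower <= p90$upper))
})
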