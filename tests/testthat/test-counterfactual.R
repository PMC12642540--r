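test_that("identity edits are exact no-ops in every mode", {
  tm <- get_tiny_model()
  m <- tm$model
  ctrl <- which(m$ds$perturbation == "control")[1:10]
  base <- predict_mean(m, spots = ctrl, g = 3, seed = 2)
  ## control -> control swap
  sw <- swap_perturbation(m, ctrl, list(perturbation = "control"),
                          predict_spots = ctrl, g = 3, seed = 2)
  expect_identical(sw$mean, base$mean)
  ## identity niche edit
  ko <- which(m$ds$perturbation == "KO")
  ne <- edit_niche(m, ctrl, ko, list(perturbation = "KO"), g = 3, seed = 2)
  expect_identical(ne$mean, base$mean)
})

test_that("edits are deterministic and never mutate the checkpoint", {
  tm <- get_tiny_model()
  m <- tm$model
  before <- m$params$pert_cb
  s1 <- swap_perturbation(m, 1:5, list(perturbation = "KO"),
                          predict_spots = 1:5, g = 4, seed = 7)
  s2 <- swap_perturbation(m, 1:5, list(perturbation = "KO"),
                          predict_spots = 1:5, g = 4, seed = 7)
  expect_identical(s1$mean, s2$mean)
  expect_identical(m$params$pert_cb, before)
  expect_error(swap_perturbation(m, 1:5, list(perturbation = "missing")),
               "unknown perturbation")
})

test_that("editing a patch influences in-range neighbors only", {
  tm <- get_tiny_model()
  m <- tm$model
  ds <- m$ds
  ctrl <- which(ds$perturbation == "control")
  ## a patch far from the trained KO patch at (6,6)
  dd <- sqrt((ds$coords[ctrl, 1] - 16)^2 + (ds$coords[ctrl, 2] - 16)^2)
  patch <- ctrl[order(dd)][1:4]
  others <- setdiff(seq_len(nrow(ds$counts)), patch)
  base <- predict_mean(m, spots = others, g = 3, seed = 2)
  sw <- swap_perturbation(m, patch, list(perturbation = "KO"),
                          predict_spots = others, g = 3, seed = 2)
  delta <- rowMeans(abs(log1p(sw$mean) - log1p(base$mean)))
  d_to_patch <- sapply(others, function(i) {
    min(sqrt(colSums((t(ds$coords[patch, , drop = FALSE]) - ds$coords[i, ])^2)))
  })
  ## near spots move more than far spots
  expect_gt(mean(delta[d_to_patch < 3]), mean(delta[d_to_patch > 10]))
})

test_that("cross-slide influence is exactly zero", {
  ts <- get_two_slide_model()
  m <- ts$model
  ds <- m$ds
  s1 <- which(ds$slide == "slide1")
  s2 <- which(ds$slide == "slide2")
  base <- predict_mean(m, spots = s2, g = 3, seed = 2)
  sw <- swap_perturbation(m, s1[1:8], list(perturbation = "KO"),
                          predict_spots = s2, g = 3, seed = 2)
  expect_identical(sw$mean, base$mean)
  ## same through the niche-editing mode
  ne <- edit_niche(m, s2[1:5], s1[1:8], list(perturbation = "KO"),
                   g = 3, seed = 2)
  base2 <- predict_mean(m, spots = s2[1:5], g = 3, seed = 2)
  expect_identical(ne$mean, base2$mean)
})

test_that("attribute-aware imputation averages neighbor basal embeddings", {
  tm <- get_tiny_model()
  m <- tm$model
  ds <- m$ds
  ## place a new spot exactly at an observed control spot
  i <- which(ds$perturbation == "control")[5]
  nn <- nichegp:::nearest_neighbors(ds$coords, ds$coords[i, , drop = FALSE],
                                    k = 2)
  expect_equal(nn[1, 1], i)  # coincident spot is its own nearest neighbor
  pred <- impute_with_attributes(m, ds$coords[i, , drop = FALSE],
                                 labels = list(perturbation = "control",
                                               disease = as.character(ds$disease[i])),
                                 k = 6, g = 6, seed = 3)
  rec <- predict_mean(m, spots = i, g = 6, seed = 3)
  ## coincident virtual spot reproduces the observed spot's profile up
  ## to GP smoothing and the neighbor-averaged basal embedding
  expect_gt(score_pcc(log1p(as.numeric(pred$mean)),
                      log1p(as.numeric(rec$mean))), 0.85)
})

test_that("blind imputation beats the global-mean baseline on a smooth field", {
  tm <- get_tiny_model()
  m <- tm$model
  ds <- m$ds
  set.seed(8)
  mask <- sample(which(ds$perturbation == "control"), 15)
  pred <- impute_blind(m, ds$coords[mask, , drop = FALSE], g = 6, seed = 3)
  truth <- ds$normalized[mask, , drop = FALSE]
  r2_model <- score_r2(as.numeric(predicted_nex(pred)), as.numeric(truth))
  gm <- colMeans(ds$normalized[-mask, , drop = FALSE])
  r2_base <- score_r2(as.numeric(matrix(gm, 15, length(gm), byrow = TRUE)),
                      as.numeric(truth))
  expect_gt(r2_model, r2_base)
})

test_that("far-from-tissue coordinates revert to the GP prior", {
  tm <- get_tiny_model()
  m <- tm$model
  far <- matrix(c(2000, 2000), 1)
  pred <- impute_blind(m, far, g = 3, seed = 2)
  expect_equal(as.numeric(pred$gp_mean), rep(0, m$cfg$gp_dim),
               tolerance = 1e-3)
  expect_equal(as.numeric(pred$gp_var), rep(1, m$cfg$gp_dim),
               tolerance = 1e-3)
})

test_that("resolution enhancement inserts deduplicated midpoints", {
  tm <- get_tiny_model()
  m <- tm$model
  pred <- suppressWarnings(enhance_resolution(m, g = 2, seed = 2))
  ## a virtual spot lies strictly inside the observed bounding box
  expect_true(nrow(pred$mean) > 0)
  co <- m$ds$coords
  expect_true(all(pred$coords[, 1] >= min(co[, 1]) &
                    pred$coords[, 1] <= max(co[, 1])))
  ## no virtual spot coincides with an observed spot
  okey <- apply(round(co, 8), 1, paste, collapse = "_")
  vkey <- apply(round(pred$coords, 8), 1, paste, collapse = "_")
  expect_false(any(vkey %in% okey))
  expect_false(anyDuplicated(vkey) > 0)
})

test_that("virtual spots on a monotone gradient interpolate their flanks", {
  ## deterministic check on the GP pathway: pseudo-observations rise
  ## linearly along x, midpoints must lie between flanking values
  co <- cbind(seq(0, 20, by = 2), rep(0, 11))
  mu <- co[, 1] / 10
  mid <- cbind(seq(1, 19, by = 2), rep(0, 10))
  fit <- sparse_gp_posterior(co, mu, rep(0.01, 11), mid, inducing = co,
                             params = kernel_params(c(4, 4)))
  for (i in seq_len(10)) {
    lo <- mu[i]; hi <- mu[i + 1]
    expect_gt(fit$mean[i, 1], lo - 0.05)
    expect_lt(fit$mean[i, 1], hi + 0.05)
  }
})

test_that("region filling recovers a removed location and records provenance", {
  tm <- get_tiny_model()
  m <- tm$model
  ds <- m$ds
  i <- 30
  sp <- nichegp:::lattice_spacing(ds$coords)
  poly <- rbind(ds$coords[i, 1:2] + c(-0.6, -0.6) * sp,
                ds$coords[i, 1:2] + c(0.6, -0.6) * sp,
                ds$coords[i, 1:2] + c(0.6, 0.6) * sp,
                ds$coords[i, 1:2] + c(-0.6, 0.6) * sp)
  pred <- fill_region(m, poly, labels = list(perturbation = "KO"),
                      g = 2, seed = 2)
  expect_gt(nrow(pred$mean), 0)
  d <- min(sqrt((pred$coords[, 1] - ds$coords[i, 1])^2 +
                  (pred$coords[, 2] - ds$coords[i, 2])^2))
  expect_lt(d, sp)
  expect_equal(pred$provenance$mode, "fill_region")
  expect_equal(pred$provenance$edits$perturbation[1], "KO")
  expect_error(fill_region(m, poly / 1e6), "empty region")
})

test_that("3D models propagate edits with z-attenuation; 2D models refuse", {
  sim <- make_fixture("stack3d", file.path(tempdir(), "cf3d"), seed = 4)
  cfg <- nichegp_config(max_epochs = 60, embed_dim = 16,
                        enc_widths = c(32, 16), dec_widths = 32,
                        batch_size = 256, patience = 10^6,
                        inducing_steps = 4, seed = 3)
  m3 <- train_nichegp(sim$dataset, cfg)
  ds <- m3$ds
  sec1 <- which(ds$coords[, 3] == min(ds$coords[, 3]))
  cand <- sec1[ds$perturbation[sec1] == "control"]; ctr <- cand[order((ds$coords[cand, 1] - 10)^2 + (ds$coords[cand, 2] - 10)^2)][1:6]
  others <- setdiff(seq_len(nrow(ds$counts)), ctr)
  base <- predict_3d(m3, predict_spots = others, g = 3, seed = 2)
  sw <- predict_3d(m3, target_spots = ctr, edits = list(perturbation = "PT"),
                   predict_spots = others, g = 3, seed = 2)
  delta <- rowMeans(abs(log1p(sw$mean) - log1p(base$mean)))
  zs <- sort(unique(ds$coords[, 3]))
  ## xy-aligned column above the edited patch: effect decays with z
  dxy <- sqrt((ds$coords[others, 1] - 10)^2 + (ds$coords[others, 2] - 10)^2)
  med <- sapply(zs[-1], function(z) {
    mean(delta[ds$coords[others, 3] == z & dxy < 6])
  })
  expect_true(all(diff(med) <= 0))
  expect_gt(med[1], med[length(med)])
  ## a 2D checkpoint refuses the 3D mode
  tm <- get_tiny_model()
  expect_error(predict_3d(tm$model), "2D")
})

test_that("tiny z-scales sever cross-section kernels", {
  kp <- kernel_params(c(10, 10, 1e-8))
  expect_lt(cauchy_kernel(c(1, 1, 0.4), c(1, 1, 0.8), kp$scales[1, ]), 1e-6)
  expect_equal(cauchy_kernel(c(1, 1, 0.4), c(1, 1, 0.4), kp$scales[1, ]), 1)
})
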