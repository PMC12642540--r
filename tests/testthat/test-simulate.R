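test_that("lattice geometry: counts, domain, hex neighbor degree", {
  sim <- simulate_spatial(sim_config(n_spots = 400, n_genes = 20,
                                     lattice = "hex",
                                     perturbations = list(
                                       KO = list(n_affected = 5, lfc = 1,
                                                 decay_scale = 4,
                                                 patch_center = NULL,
                                                 patch_radius = 2.5)),
                                     seed = 2))
  co <- sim$dataset$coords
  expect_equal(nrow(co), 400)
  expect_true(max(co) <= 20 + 1e-9 && min(co) >= 0)
  ## hex lattice: median neighbor degree 6 within 1.5 spacings
  d <- as.matrix(dist(co)); diag(d) <- Inf
  spacing <- median(apply(d, 1, min))
  deg <- rowSums(d <= 1.5 * spacing)
  expect_equal(median(deg), 6)
})

test_that("simulation is deterministic under seed and labels are consistent", {
  cfg <- sim_config(n_spots = 80, n_genes = 25,
                    perturbations = list(KO = list(n_affected = 5, lfc = 1,
                                                   decay_scale = 4,
                                                   patch_center = NULL,
                                                   patch_radius = 3)),
                    seed = 9)
  s1 <- simulate_spatial(cfg)
  s2 <- simulate_spatial(cfg)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$truth$mean, s2$truth$mean)
  ## patch spots carry the perturbed label and full effect weight
  ko <- which(s1$dataset$perturbation == "KO")
  expect_true(length(ko) > 0)
  expect_true(all(s1$truth$decay[ko, "KO"] == 1))
  ## decay weights fall off away from the patch
  ctrl <- which(s1$dataset$perturbation == "control")
  dd <- sqrt((s1$dataset$coords[ctrl, 1] - 10)^2 +
               (s1$dataset$coords[ctrl, 2] - 10)^2)
  expect_lt(mean(s1$truth$decay[ctrl[dd > 8], "KO"]),
            mean(s1$truth$decay[ctrl[dd < 5], "KO"]))
})

test_that("counts are NB around size_factor * exp(log_mean)", {
  ## replicate the emission at fixed latent state on a 5-spot probe
  cfg <- sim_config(n_spots = 60, n_genes = 30,
                    perturbations = list(KO = list(n_affected = 5, lfc = 1,
                                                   decay_scale = 4,
                                                   patch_center = NULL,
                                                   patch_radius = 3)),
                    seed = 12)
  sim <- simulate_spatial(cfg)
  probe <- 1:5
  mu <- sim$truth$mean[probe, , drop = FALSE]
  set.seed(1)
  reps <- 2000
  acc <- matrix(0, length(probe), ncol(mu))
  for (r in seq_len(reps)) {
    acc <- acc + matrix(rnbinom(length(mu), size = cfg$nb_dispersion,
                                mu = as.numeric(mu)), nrow(mu)) / reps
  }
  expect_lt(max(abs(acc - mu) / pmax(mu, 0.5)), 0.15)
  ## and the generator's own draw has the right scale overall
  expect_equal(mean(sim$dataset$counts), mean(sim$truth$mean),
               tolerance = 0.1)
})

test_that("simulated GP field covariance matches the Cauchy kernel", {
  ## empirical covariance over replicate fields vs the specified kernel
  set.seed(3)
  n <- 100
  co <- nichegp:::lattice_coords(n, "square", 20)
  K <- nichegp:::kernel_matrix(co, co, kernel_params(c(10, 10)))
  reps <- 1000
  emp <- matrix(0, n, n)
  L <- chol(K + diag(1e-6, n))
  for (r in seq_len(reps)) {
    f <- as.numeric(t(L) %*% rnorm(n))
    emp <- emp + tcrossprod(f) / reps
  }
  expect_lt(norm(emp - K, "F") / norm(K, "F"), 0.15)
})

test_that("zero effect vectors leave perturbed spots exchangeable", {
  ## E-distance permutation test between labelled groups, no effect
  pvals <- sapply(1:5, function(s) {
    sim <- simulate_spatial(sim_config(
      n_spots = 120, n_genes = 20, gp_scale = 1e4, niche_effect = 0,
      perturbations = list(KO = list(n_affected = 0, lfc = 0,
                                     decay_scale = 4, patch_center = NULL,
                                     patch_radius = 4)),
      seed = s))
    ds <- normalize_counts(sim$dataset)
    ko <- which(ds$perturbation == "KO")
    ctrl <- which(ds$perturbation == "control")
    obs <- e_distance(ds$normalized[ko, ], ds$normalized[ctrl, ])
    k <- length(ko)
    perm <- replicate(99, {
      sh <- sample(nrow(ds$normalized))
      e_distance(ds$normalized[sh[seq_len(k)], , drop = FALSE],
                 ds$normalized[sh[-seq_len(k)], , drop = FALSE])
    })
    mean(c(perm, obs) >= obs)
  })
  ## at alpha = 0.05 the null should not be rejected systematically
  expect_gt(mean(pvals > 0.05), 0.5)
})

test_that("fixtures are written as CSV triplets with ground truth", {
  dir <- file.path(tempdir(), "fix_tiny")
  sim <- make_fixture("tiny", dir, seed = 4)
  expect_equal(nrow(sim$dataset$counts), 50)
  expect_equal(ncol(sim$dataset$counts), 40)
  expect_equal(nlevels(sim$dataset$perturbation), 3)  # control + 2 KOs
  expect_true(all(file.exists(file.path(dir,
    c("counts.csv", "coords.csv", "attrs.csv", "ground_truth.json")))))
  back <- load_dataset(dir, "csv_triplet")
  expect_equal(unname(back$counts), unname(sim$dataset$counts))
})

test_that("time-course fixture has monotone marker decline", {
  dir <- file.path(tempdir(), "fix_tc")
  sim <- make_fixture("time_course", dir, seed = 4)
  ds <- sim$dataset
  mg <- sim$truth$marker_genes
  expect_true(length(mg) > 0)
  days <- sort(unique(ds$continuous$day))
  med_by_day <- sapply(days, function(d) {
    mean(sim$truth$log_mean[ds$continuous$day == d, mg])
  })
  expect_true(all(diff(med_by_day) < 0))
})

test_that("3D stack carries section z and z-decaying effects", {
  dir <- file.path(tempdir(), "fix_3d")
  sim <- make_fixture("stack3d", dir, seed = 4)
  ds <- sim$dataset
  expect_equal(ncol(ds$coords), 3)
  expect_setequal(unique(ds$coords[, 3]), c(0.4, 0.8, 2.0, 3.2))
  ## all perturbed spots sit in section 1; mean effect weight decays in z
  expect_true(all(ds$coords[ds$perturbation == "PT", 3] == 0.4))
  w_by_z <- sapply(c(0.4, 0.8, 2.0, 3.2), function(z) {
    mean(sim$truth$decay[ds$coords[, 3] == z, "PT"])
  })
  expect_true(all(diff(w_by_z) < 0))
})
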