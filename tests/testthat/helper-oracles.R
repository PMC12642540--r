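# Independent brute-force oracles used to pin down the package's
# metric and model computations.

# energy distance via explicit double loops
brute_e_distance <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- nrow(Y)
  s_xy <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    s_xy <- s_xy + sqrt(sum((X[i, ] - Y[j, ])^2))
  s_xx <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s_xx <- s_xx + sqrt(sum((X[i, ] - X[j, ])^2))
  s_yy <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    s_yy <- s_yy + sqrt(sum((Y[i, ] - Y[j, ])^2))
  2 * s_xy / (n * m) - s_xx / n^2 - s_yy / m^2
}

brute_r2 <- function(x, y) 1 - sum((y - x)^2) / sum((y - mean(y))^2)
brute_pcc <- function(x, y) {
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
brute_mae <- function(x, y) sum(abs(y - x)) / length(x)

# exact heteroscedastic GP regression posterior (dense, no inducing
# approximation): f | y ~ GP with observation noise variances s2
exact_gp_posterior <- function(K_train, K_cross, K_test_diag, y, s2) {
  A <- K_train + diag(s2)
  Ainv_y <- solve(A, y)
  mean <- K_cross %*% Ainv_y
  V <- solve(A, t(K_cross))
  var <- K_test_diag - rowSums(t(V) * K_cross)
  list(mean = as.numeric(mean), var = as.numeric(var))
}

# tiny standard dataset constructors
tiny_dataset <- function(n = 30, g = 12, seed = 7) {
  sim <- simulate_spatial(sim_config(
    n_spots = n, n_genes = g,
    perturbations = list(KO = list(n_affected = 4, lfc = 1, decay_scale = 4,
                                   patch_center = NULL, patch_radius = 4)),
    seed = seed))
  sim
}
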