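# The study-scale fixture shared by the calibration tests: a 500-spot,
# 200-gene square lattice with one perturbation patch (Cauchy GP scale
# 10, NB dispersion 2, log-normal libraries), a 10% spot holdout, and
# one model trained on the remaining 90% with the default
# configuration. Built once per test run.

get_study_model <- function() {
  if (!is.null(.model_cache$study)) return(.model_cache$study)
  sim <- simulate_spatial(sim_config(seed = 11))
  ds <- sim$dataset
  n <- nrow(ds$counts)
  set.seed(77)
  holdout <- sort(sample(n, round(0.1 * n)))
  keep <- setdiff(seq_len(n), holdout)
  cfg <- nichegp_config(seed = 2)
  model <- train_nichegp(subset_spots(ds, keep), cfg)
  .model_cache$study <- list(model = model, sim = sim,
                             holdout = holdout, keep = keep)
  .model_cache$study
}
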