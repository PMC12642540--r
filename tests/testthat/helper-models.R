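# Shared trained models, built once per test run (lazily) and reused
# across test files.

.model_cache <- new.env(parent = emptyenv())

# small two-state model for counterfactual / benchmark unit tests
get_tiny_model <- function() {
  if (!is.null(.model_cache$tiny)) return(.model_cache$tiny)
  sim <- simulate_spatial(sim_config(
    n_spots = 200, n_genes = 40,
    gp_loading_sd = 0.7, library_meanlog = log(5000),
    perturbations = list(KO = list(n_affected = 8, lfc = 1.2, decay_scale = 4,
                                   patch_center = c(6, 6), patch_radius = 3)),
    seed = 31))
  cfg <- nichegp_config(max_epochs = 300, embed_dim = 32,
                        enc_widths = c(48, 32), dec_widths = 48,
                        batch_size = 64, min_steps = 10^9, seed = 5)
  model <- train_nichegp(sim$dataset, cfg)
  .model_cache$tiny <- list(model = model, sim = sim)
  .model_cache$tiny
}

# two-slide model for slide-separation checks
get_two_slide_model <- function() {
  if (!is.null(.model_cache$two_slide)) return(.model_cache$two_slide)
  sim <- simulate_spatial(sim_config(
    n_spots = 100, n_genes = 30, n_slides = 2, batch_effect = 0.2,
    perturbations = list(KO = list(n_affected = 6, lfc = 1.2, decay_scale = 4,
                                   patch_center = c(10, 10), patch_radius = 3)),
    seed = 41))
  cfg <- nichegp_config(max_epochs = 80, embed_dim = 16,
                        enc_widths = c(32, 16), dec_widths = 32,
                        batch_size = 128, patience = 10^6, seed = 6)
  model <- train_nichegp(sim$dataset, cfg)
  .model_cache$two_slide <- list(model = model, sim = sim)
  .model_cache$two_slide
}
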