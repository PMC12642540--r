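# nichegp

Counterfactual prediction for spatial perturbation transcriptomics with
a niche-aware Gaussian-process variational autoencoder.

## The problem

Sequencing-based spatial transcriptomics destroys the tissue it
measures, so no spot is ever observed both with and without a
perturbation: predicting post-perturbation expression (rGEX) is a
counterfactual problem. Responses also depend on the niche — the state
of a spot's spatial neighbourhood — through which perturbation effects
propagate. `nichegp` is for computational biologists who want to ask
"what would this tissue region look like under knockout X / at day 50 /
with this patch moved elsewhere?" from a single spot-level experiment
(Visium-style counts, coordinates, and per-spot condition labels).

## The model

Each spot's expression profile is disentangled into learnable
embeddings: a free per-spot *basal* code `e_s` (latent optimization,
Gaussian-noise regularized, L2 penalized), plus codebook rows for its
perturbation state `e_p`, disease/region state `e_d`, slide, and
continuous covariates. The concatenated embedding is encoded into a
latent vector that splits into

- a **spatial block** with a Gaussian-process prior,
  `z_GP ~ GP(0, k_p)`, where
  `k_p(s_a, s_b) = 1 / (1 + Σ_i (s_ia − s_ib)² / l_ip)` is an
  anisotropic Cauchy kernel with learnable scales (and an optional
  learnable per-spot cutoff mask
  `k · sigmoid(−τ(k − (c_a + c_b)/2))`), approximated with inducing
  points on a fixed grid; and
- a **non-spatial block** `z_G ~ N(0, I)`.

A decoder maps latent draws to negative-binomial parameters
`μ = exp(h_μ)`, `θ = exp(softplus(h_θ))`, and counts are modelled as
`NB(l_k · μ, θ)` with size factors `l_k = library_k / median library`.
Training maximizes the ELBO with a learnable KL weight β steered toward
a target KL, plus the basal L2 penalty, using AdamW.

Counterfactuals are embedding edits: `swap_perturbation()` replaces a
spot's perturbation row and re-runs the generative path (the GP
posterior is re-solved, so effects propagate to neighbours, never across
slides); `impute_with_attributes()` / `impute_blind()` predict unseen
coordinates from neighbour-averaged embeddings and the GP posterior;
`enhance_resolution()`, `fill_region()`, `edit_niche()` and
`predict_3d()` compose these into sub-spot mapping, gap filling, niche
editing and serial-section propagation. A benchmark harness provides
energy distance, R², PCC, MAE, rank scores, kNN-SP / kNN-GEX baselines,
masking-based imputation evaluation and predictive-interval coverage.

## Worked example

```r
library(nichegp)

## simulate a 500-spot, 200-gene slide with one knockout patch whose
## effect decays spatially (ground truth retained)
sim <- simulate_spatial(sim_config(seed = 11))
ds  <- sim$dataset
ds
#> spatial_dataset: 500 spots x 200 genes (2D coordinates)
#>   perturbation states: control, KO
#>   disease states: core, periphery, normal
#>   normalized: FALSE

## train with the default configuration
model <- train_nichegp(ds, nichegp_config(seed = 2))
model
#> nichegp_model: 500 spots x 200 genes, single_kernel mode
#>   kernel scales: 10.686/10.655
#>   trained 1450 epochs, best val loss 620.079, beta 1.893

## counterfactually knock out the most distant control spots
ctrl <- which(ds$perturbation == "control")[1:20]
base <- predict_mean(model, spots = ctrl, seed = 4)
ko   <- swap_perturbation(model, ctrl, list(perturbation = "KO"),
                          predict_spots = ctrl, seed = 4)
shift <- colMeans(log1p(ko$mean)) - colMeans(log1p(base$mean))
eff <- which(sim$truth$effects$KO != 0)
round(score_pcc(shift[eff], sim$truth$effects$KO[eff]), 2)
#> [1] 0.91
mean(sign(shift[eff]) == sign(sim$truth$effects$KO[eff]))
#> [1] 1
```

The learned kernel scales sit near the simulated truth (10), and the
predicted counterfactual shift recovers the injected 20-gene
log-fold-change pattern: correlation 0.91 over the effect genes with
every direction correct. `predict_mean(..., intervals = TRUE)` adds
per-spot-per-gene NB predictive intervals (empirical quantiles over 20
posterior draws).

A thin command-line dispatcher over the same functions ships in
`inst/cli/nichegp.R` (`simulate`, `prep`, `train`, `predict`, `impute`
subcommands).

## Vignette

`vignettes/nichegp-methods.Rmd` documents the model, its assumptions,
the tunable parameters, the synthetic-data generator and its
limitations, the optimization conventions, and degenerate-input
handling.
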