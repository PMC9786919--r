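# Small shared simulation configurations; built in code, no fixture files.

tiny_config <- function(seed = 1L, ...) {
  simulation_config(species = default_species_table()[c(1, 2, 4, 7, 9), ],
                    n_per_species_site = 4, n_water_per_site = 3,
                    n_baseline_per_site = 8, seed = seed, ...)
}

# the recovery design: 3 sites x 8 species x 15 individuals
recovery_config <- function(beta_tp, seed) {
  simulation_config(species = default_species_table()[1:8, ],
                    beta_tp = beta_tp, lambda_blank = 0.25,
                    sigma_species = 0.5, n_per_species_site = 15,
                    seed = seed)
}

fit_digestive <- function(sim, blank_model, seed = 1L, iterations = 2000,
                          thin = 1) {
  dig <- sim$samples[sim$samples$sample_type == "digestive", ]
  md <- model_data("digestive_tract", dig, sim$isotopes, sim$baselines)
  spec <- model_spec("digestive_tract", iterations = iterations, thin = thin)
  suppressWarnings(sample_posterior(spec, md, blank_model, seed = seed))
}
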