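# mpfoodweb

Hierarchical Bayesian analysis of microplastic (MP) particle counts in
coastal marine food webs, with a probabilistic correction for background
laboratory contamination.

Counting studies of MPs face two coupled problems. First, procedural blanks
are rarely empty: some contamination enters every sample during processing,
and subtracting a blank mean deterministically (or censoring counts below a
limit of detection) destroys information exactly where concentrations are
low. Second, relating concentrations to trophic ecology requires trophic
positions that carry their own baseline and measurement uncertainty. This
package implements both layers jointly, for the six model forms used in
food-web MP surveys (seawater tows and jar grabs, digestive tracts, fish
livers, prey-to-predator transfer, and gut-fullness contrasts), together
with a random-forest stage that assigns synthetic/natural labels to
particles whose chemical identity could not be confirmed by spectroscopy,
and a synthetic-data generator with recorded ground truth for
parameter-recovery studies.

## The model

Observed counts are Poisson with additive contamination:

```
P_observed ~ Poisson(lambda_observed),   lambda_observed = lambda_sample + lambda_blanks
log lambda_sample = L_j
```

where `lambda_blanks` is the mean MP count of the procedural blanks run
alongside each kind of sample and `L_j` is the linear predictor of the model
form `j` — e.g. `L_digestive = alpha_species + beta_TP[site] * TP_i +
gamma_site`, with species as a random intercept (`alpha_species ~ Normal(0,
sigma_species)`, `sigma_species ~ Exponential(1)`) and weakly regularizing
`Normal(0, 1)` priors on the fixed effects (`Normal(0, 10)` for the
water-sample intercepts). Offsets carry tow volume (L) or tissue mass (g).

Trophic position enters through a scaled (saturating) enrichment model,
anchored at mussels as the trophic-level-2 baseline consumer:

```
TP_i = [log(d15N_lim - d15N_base) - log(d15N_lim - d15N_i)] / k + 2
```

with `k = 0.315` and `d15N_lim = 21.926` permil. The site baseline gets a
moment-matched gamma prior (`alpha = mu^2/sigma^2`, `beta = mu/sigma^2` from
the site's mussel delta15N mean and SD), and each specimen's true delta15N a
`Normal(observed, 0.052)` measurement-error prior. Posteriors are sampled by
a blockwise adaptive Metropolis sampler written for this joint density, with
Gelman–Rubin R-hat (threshold 1.01) on every scalar parameter.

Derived metrics: bioaccumulation factors `BAF = C_a / C_w` (particles per kg
animal over particles per L seawater), the trophic magnification factor
`TMF = exp(beta_TP)` (TMF < 1 indicates trophic dilution), species-by-site
concentration tables, and predator daily-intake bounds from body-mass ration
fractions.

## Worked example

```r
library(mpfoodweb)

## 1. a synthetic three-site food web with known ground truth
cfg <- simulation_config(n_per_species_site = 10, seed = 42)
sim <- simulate_foodweb(cfg)
particles <- simulate_particle_table(sim)

## 2. classify the particles that lack a spectroscopy label
labelled <- particles[particles$label != "unknown", ]
clf <- train_particle_classifier(labelled, n_trees = 1000, vars_per_split = 2,
                                 seed = 1)
round(unlist(clf$report$oob[c("sensitivity", "specificity", "accuracy")]), 3)
#> sensitivity specificity    accuracy
#>       0.840       0.796       0.820
particles <- classify_unknowns(clf, particles)

## 3. blank rates and the blank-corrected digestive-tract model
blanks <- blank_rate(sim$blanks)
dig <- sim$samples[sim$samples$sample_type == "digestive", ]
fit <- sample_posterior(
  model_spec("digestive_tract", iterations = 2000, thin = 1),
  model_data("digestive_tract", dig, sim$isotopes, sim$baselines),
  blanks, seed = 1)
fit
#> Blank-corrected Poisson model fit ('digestive_tract')
#>   chains 3, iterations 2000 (burn-in 500, thin 1)
#>   270 observations, max R-hat 1.0084

## 4. trophic magnification factor from the fitted slopes
trophic_magnification_factor(parameter_draws(fit, "^beta_tp\\["))
#> TMF 0.85 (95% CI 0.43-1.47) -- trophic dilution

## 5. per-species posterior predictive concentrations (particles per
##    individual, TP held at each species' mean, pooled across sites)
pred <- posterior_predict(fit, make_prediction_grid(fit, "species"),
                          level = "species")
head(pred[order(pred$mean), c("species", "mean", "lo95", "hi95")], 4)
#>                   species      mean       lo95      hi95
#> 3         copper_rockfish 0.2998300 0.03654119 0.9362355
#> 2 california_sea_cucumber 0.3667947 0.06629930 1.0170204
#> 1             blue_mussel 0.3671009 0.06195858 1.0100137
#> 8             manila_clam 0.4746578 0.08831094 1.3057543
```

The classifier's out-of-bag accuracy (0.82) sits just above the generator's
expert-concordance setting of 0.79 because shape/colour/length carry a mild
additional signal. The generator's default digestive-tract slope is zero, so
the fitted TMF interval comfortably covers 1 (no biomagnification), and the
per-species predictive means land below one particle per individual, on the
scale the blank correction is designed for.

The full `simulate -> classify -> trophic -> fit -> metrics` chain, with CSV
and JSON artifacts and a run manifest, is available as
`run_pipeline(list(simulate = cfg, seed = 1, outdir = "out"))`.

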