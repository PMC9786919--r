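---
title: "Blank-corrected hierarchical models for microplastics in food webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blank-corrected hierarchical models for microplastics in food webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microplastic (MP) surveys count particles in water samples and animal
tissues. Two features of such data defeat ordinary count regression. First,
background contamination: procedural blanks processed alongside the samples
are rarely empty, and the common remedies — subtracting the blank mean from
each count, or zeroing counts below a limit of detection — are deterministic
operations on integer data whose concentrations are often below one particle
per sample, so they discard most of the signal. Second, the ecological
covariate of interest, trophic position, is itself an estimate with baseline
and instrument uncertainty that should propagate into the count model rather
than being plugged in.

`mpfoodweb` treats both in one hierarchical Bayesian model. The key
observation-layer device is that the sum of two Poisson variables is
Poisson, so contamination can be modelled additively:

$$P_{\mathrm{obs}} \sim \mathrm{Poisson}(\lambda_{\mathrm{sample}} +
\lambda_{\mathrm{blanks}}), \qquad
\log \lambda_{\mathrm{sample}} = L_j,$$

with $\lambda_{\mathrm{blanks}}$ the arithmetic mean of the blank counts
keyed to each kind of sample (`blank_rate()`), and $L_j$ one of six linear
predictors (`model_spec()`): site intercepts for tow and jar seawater
samples (with a log-volume offset for tows), species random intercepts plus
per-site trophic-position slopes plus site effects for digestive tracts and
livers (log tissue-mass offset for livers), species and site effects for
prey-to-predator transfer (log dry-mass offset), and a stomach-fullness
contrast for the rockfish gut model.

## The trophic layer

Trophic position comes from nitrogen stable isotopes through a scaled
enrichment model in which the per-step discrimination factor shrinks as
$\delta^{15}N$ approaches a saturating limit:

$$TP_i = \frac{\log(\delta^{15}N_{lim} - \delta^{15}N_{base}) -
\log(\delta^{15}N_{lim} - \delta^{15}N_i)}{k} + 2 .$$

Defaults are $k = 0.315$ and $\delta^{15}N_{lim} = 21.926$ permil, from the
meta-analytic estimates for marine food webs; mussels anchor the baseline at
trophic level 2. Uncertainty enters twice:

* the site baseline $\delta^{15}N_{base}$ has a gamma prior moment-matched
  to the site's mussel values, $\alpha = \mu^2/\sigma^2$, $\beta =
  \mu/\sigma^2$ (`fit_gamma_baseline()`, sample SD with the $n-1$
  convention);
* each specimen's true $\delta^{15}N$ is latent with a
  $\mathrm{Normal}(\delta^{15}N_{\mathrm{sample}}, 0.052)$ prior, 0.052
  permil being the replicate SD of reference-standard tissue run alongside
  the samples. The layer lives inside the model; the data are never
  pre-jittered.

For fish, liver is systematically less enriched than muscle, so the
specimen value is the arithmetic mean of the two tissues; if one tissue is
missing the other is used and flagged (`fish_composite_d15n()`).

**Logarithm base.** The source literature writes the TP equation with an
unqualified "log". The package defaults to base 10 and exposes the base as a
parameter of `trophic_params()` (natural log via `log_base = exp(1)`); every
object that depends on it carries the parameter set, and the synthetic
generator inverts the equation with the same base, so the package is
self-consistent under either choice. Note that the saturating-exponential
derivation of the scaled estimator, in which $k$ arises as
$-\ln(1 - \beta_1)$ of the discrimination regression, reads most naturally
in natural log; users matching published point estimates should check which
base reproduces them and set it explicitly.

## Priors and their scale convention

`Normal(0, 10)` for water-sample intercepts and `Normal(0, 1)` for all
animal-model fixed effects, with the second argument read as the **standard
deviation**: the animal models are described as more regularizing than the
water models, which is only true under the SD reading. Species intercepts
are `Normal(0, sigma_species)` with `sigma_species ~ Exponential(1)`. The
trophic-position slope `beta_tp` is a separate coefficient per site (a
pooled version for magnification summaries is obtained by pooling the
per-site draws; see below). Site and gut-fullness effects get one
coefficient per level rather than reference coding — the proper priors make
this identifiable — except that a single-site dataset fixes the site effect
at 0, since a lone free intercept level would be pure prior noise.

## Sampling and convergence

The joint density (`joint_logdensity()`) is sampled by a blockwise adaptive
random-walk Metropolis sampler (`sample_posterior()`). Within each block
(site intercepts; site effects; species intercepts; per-site slopes;
fullness effects; site baselines; latent specimen $\delta^{15}N$) the
component full conditionals are mutually independent given the rest of the
state, so all components are proposed at once and accepted componentwise.
Two ingredients matter for mixing:

* **Ridge moves.** The species-intercept mean, the site effects, and the
  slopes are weakly identified against one another (trophic position varies
  mostly *across* species). The sampler therefore adds translation moves
  along the confounded directions: a likelihood-invariant exchange between
  species intercepts and site effects, a common slope shift compensated
  through the species intercepts at their mean trophic positions, and
  per-site slope shifts compensated through the site effects. The
  translation directions depend only on state blocks the move does not
  update, so the proposals remain symmetric and the algorithm is valid
  Metropolis.
* **Adaptation.** Proposal scales adapt toward a 0.44 acceptance rate in
  batches of 50 iterations during burn-in only, and are frozen afterwards,
  preserving detailed balance for the retained draws.

Initial values are drawn from the priors and redrawn (up to 10 times) if the
joint density is not finite. Three chains are run by default; per-form
iteration defaults are 10000/500/5 (tow), 2000/500/1 (jar), 7000/500/2
(digestive), 5000/500/1 (liver), 2000/500/1 (transfer) and 5000/500/1
(gut), as iterations/burn-in/thinning. Convergence is summarised by the
Gelman–Rubin statistic
$\hat R = \sqrt{(\tfrac{n-1}{n} W + \tfrac{B}{n}) / W}$ for every scalar
parameter, including the latent isotope values; any $\hat R > 1.01$ produces
a warning advising more iterations, never a silent failure.

Model adequacy is assessed by a posterior-predictive dispersion check
(`dispersion_check()`): replicate counts are simulated from
$\mathrm{Poisson}(\lambda_{\mathrm{sample}} + \lambda_{\mathrm{blanks}})$
draws and the observed variance-to-mean ratio is located within the
replicate distribution. The gut-fullness data are known to be somewhat
heterogeneous (full stomachs are more variable); no overdispersion term is
added — the model is kept as specified and the check reports the tension.

## Posterior prediction and derived metrics

`posterior_predict()` simulates $\lambda_{\mathrm{sample}} = e^{L}$ over a
covariate grid — the blank term is excluded, since predictions are of the
true rate — and reports the mean with nested central 25/50/75/95%
intervals. `make_prediction_grid()` builds the three standard designs:
randomized site-by-species-by-TP combinations pooled to site-level curves
(TP over 1–6 for digestive tracts, 1–4.5 for livers), per-species summaries
holding TP at the species' mean, and the fullness contrast. The gut model's
grid covers species, site and fullness only, matching the terms that appear
in its linear predictor.

Derived metrics follow the definitions used in field studies:

* `bioaccumulation_factor()`: $BAF = C_a / C_w$, with $C_a$ the
  posterior-mean animal rate per kg wet body mass and $C_w$ the
  posterior-mean jar-sample seawater rate per L. The literal definition uses
  $\lambda_{\mathrm{observed}}$ (it includes the blank term); a
  `use = "lambda_sample"` switch gives the blank-free version, and the
  choice is recorded in the output. Both site-matched and pooled seawater
  denominators are available, because near-zero site-specific jar posteriors
  make site-matched BAFs unstable.
* `trophic_magnification_factor()`: $TMF = e^{\beta_{TP}}$, draw by draw;
  per-site slope draws are pooled by concatenation (the "across all sites"
  summary), with a per-site table attached. The liver model's offset is wet
  tissue mass while magnification is conventionally quoted per dry mass; the
  slope is unit-free, so the TMF is unaffected, but the per-gram intercepts
  are not comparable across the two conventions.
* `species_site_summary()`: posterior-mean TP and particles per individual,
  per g wet and per g dry weight, with ranges, per species and site.
* `rockfish_daily_intake()`: ration fraction × body mass × prey
  concentration, evaluated at the default ration range 0.5%–3.7% of body
  mass per day.

## What the synthetic generator emulates — and what it does not

`simulate_foodweb()` inverts the generative model: mussel baselines are
normal per site; each individual's biological $\delta^{15}N$ is obtained by
inverting the scaled TP equation at the species' true trophic position
(plus a within-species spread), so the trophic module can recover TP
exactly when the instrument SD is set to zero; counts are Poisson with the
configured log-linear structure plus the blank rate; blanks are Poisson;
particle features (shape, colour, lognormal lengths truncated to the
100–5000 µm detection window, a 150 µm / 1 mm size fractionation) are drawn
per class with an expert guess that agrees with the truth at the configured
concordance (default 0.79) and spectroscopy labels on a configured fraction
(default 0.69). Rockfish stomachs carry pooled prey with Poisson MP counts
(default 0.55 per stomach) and a log-additive gut-fullness effect.

Defaults were fixed once to resemble a three-site coastal survey: site
effects at the logs of 0.65/0.33/1.24 particles per individual, no
digestive-tract trophic trend, a liver slope of $\log 0.53$ (trophic
dilution), blank contamination of 0.24 particles per sample, mussel
baselines of 9–10 permil with one more-variable site. The within-species
biological $\delta^{15}N$ spread is not identified by any of the model
layers and is exposed as a free parameter (default 0.25 permil, a typical
within-species spread).

The generator does **not** emulate: spatial or oceanographic structure
within sites, particle spectra or their failure modes (unidentifiable
particles are produced by thinning labels at random, not by modelling
fluorescence or burning), particle fragmentation, overdispersed or
zero-inflated counts, or diet composition. Passing recovery tests therefore
demonstrates that the estimation machinery is calibrated *under the model's
own assumptions*; it cannot certify robustness to overdispersion or
size-selective detection in real data.

## Particle classification

`train_particle_classifier()` fits a random forest (default 1000 trees, two
variables per split) to spectroscopy-labelled particles, with the expert's
binary guess, sample type, size fraction, shape, colour and length as
predictors. Performance is reported both out-of-bag and by resubstitution:
published "during fitting" figures do not say which convention they use, so
both are exposed, and OOB — the honest estimate — is the default summary.
Unknown particles receive the majority vote; exact ties go to "natural",
the conservative direction for contamination claims (configurable). Unseen
factor levels at prediction time are an error, not a silent drop.
`aggregate_sample_counts()` pools synthetic labels across size fractions per
sample, emitting explicit zeros for particle-free samples, and its totals
are conserved by construction.

## Numerical choices and degenerate inputs

* Specimens with $\delta^{15}N \ge \delta^{15}N_{lim} - 10^{-6}$ are
  rejected with an error rather than clamped; the scaled TP estimator is
  infinite there and a clamped value would silently distort the slope.
* `poisson_blank_loglik()` returns $-\infty$ (not an error) for a positive
  count with total rate zero — the correct support statement inside the
  sampler.
* Blank rates are plug-in constants (the blank-count mean per key),
  matching the definition of the correction; the per-run `blank_key` lets
  users stratify blanks per processing run instead of per sample type.
* All counts are stored as integers end to end; concentrations are computed
  only at reporting time. Units are fixed: volumes L, tissue masses g, body
  masses kg, lengths µm.
* The pipeline expands one global seed deterministically into per-stage
  seeds, so a single integer reproduces every artifact; the run manifest
  records seeds, settings, R-hat maxima and file checksums.

## Problem sizes in the test suite

The suite exercises recovery at 3 sites × 8 species × 15 individuals with
blank contamination 0.25 and species-intercept SD 0.5, at reduced MCMC
settings (2000 iterations, 500 burn-in, no thinning, 3 chains), over 20
replicate seeds per slope value ($\beta_{TP} \in \{0, 0.5\}$) — enough for
interval coverage and bias to be measured to a few percent while keeping
the default test run in the minutes range. Convergence at these reduced
settings relies on the ridge moves described above; production analyses
should use the per-form default iteration counts.

## Known limitations

* The Poisson observation layer is deliberate (it makes the additive blank
  correction exact) but cannot absorb overdispersion; the dispersion check
  will flag it, and a negative-binomial variant is out of scope.
* Site-matched BAFs are unstable when a site's seawater posterior is near
  zero; the pooled-denominator option is provided for that reason.
* The random-forest stage inherits the biases of the expert guess: when
  concordance is the only signal, classifier accuracy is bounded by it.
* The scaled-TP log base is a genuine ambiguity of the source formula (see
  above); results that depend on absolute TP values should state the base.
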