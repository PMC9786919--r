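## The six blank-corrected hierarchical Poisson model forms and their joint
## posterior density. Uncertainty is layered: a gamma prior on the site
## baseline delta15N, a normal measurement-error prior on each specimen's true
## delta15N, the scaled trophic-position transform, a log-linear Poisson model
## with offsets and species random intercepts, and additive blank
## contamination in the observation layer.

.model_forms <- c("seawater_tow", "seawater_jar", "digestive_tract", "liver",
                  "transfer", "gut_fullness")
## which layers each form carries
.form_has <- function(form) {
  list(
    tp      = form %in% c("digestive_tract", "liver"),
    species = form %in% c("digestive_tract", "liver", "transfer",
                          "gut_fullness"),
    site_fixed = form %in% c("digestive_tract", "liver", "transfer",
                             "gut_fullness"),
    site_intercept = form %in% c("seawater_tow", "seawater_jar"),
    gut     = form == "gut_fullness",
    offset  = form %in% c("seawater_tow", "liver", "transfer"))
}

.default_mcmc <- list(
  seawater_tow    = c(iterations = 10000L, burnin = 500L, thin = 5L),
  seawater_jar    = c(iterations = 2000L,  burnin = 500L, thin = 1L),
  digestive_tract = c(iterations = 7000L,  burnin = 500L, thin = 2L),
  liver           = c(iterations = 5000L,  burnin = 500L, thin = 1L),
  transfer        = c(iterations = 2000L,  burnin = 500L, thin = 1L),
  gut_fullness    = c(iterations = 5000L,  burnin = 500L, thin = 1L))

#' Specify one of the six count models
#'
#' Linear predictors (log scale, `L = log lambda_sample`):
#' \itemize{
#' \item `seawater_tow`: `log V + alpha_site`
#' \item `seawater_jar`: `alpha_site` (1-L jars)
#' \item `digestive_tract`: `alpha_species + beta_tp[site] * TP + gamma_site`
#' \item `liver`: `log W + alpha_species + beta_tp[site] * TP + gamma_site`
#' \item `transfer`: `log W + alpha_species + gamma_site`
#' \item `gut_fullness`: `alpha_gut + gamma_site + alpha_species`
#' }
#' Priors: `alpha_site ~ Normal(0, 10)` for the water models; elsewhere
#' `gamma_site`, `beta_tp`, `alpha_gut ~ Normal(0, 1)` (the second argument is
#' the standard deviation: the animal models are deliberately more
#' regularizing); `alpha_species ~ Normal(0, sigma_species)` with
#' `sigma_species ~ Exponential(1)`. `beta_tp` is a separate slope per site.
#' Site and fullness effects get one coefficient per level (proper priors make
#' this identifiable); with a single site the site effect is fixed at 0.
#'
#' @param form One of the six model forms.
#' @param chains Number of MCMC chains (default 3).
#' @param iterations,burnin,thin MCMC settings; defaults depend on the form
#'   (tow 10000/500/5, jar 2000/500/1, digestive 7000/500/2, liver 5000/500/1,
#'   transfer 2000/500/1, gut 5000/500/1).
#' @param rhat_threshold Convergence warning threshold (default 1.01).
#' @return A `model_spec`.
#' @export
model_spec <- function(form, chains = 3L, iterations = NULL, burnin = NULL,
                       thin = NULL, rhat_threshold = 1.01) {
  form <- match.arg(form, .model_forms)
  d <- .default_mcmc[[form]]
  iterations <- as.integer(iterations %||% d[["iterations"]])
  burnin <- as.integer(burnin %||% d[["burnin"]])
  thin <- as.integer(thin %||% d[["thin"]])
  errs <- character()
  if (chains < 2L) errs <- c(errs, "`chains` must be >= 2")
  if (iterations <= burnin) errs <- c(errs, "`iterations` must exceed `burnin`")
  if (thin < 1L) errs <- c(errs, "`thin` must be >= 1")
  collect_errors(errs, "invalid model_spec")
  structure(list(form = form, chains = as.integer(chains),
                 iterations = iterations, burnin = burnin, thin = thin,
                 rhat_threshold = rhat_threshold,
                 prior_sd_alpha_site = 10, prior_sd_fixed = 1),
            class = "model_spec")
}

#' Assemble model data for a given form
#'
#' Validates and indexes the observation table (and, for the trophic forms,
#' the isotope and mussel-baseline tables) into the structure the density and
#' sampler functions consume.
#'
#' @param form Model form (see [model_spec()]).
#' @param samples Observation table: columns `sample_id`, `count`, `site`, and
#'   per form: `volume_l` (tow), `species` (+ `specimen_id` for trophic
#'   forms), `tissue_ww_g` (liver), `tissue_dw_g` (transfer), `fullness`
#'   (gut), `blank_key`.
#' @param isotopes Isotope table (trophic forms; see [composite_isotopes()]).
#' @param baselines Mussel baseline table with columns `site`, `d15n`
#'   (trophic forms), or a named list of [baseline_prior()] objects.
#' @param measurement_sd Instrument delta15N SD (permil), default 0.052.
#' @param trophic A [trophic_params()] object.
#' @return A `model_data` list.
#' @export
model_data <- function(form, samples, isotopes = NULL, baselines = NULL,
                       measurement_sd = 0.052, trophic = trophic_params()) {
  form <- match.arg(form, .model_forms)
  has <- .form_has(form)
  errs <- character()
  need <- c("sample_id", "count", "site")
  if (has$species) need <- c(need, "species")
  if (has$tp) need <- c(need, "specimen_id")
  if (has$gut) need <- c(need, "fullness")
  if (form == "seawater_tow") need <- c(need, "volume_l")
  if (form == "liver") need <- c(need, "tissue_ww_g")
  if (form == "transfer") need <- c(need, "tissue_dw_g")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0L)
    stop("`samples` missing column(s) for form '", form, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is_count_vector(samples$count)) {
    bad <- which(!(is.finite(samples$count) & samples$count >= 0 &
                     samples$count == round(samples$count)))
    errs <- c(errs, paste0("`count` must be non-negative integers (rows ",
                           paste(utils::head(bad, 5L), collapse = ", "), ")"))
  }
  off <- rep(0, nrow(samples))
  if (form == "seawater_tow") {
    if (any(!is.finite(samples$volume_l) | samples$volume_l <= 0))
      errs <- c(errs, "`volume_l` must be positive for every tow")
    else off <- log(samples$volume_l)
  }
  if (form == "liver") {
    if (any(!is.finite(samples$tissue_ww_g) | samples$tissue_ww_g <= 0))
      errs <- c(errs, "`tissue_ww_g` must be positive for every liver sample")
    else off <- log(samples$tissue_ww_g)
  }
  if (form == "transfer") {
    if (any(!is.finite(samples$tissue_dw_g) | samples$tissue_dw_g <= 0))
      errs <- c(errs, "`tissue_dw_g` must be positive for every prey sample")
    else off <- log(samples$tissue_dw_g)
  }
  collect_errors(errs, paste0("invalid data for form '", form, "'"))

  site <- factor(samples$site)
  md <- list(form = form, sample_id = samples$sample_id,
             y = as.integer(samples$count), off = off,
             tissue_ww_g = samples$tissue_ww_g, tissue_dw_g = samples$tissue_dw_g,
             body_ww_kg = samples$body_ww_kg,
             site = site, n_site = nlevels(site),
             blank_key = if ("blank_key" %in% names(samples))
               samples$blank_key else rep("all", nrow(samples)),
             trophic = trophic, measurement_sd = measurement_sd)

  if (has$species) md$species <- factor(samples$species)
  if (has$gut) {
    md$gut <- factor(samples$fullness, levels = c("empty", "full"))
    if (anyNA(md$gut))
      stop("`fullness` must be 'empty' or 'full'", call. = FALSE)
  }

  if (has$tp) {
    if (is.null(isotopes) || is.null(baselines))
      stop("form '", form, "' needs `isotopes` and `baselines`",
           call. = FALSE)
    comp <- composite_isotopes(isotopes)
    i <- match(samples$specimen_id, comp$specimen_id)
    if (anyNA(i))
      stop("no isotope record for specimen(s): ",
           paste(unique(samples$specimen_id[is.na(i)]), collapse = ", "),
           call. = FALSE)
    ## one latent true delta15N per distinct specimen
    spec_ids <- unique(samples$specimen_id)
    j <- match(spec_ids, comp$specimen_id)
    md$specimen_id <- spec_ids
    md$d15n_obs <- comp$d15n[j]
    md$spec_site <- match(
      comp$site[j], levels(site))
    if (anyNA(md$spec_site))
      stop("specimen site not among sample sites", call. = FALSE)
    md$obs_specimen <- match(samples$specimen_id, spec_ids)
    if (is.list(baselines) && !is.data.frame(baselines)) {
      bp <- baselines
    } else {
      bp <- lapply(split(baselines$d15n, baselines$site), fit_gamma_baseline)
      for (s in names(bp)) bp[[s]]$site <- s
    }
    miss_b <- setdiff(levels(site), names(bp))
    if (length(miss_b) > 0L)
      stop("no baseline values for site(s): ",
           paste(miss_b, collapse = ", "), call. = FALSE)
    md$baseline <- bp[levels(site)]
    if (any(md$d15n_obs >= trophic$delta15n_lim - 1e-6))
      stop("specimen delta15N at or above the saturating limit; cannot be ",
           "placed on the trophic scale", call. = FALSE)
  }
  class(md) <- "model_data"
  md
}

#' Evaluate a form's linear predictor
#'
#' Returns `log lambda_sample` for each observation row, given a parameter
#' state. The state is a named list of named vectors: `alpha_site`,
#' `gamma_site`, `alpha_species`, `beta_tp` (per site), `alpha_gut`
#' (`empty`/`full`); trophic position `tp` is supplied per row (already
#' transformed from delta15N).
#'
#' @param form Model form.
#' @param covariates Data frame (or list) with the columns the form needs:
#'   `site`, and per form `volume_l`, `species`, `tp`, `tissue_ww_g`,
#'   `tissue_dw_g`, `fullness`.
#' @param state Parameter state (named list of named numeric vectors).
#' @return Numeric vector of log rates.
#' @export
linear_predictor <- function(form, covariates, state) {
  form <- match.arg(form, .model_forms)
  cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
  pick <- function(par, keys) {
    v <- state[[par]]
    if (is.null(v)) stop("state missing `", par, "` for form '", form, "'",
                         call. = FALSE)
    i <- match(as.character(keys), names(v))
    if (anyNA(i)) stop("state `", par, "` missing level(s): ",
                       paste(unique(keys[is.na(i)]), collapse = ", "),
                       call. = FALSE)
    unname(v[i])
  }
  need_col <- function(col) {
    if (is.null(cv[[col]]))
      stop("covariates missing `", col, "` for form '", form, "'",
           call. = FALSE)
    cv[[col]]
  }
  switch(form,
    seawater_tow = log(need_col("volume_l")) + pick("alpha_site", cv$site),
    seawater_jar = pick("alpha_site", need_col("site")),
    digestive_tract = pick("alpha_species", need_col("species")) +
      pick("beta_tp", need_col("site")) * need_col("tp") +
      pick("gamma_site", cv$site),
    liver = log(need_col("tissue_ww_g")) +
      pick("alpha_species", need_col("species")) +
      pick("beta_tp", need_col("site")) * need_col("tp") +
      pick("gamma_site", cv$site),
    transfer = log(need_col("tissue_dw_g")) +
      pick("alpha_species", need_col("species")) +
      pick("gamma_site", need_col("site")),
    gut_fullness = pick("alpha_gut", need_col("fullness")) +
      pick("gamma_site", need_col("site")) +
      pick("alpha_species", cv$species))
}

## covariate frame for linear_predictor() from model_data + latent TP
.covariates_from_md <- function(md, tp_obs = NULL) {
  cv <- data.frame(site = as.character(md$site), stringsAsFactors = FALSE)
  if (!is.null(md$species)) cv$species <- as.character(md$species)
  if (!is.null(md$gut)) cv$fullness <- as.character(md$gut)
  if (md$form == "seawater_tow") cv$volume_l <- exp(md$off)
  if (md$form == "liver") cv$tissue_ww_g <- exp(md$off)
  if (md$form == "transfer") cv$tissue_dw_g <- exp(md$off)
  if (!is.null(tp_obs)) cv$tp <- tp_obs
  cv
}

#' Joint log density of a model's full latent state
#'
#' Sum of the gamma baseline log-priors, the delta15N measurement-error
#' log-priors, the regression-parameter log-priors, the species random-effect
#' log-priors, the `sigma_species` exponential log-prior, and the
#' blank-corrected Poisson log likelihood. Returns `-Inf` outside the support
#' (non-positive `sigma_species`, baseline outside `(0, delta15n_lim)`, any
#' latent delta15N at or above the limit).
#'
#' @param spec A [model_spec()].
#' @param data A [model_data()] object.
#' @param state Full latent state: the regression vectors of
#'   [linear_predictor()] plus, as required, `sigma_species`, `d15n_base`
#'   (named by site) and `d15n_true` (named by specimen id).
#' @param blank_model A [blank_rate()] model or `NULL` for no correction.
#' @return Scalar log density.
#' @export
joint_logdensity <- function(spec, data, state, blank_model = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "model_data"))
  if (spec$form != data$form) stop("spec/data form mismatch", call. = FALSE)
  has <- .form_has(data$form)
  lp <- 0
  lim <- data$trophic$delta15n_lim

  if (has$site_intercept)
    lp <- lp + sum(dnorm(state$alpha_site, 0, spec$prior_sd_alpha_site,
                         log = TRUE))
  if (has$site_fixed && data$n_site > 1L)
    lp <- lp + sum(dnorm(state$gamma_site, 0, spec$prior_sd_fixed, log = TRUE))
  if (has$tp)
    lp <- lp + sum(dnorm(state$beta_tp, 0, spec$prior_sd_fixed, log = TRUE))
  if (has$gut)
    lp <- lp + sum(dnorm(state$alpha_gut, 0, spec$prior_sd_fixed, log = TRUE))
  if (has$species) {
    sg <- state$sigma_species
    if (is.null(sg) || !is.finite(sg) || sg <= 0) return(-Inf)
    lp <- lp + dexp(sg, 1, log = TRUE) +
      sum(dnorm(state$alpha_species, 0, sg, log = TRUE))
  }

  tp_obs <- NULL
  if (has$tp) {
    base <- state$d15n_base[levels(data$site)]
    dtrue <- state$d15n_true[data$specimen_id]
    if (anyNA(base) || anyNA(dtrue)) stop("state/spec mismatch: missing ",
                                          "d15n_base or d15n_true",
                                          call. = FALSE)
    if (any(base <= 0) || any(base >= lim - 1e-6) ||
        any(dtrue >= lim - 1e-6)) return(-Inf)
    lp <- lp + sum(dgamma(unname(base),
                          shape = vapply(data$baseline, `[[`, 0, "alpha"),
                          rate = vapply(data$baseline, `[[`, 0, "beta"),
                          log = TRUE))
    lp <- lp + sum(dnorm(dtrue, data$d15n_obs, data$measurement_sd,
                         log = TRUE))
    tp <- scaled_trophic_position(dtrue, base[data$spec_site], data$trophic)
    tp_obs <- tp[data$obs_specimen]
  }

  st <- state
  if (has$site_fixed && data$n_site == 1L)
    st$gamma_site <- setNames(0, levels(data$site))  # single site: fixed at 0
  eta <- linear_predictor(data$form, .covariates_from_md(data, tp_obs), st)
  lb <- blank_lambda(blank_model, data$blank_key)
  lp + sum(poisson_blank_loglik(data$y, exp(eta), lb))
}
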