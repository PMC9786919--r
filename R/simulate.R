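## Synthetic food-web data generator. Inverts the generative model the
## analysis assumes -- log-linear Poisson counts with offsets, species random
## intercepts and additive blank contamination; delta15N emitted by inverting
## the scaled trophic-position equation at each species' true trophic
## position -- and records the realized ground truth for recovery studies.

#' Default species pool for the synthetic coastal food web
#'
#' Nine benthic/demersal taxa spanning trophic levels 2.0-3.6: suspension
#' feeders (bivalves), deposit feeders (sea cucumbers), predatory crabs, a sea
#' star, and three fish (livers sampled for fish only). Median body and tissue
#' masses are order-of-magnitude realistic for small coastal individuals.
#'
#' @return Data frame with columns `species`, `tp` (true trophic position),
#'   `guild`, `body_kg`, `gut_ww_g`, `liver_ww_g` (NA for non-fish), `is_fish`.
#' @export
default_species_table <- function() {
  data.frame(
    species = c("blue_mussel", "manila_clam", "california_sea_cucumber",
                "graceful_rock_crab", "dungeness_crab", "leather_star",
                "english_sole", "shiner_surfperch", "copper_rockfish"),
    tp      = c(2.0, 2.1, 2.4, 2.7, 2.8, 3.0, 3.1, 3.2, 3.6),
    guild   = c("suspension", "suspension", "deposit", "predator", "predator",
                "predator", "predator", "planktivore", "predator"),
    body_kg = c(0.001, 0.004, 0.15, 0.08, 0.4, 0.12, 0.15, 0.02, 0.5),
    gut_ww_g = c(0.8, 0.7, 5, 0.8, 2, 3, 1.5, 0.5, 4),
    liver_ww_g = c(NA, NA, NA, NA, NA, NA, 1.2, 0.3, 3),
    is_fish = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic food-web generator
#'
#' Defaults emulate a three-site coastal survey: site intercepts on the count
#' scale near the fitted per-site digestive-tract means (0.65, 0.33, 1.24
#' particles per individual), no trophic trend in digestive tracts, trophic
#' dilution in livers (slope log 0.53), procedural-blank contamination of 0.24
#' synthetic particles per sample, mussel baselines of 9-10 permil with the
#' first site more variable, instrument noise of 0.052 permil, expert/label
#' concordance 0.79 and 69% of particles carrying spectroscopy labels.
#'
#' @param sites Character vector of site labels.
#' @param species Species table as in [default_species_table()].
#' @param baseline_mu,baseline_sd Per-site mussel delta15N mean/SD (permil).
#' @param gamma_site Per-site log-scale offsets for animal count models.
#' @param beta_tp True digestive-tract log-slope per trophic level (scalar or
#'   one per site).
#' @param beta_liver True liver log-slope per trophic level.
#' @param sigma_species SD of species random intercepts (log scale); may be 0
#'   for degenerate checks.
#' @param alpha_tow,alpha_jar Per-site log seawater concentration
#'   (particles per L) for plankton tows and 1-L jar grabs.
#' @param lambda_blank Mean blank (contamination) particles per sample.
#' @param n_per_species_site Individuals per species per site.
#' @param n_water_per_site Tow and jar samples per site (each).
#' @param n_baseline_per_site Mussel baseline isotope measurements per site.
#' @param n_blanks_per_run Procedural blanks per processing run (default 3).
#' @param samples_per_run Samples per processing run (sets run count).
#' @param tow_volume_l Median tow volume (L); jars are 1 L.
#' @param isotope_measurement_sd Instrument delta15N SD (permil), default
#'   0.052.
#' @param isotope_spread Within-species biological delta15N SD (permil) around
#'   the trophic-implied mean; default 0.25.
#' @param particle_features List: `concordance` (expert guess agrees with
#'   truth, default 0.79), `labelled_fraction` (default 0.69), `natural_rate`
#'   (mean natural particles per sample), `natural_rate_blank`, `informative`
#'   (when FALSE, shape/colour/length carry no class signal).
#' @param rockfish List controlling [simulate_rockfish_stomachs()]:
#'   `n_per_site`, `p_full`, `prey_rate` (mean ingested-prey MP count per
#'   stomach), `prey_mass_g`, `gut_rate_empty`, `fullness_effect` (additive,
#'   log scale).
#' @param trophic A [trophic_params()] object.
#' @param seed Integer seed; the single source of randomness.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(
    sites = c("Coles Bay", "Elliot Beach", "Victoria Harbour"),
    species = default_species_table(),
    baseline_mu = c(9.2, 8.8, 10.1),
    baseline_sd = c(1.0, 0.5, 0.5),
    gamma_site = log(c(0.65, 0.33, 1.24)),
    beta_tp = 0,
    beta_liver = log(0.53),
    sigma_species = 0.5,
    alpha_tow = log(c(8.6e-5, 5.6e-5, 3.2e-4)),
    alpha_jar = log(c(1.5, 0.8, 2.0)),
    lambda_blank = 0.24,
    n_per_species_site = 15,
    n_water_per_site = 5,
    n_baseline_per_site = 12,
    n_blanks_per_run = 3,
    samples_per_run = 20,
    tow_volume_l = 6e4,
    isotope_measurement_sd = 0.052,
    isotope_spread = 0.25,
    particle_features = list(),
    rockfish = list(),
    trophic = trophic_params(),
    seed = 1L) {

  pf <- utils::modifyList(list(concordance = 0.79, labelled_fraction = 0.69,
                               natural_rate = 1.0, natural_rate_blank = 0.5,
                               informative = TRUE,
                               length_meanlog = log(600), length_sdlog = 0.9),
                          particle_features)
  rf <- utils::modifyList(list(n_per_site = 8, p_full = 0.5, prey_rate = 0.55,
                               prey_mass_g = 2, gut_rate_empty = 0.08,
                               fullness_effect = 2.3),
                          rockfish)

  ns <- length(sites)
  if (length(beta_tp) == 1L) beta_tp <- rep(beta_tp, ns)
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(ns >= 1 && !anyDuplicated(sites), "`sites` must be unique labels")
  chk(is.data.frame(species) &&
        all(c("species", "tp", "guild", "body_kg", "gut_ww_g", "is_fish")
            %in% names(species)),
      "`species` must have columns species/tp/guild/body_kg/gut_ww_g/is_fish")
  if (is.data.frame(species) && "tp" %in% names(species))
    chk(all(species$tp >= 1 & species$tp <= 6),
        "`species$tp`: every true trophic position must lie in [1, 6]")
  chk(length(baseline_mu) == ns && all(baseline_mu > 0),
      "`baseline_mu` must be positive, one per site")
  chk(all(baseline_mu < trophic$delta15n_lim),
      "`baseline_mu` must lie below `delta15n_lim`")
  chk(length(baseline_sd) == ns && all(baseline_sd > 0),
      "`baseline_sd` must be positive, one per site")
  chk(length(gamma_site) == ns, "`gamma_site` needs one value per site")
  chk(length(beta_tp) == ns, "`beta_tp` must be scalar or one per site")
  chk(length(alpha_tow) == ns && length(alpha_jar) == ns,
      "`alpha_tow`/`alpha_jar` need one value per site")
  chk(sigma_species >= 0, "`sigma_species` must be >= 0")
  chk(lambda_blank >= 0, "`lambda_blank` must be >= 0")
  chk(isotope_measurement_sd > 0, "`isotope_measurement_sd` must be > 0")
  chk(isotope_spread >= 0, "`isotope_spread` must be >= 0")
  chk(pf$concordance >= 0 && pf$concordance <= 1,
      "`particle_features$concordance` must lie in [0, 1]")
  chk(pf$labelled_fraction >= 0 && pf$labelled_fraction <= 1,
      "`particle_features$labelled_fraction` must lie in [0, 1]")
  chk(n_per_species_site >= 1, "`n_per_species_site` must be >= 1")
  chk(n_blanks_per_run >= 1, "`n_blanks_per_run` must be >= 1")
  chk(tow_volume_l > 0, "`tow_volume_l` must be > 0")
  chk(rf$p_full >= 0 && rf$p_full <= 1, "`rockfish$p_full` must lie in [0,1]")
  chk(rf$prey_rate >= 0, "`rockfish$prey_rate` must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
      "`seed` must be a single integer")
  collect_errors(errs, "invalid simulation_config")

  structure(list(
    sites = sites, species = species, baseline_mu = baseline_mu,
    baseline_sd = baseline_sd, gamma_site = gamma_site, beta_tp = beta_tp,
    beta_liver = beta_liver, sigma_species = sigma_species,
    alpha_tow = alpha_tow, alpha_jar = alpha_jar,
    lambda_blank = lambda_blank, n_per_species_site = n_per_species_site,
    n_water_per_site = n_water_per_site,
    n_baseline_per_site = n_baseline_per_site,
    n_blanks_per_run = n_blanks_per_run, samples_per_run = samples_per_run,
    tow_volume_l = tow_volume_l,
    isotope_measurement_sd = isotope_measurement_sd,
    isotope_spread = isotope_spread, particle_features = pf, rockfish = rf,
    trophic = trophic, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate a complete synthetic food-web dataset
#'
#' Draws mussel baselines, per-individual delta15N (inverting the scaled
#' trophic-position equation at the species' true trophic position, plus
#' biological spread and instrument noise), seawater and animal particle
#' counts as Poisson with mean `lambda_sample + lambda_blank`, and procedural
#' blank counts as Poisson(`lambda_blank`). The same seed always reproduces
#' the same tables.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mp_simulation`: `samples`, `isotopes`,
#'   `baselines`, `blanks`, and `truth` (class `synthetic_truth`, the realized
#'   parameters and per-sample true rates).
#' @export
simulate_foodweb <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sites <- config$sites
  sp <- config$species
  ns <- length(sites)
  tp_pars <- config$trophic

  ## mussel baseline measurements (truncated-positive normal)
  baselines <- do.call(rbind, lapply(seq_len(ns), function(s) {
    v <- rnorm(config$n_baseline_per_site, config$baseline_mu[s],
               config$baseline_sd[s])
    while (any(v <= 0))
      v[v <= 0] <- rnorm(sum(v <= 0), config$baseline_mu[s],
                         config$baseline_sd[s])
    data.frame(site = sites[s], mussel_id = sprintf("mus_%d_%02d", s,
                                                    seq_along(v)),
               d15n = v, stringsAsFactors = FALSE)
  }))

  ## species random intercepts
  alpha_species <- rnorm(nrow(sp), 0, config$sigma_species)
  names(alpha_species) <- sp$species

  ## water samples ------------------------------------------------------
  water <- do.call(rbind, lapply(seq_len(ns), function(s) {
    nv <- config$n_water_per_site
    vol <- rlnorm(nv, log(config$tow_volume_l), 0.3)
    lam_tow <- vol * exp(config$alpha_tow[s])
    lam_jar <- rep(exp(config$alpha_jar[s]), nv)
    data.frame(
      sample_id = c(sprintf("tow_%d_%02d", s, seq_len(nv)),
                    sprintf("jar_%d_%02d", s, seq_len(nv))),
      sample_type = rep(c("tow", "jar"), each = nv),
      site = sites[s], species = NA_character_,
      specimen_id = NA_character_,
      volume_l = c(vol, rep(1, nv)),
      tissue_ww_g = NA_real_, tissue_dw_g = NA_real_, body_ww_kg = NA_real_,
      lambda_sample = c(lam_tow, lam_jar),
      stringsAsFactors = FALSE)
  }))

  ## animal specimens ---------------------------------------------------
  grid <- expand.grid(site_i = seq_len(ns), sp_i = seq_len(nrow(sp)),
                      ind = seq_len(config$n_per_species_site))
  m <- nrow(grid)
  spid <- sprintf("spec_%d_%s_%02d", grid$site_i, sp$species[grid$sp_i],
                  grid$ind)
  base_mu_i <- config$baseline_mu[grid$site_i]
  d15n_bio <- delta15n_from_tp(sp$tp[grid$sp_i], base_mu_i, tp_pars) +
    rnorm(m, 0, config$isotope_spread)
  ## biological values must stay below the saturating limit
  d15n_bio <- pmin(d15n_bio, tp_pars$delta15n_lim - 0.5)
  tp_true <- scaled_trophic_position(d15n_bio, base_mu_i, tp_pars)

  body_kg <- rlnorm(m, log(sp$body_kg[grid$sp_i]), 0.3)
  gut_ww <- rlnorm(m, log(sp$gut_ww_g[grid$sp_i]), 0.4)
  gut_dw <- gut_ww * 0.2

  eta_dig <- alpha_species[grid$sp_i] +
    config$beta_tp[grid$site_i] * tp_true + config$gamma_site[grid$site_i]
  dig <- data.frame(
    sample_id = paste0("dig_", spid), sample_type = "digestive",
    site = sites[grid$site_i], species = sp$species[grid$sp_i],
    specimen_id = spid, volume_l = NA_real_,
    tissue_ww_g = gut_ww, tissue_dw_g = gut_dw, body_ww_kg = body_kg,
    lambda_sample = exp(eta_dig), stringsAsFactors = FALSE)

  is_fish_i <- sp$is_fish[grid$sp_i]
  liver <- NULL
  if (any(is_fish_i)) {
    fi <- which(is_fish_i)
    liver_ww <- rlnorm(length(fi), log(sp$liver_ww_g[grid$sp_i[fi]]), 0.4)
    eta_liv <- log(liver_ww) + alpha_species[grid$sp_i[fi]] +
      config$beta_liver * tp_true[fi] + config$gamma_site[grid$site_i[fi]]
    liver <- data.frame(
      sample_id = paste0("liv_", spid[fi]), sample_type = "liver",
      site = sites[grid$site_i[fi]], species = sp$species[grid$sp_i[fi]],
      specimen_id = spid[fi], volume_l = NA_real_,
      tissue_ww_g = liver_ww, tissue_dw_g = liver_ww * 0.25,
      body_ww_kg = body_kg[fi],
      lambda_sample = exp(eta_liv), stringsAsFactors = FALSE)
  }

  samples <- rbind(water, dig, liver)
  samples$count <- rpois(nrow(samples),
                         samples$lambda_sample + config$lambda_blank)
  samples$blank_key <- samples$sample_type

  ## isotope table ------------------------------------------------------
  msd <- config$isotope_measurement_sd
  iso <- vector("list", 2L)
  inv <- !is_fish_i
  iso[[1]] <- data.frame(
    specimen_id = spid[inv], species = sp$species[grid$sp_i[inv]],
    site = sites[grid$site_i[inv]], tissue = "body",
    d13c = rnorm(sum(inv), -18, 1.5),
    d15n = d15n_bio[inv] + rnorm(sum(inv), 0, msd),
    stringsAsFactors = FALSE)
  if (any(is_fish_i)) {
    fi <- which(is_fish_i)
    sep <- 0.4  # liver less enriched than muscle; composite mean preserved
    iso[[2]] <- data.frame(
      specimen_id = rep(spid[fi], 2L),
      species = rep(sp$species[grid$sp_i[fi]], 2L),
      site = rep(sites[grid$site_i[fi]], 2L),
      tissue = rep(c("muscle", "liver"), each = length(fi)),
      d13c = rnorm(2L * length(fi), -18, 1.5),
      d15n = c(d15n_bio[fi] + sep, d15n_bio[fi] - sep) +
        rnorm(2L * length(fi), 0, msd),
      stringsAsFactors = FALSE)
  }
  isotopes <- do.call(rbind, iso)

  ## procedural blanks, n_blanks_per_run per run, keyed by sample type ---
  blanks <- do.call(rbind, lapply(split(samples, samples$sample_type),
                                  function(d) {
    n_runs <- max(1L, ceiling(nrow(d) / config$samples_per_run))
    nb <- n_runs * config$n_blanks_per_run
    data.frame(blank_id = sprintf("blank_%s_%02d", d$sample_type[1L],
                                  seq_len(nb)),
               blank_key = d$sample_type[1L],
               run = rep(seq_len(n_runs), each = config$n_blanks_per_run),
               count = rpois(nb, config$lambda_blank),
               stringsAsFactors = FALSE)
  }))
  rownames(blanks) <- NULL

  truth <- structure(list(
    alpha_species = alpha_species,
    gamma_site = setNames(config$gamma_site, sites),
    beta_tp = setNames(config$beta_tp, sites),
    beta_liver = config$beta_liver,
    alpha_tow = setNames(config$alpha_tow, sites),
    alpha_jar = setNames(config$alpha_jar, sites),
    sigma_species = config$sigma_species,
    lambda_blank = config$lambda_blank,
    lambda = data.frame(sample_id = samples$sample_id,
                        lambda_sample = samples$lambda_sample,
                        lambda_blank = config$lambda_blank,
                        stringsAsFactors = FALSE),
    specimens = data.frame(specimen_id = spid,
                           species = sp$species[grid$sp_i],
                           site = sites[grid$site_i],
                           tp_true = tp_true, d15n_bio = d15n_bio,
                           stringsAsFactors = FALSE),
    seed = config$seed), class = "synthetic_truth")

  samples$lambda_sample <- NULL
  samples <- samples[, c("sample_id", "sample_type", "site", "species",
                         "specimen_id", "count", "volume_l", "tissue_ww_g",
                         "tissue_dw_g", "body_ww_kg", "blank_key")]
  rownames(samples) <- NULL
  rownames(isotopes) <- NULL
  rownames(baselines) <- NULL
  structure(list(samples = samples, isotopes = isotopes,
                 baselines = baselines, blanks = blanks, truth = truth,
                 config = config),
            class = "mp_simulation")
}

## feature emission shared by samples and blanks
.draw_particle_features <- function(n, synthetic, pf) {
  shapes <- c("fiber", "fragment", "film")
  colors <- c("clear", "blue", "black", "red", "brown")
  if (pf$informative) {
    p_shape <- if (synthetic) c(0.94, 0.05, 0.01) else c(0.985, 0.012, 0.003)
    p_col <- if (synthetic) c(0.20, 0.32, 0.23, 0.15, 0.10)
             else c(0.33, 0.15, 0.21, 0.06, 0.25)
    mu_len <- pf$length_meanlog + if (synthetic) 0.25 else 0
  } else {
    p_shape <- c(0.95, 0.04, 0.01)
    p_col <- c(0.25, 0.25, 0.2, 0.15, 0.15)
    mu_len <- pf$length_meanlog
  }
  len <- rlnorm(n, mu_len, pf$length_sdlog)
  bad <- len < 100 | len > 5000
  while (any(bad)) {  # truncation to the 100-5000 um detection window
    len[bad] <- rlnorm(sum(bad), mu_len, pf$length_sdlog)
    bad <- len < 100 | len > 5000
  }
  data.frame(
    shape = sample(shapes, n, replace = TRUE, prob = p_shape),
    color = sample(colors, n, replace = TRUE, prob = p_col),
    length_um = len,
    stringsAsFactors = FALSE)
}

#' Simulate the per-particle feature table
#'
#' Emits one row per counted particle: the synthetic particles of each sample
#' (and blank), plus natural particles at the configured rate. Each particle
#' carries shape, colour, length (lognormal truncated to the 100-5000 um
#' detection window), a size fraction cut at 150 um and 1 mm, an expert guess
#' that agrees with the true class with probability
#' `particle_features$concordance`, and a spectroscopy label for a
#' `labelled_fraction` subset (the rest are `"unknown"`). The ground-truth
#' class is kept in `true_label` for recovery scoring only.
#'
#' @param sim An `mp_simulation` from [simulate_foodweb()], or a list with
#'   elements `samples` and `blanks` in the same schema.
#' @param config The [simulation_config()] used (defaults to `sim$config`).
#' @return Data frame, one row per particle.
#' @export
simulate_particle_table <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 104729L)  # decoupled stream, still seed-determined
  pf <- config$particle_features

  samples <- sim$samples
  blanks <- sim$blanks
  src <- data.frame(
    sample_id = c(samples$sample_id, blanks$blank_id),
    sample_type = c(samples$sample_type, rep("blank", nrow(blanks))),
    n_syn = c(samples$count, blanks$count),
    nat_rate = c(rep(pf$natural_rate, nrow(samples)),
                 rep(pf$natural_rate_blank, nrow(blanks))),
    stringsAsFactors = FALSE)
  src$n_nat <- rpois(nrow(src), src$nat_rate)

  n_syn <- sum(src$n_syn); n_nat <- sum(src$n_nat)
  rows <- data.frame(
    sample_id = c(rep(src$sample_id, src$n_syn), rep(src$sample_id, src$n_nat)),
    sample_type = c(rep(src$sample_type, src$n_syn),
                    rep(src$sample_type, src$n_nat)),
    true_label = rep(c("synthetic", "natural"), c(n_syn, n_nat)),
    stringsAsFactors = FALSE)
  n <- nrow(rows)
  if (n == 0L) {
    return(data.frame(particle_id = character(), sample_id = character(),
                      sample_type = character(), size_fraction = character(),
                      shape = character(), color = character(),
                      length_um = numeric(), expert_guess = character(),
                      label = character(), true_label = character(),
                      stringsAsFactors = FALSE))
  }
  feats <- rbind(.draw_particle_features(n_syn, TRUE, pf),
                 .draw_particle_features(n_nat, FALSE, pf))
  agree <- runif(n) < pf$concordance
  other <- ifelse(rows$true_label == "synthetic", "natural", "synthetic")
  labelled <- runif(n) < pf$labelled_fraction
  out <- data.frame(
    particle_id = sprintf("part_%05d", seq_len(n)),
    sample_id = rows$sample_id, sample_type = rows$sample_type,
    size_fraction = cut(feats$length_um, c(0, 150, 1000, Inf),
                        labels = c("100-150um", "150um-1mm", ">1mm")),
    shape = feats$shape, color = feats$color, length_um = feats$length_um,
    expert_guess = ifelse(agree, rows$true_label, other),
    label = ifelse(labelled, rows$true_label, "unknown"),
    true_label = rows$true_label,
    stringsAsFactors = FALSE)
  out$size_fraction <- as.character(out$size_fraction)
  ## shuffle so particle order carries no class signal
  out <- out[sample.int(n), , drop = FALSE]
  out$particle_id <- sprintf("part_%05d", seq_len(n))
  rownames(out) <- NULL
  out
}

#' Simulate rockfish stomach-content data
#'
#' One row per rockfish: a stomach-fullness flag (full stomachs contain
#' ingested prey on the 1-mm sieve), pooled prey dry mass and prey microplastic
#' count (Poisson at `rockfish$prey_rate` per stomach), and the rockfish's own
#' digestive-tract count drawn with an additive (log-scale) fullness effect:
#' `gut_count ~ Poisson(exp(log(gut_rate_empty) + fullness_effect * full))`.
#'
#' @param config A [simulation_config()]. Rockfish parameters come from
#'   `config$rockfish`.
#' @return Data frame with one row per stomach and the generating rates as
#'   attributes `gut_rate_empty`, `gut_rate_full`, `prey_rate`.
#' @export
simulate_rockfish_stomachs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rf <- config$rockfish
  set.seed(config$seed + 224737L)
  rock_sp <- config$species$species[grepl("rockfish", config$species$species)]
  if (length(rock_sp) == 0L)
    stop("`config$species` contains no rockfish species", call. = FALSE)
  grid <- expand.grid(site = config$sites, species = rock_sp,
                      ind = seq_len(rf$n_per_site),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  full <- runif(n) < rf$p_full
  lam_gut <- exp(log(rf$gut_rate_empty) + rf$fullness_effect * full)
  prey_count <- ifelse(full, rpois(n, rf$prey_rate), 0L)
  prey_mass <- ifelse(full, rlnorm(n, log(rf$prey_mass_g), 0.5), NA_real_)
  out <- data.frame(
    stomach_id = sprintf("stom_%03d", seq_len(n)),
    specimen_id = sprintf("rock_%03d", seq_len(n)),
    species = grid$species, site = grid$site,
    fullness = ifelse(full, "full", "empty"),
    gut_count = rpois(n, lam_gut),
    prey_count = prey_count,
    prey_mass_g = prey_mass,
    stringsAsFactors = FALSE)
  attr(out, "gut_rate_empty") <- rf$gut_rate_empty
  attr(out, "gut_rate_full") <- exp(log(rf$gut_rate_empty) +
                                      rf$fullness_effect)
  attr(out, "prey_rate") <- rf$prey_rate
  out
}

#' Expected count of every generated observable, from the recorded truth
#'
#' Brute-force expectation calculator used to verify that the ground truth
#' fully determines the mean of each emitted count:
#' `E[count] = lambda_sample + lambda_blank`.
#'
#' @param truth A `synthetic_truth` from [simulate_foodweb()].
#' @return Data frame `sample_id`, `expected_count`.
#' @export
expected_counts <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  data.frame(sample_id = truth$lambda$sample_id,
             expected_count = truth$lambda$lambda_sample +
               truth$lambda$lambda_blank,
             stringsAsFactors = FALSE)
}
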