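## Derived exposure metrics: bioaccumulation factors, the trophic
## magnification factor, species x site concentration summaries, and rockfish
## daily-intake bounds.

#' Individual bioaccumulation factors
#'
#' `BAF = C_a / C_w` (L per kg), where `C_a` is the animal's posterior-mean
#' particle count divided by its wet body mass (kg) and `C_w` the
#' posterior-mean seawater concentration (particles per L, jar model). The
#' animal rate is `lambda_observed` by default, the literal definition used
#' in the study (it includes the blank term); set `use = "lambda_sample"` for
#' the blank-free alternative -- the choice is recorded in the output.
#'
#' @param animal_fit `mp_posterior` for the animals (digestive-tract model).
#' @param body_ww_kg Wet body masses (kg), one per animal observation (in the
#'   order of `animal_fit$data$sample_id`).
#' @param water_fit `mp_posterior` for the jar seawater model.
#' @param use Animal rate: `"lambda_observed"` (default) or `"lambda_sample"`.
#' @param water_pooling `"site"` matches each animal to its own site's
#'   seawater posterior mean; `"pooled"` uses the overall mean across sites.
#' @return Data frame: `sample_id`, `site`, `species`, `c_a` (particles per
#'   kg), `c_w` (particles per L), `baf` (L per kg); attribute `rate_used`.
#' @export
bioaccumulation_factor <- function(animal_fit, body_ww_kg, water_fit,
                                   use = c("lambda_observed",
                                           "lambda_sample"),
                                   water_pooling = c("site", "pooled")) {
  stopifnot(inherits(animal_fit, "mp_posterior"),
            inherits(water_fit, "mp_posterior"))
  use <- match.arg(use)
  water_pooling <- match.arg(water_pooling)
  n <- length(animal_fit$data$y)
  if (length(body_ww_kg) != n)
    stop("`body_ww_kg` must supply one mass per animal observation",
         call. = FALSE)
  if (any(!is.finite(body_ww_kg) | body_ww_kg <= 0))
    stop("`body_ww_kg` must be positive", call. = FALSE)

  lam_a <- colMeans(if (use == "lambda_observed")
    lambda_observed_draws(animal_fit) else lambda_sample_draws(animal_fit))
  c_a <- lam_a / body_ww_kg

  lam_w <- colMeans(lambda_observed_draws(water_fit))
  w_site <- as.character(water_fit$data$site)
  cw_by_site <- tapply(lam_w, w_site, mean)  # jars are 1 L: rate = conc per L
  if (water_pooling == "pooled") {
    c_w <- rep(mean(lam_w), n)
  } else {
    a_site <- as.character(animal_fit$data$site)
    miss <- setdiff(unique(a_site), names(cw_by_site))
    if (length(miss) > 0L)
      stop("no seawater posterior for site(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    c_w <- as.numeric(cw_by_site[a_site])
  }
  if (any(c_w <= 0))
    stop("seawater concentration is zero; BAF undefined", call. = FALSE)

  out <- data.frame(sample_id = animal_fit$data$sample_id,
                    site = as.character(animal_fit$data$site),
                    species = as.character(animal_fit$data$species),
                    c_a = c_a, c_w = c_w, baf = c_a / c_w,
                    stringsAsFactors = FALSE)
  attr(out, "rate_used") <- use
  attr(out, "water_pooling") <- water_pooling
  out
}

#' Trophic magnification factor
#'
#' `TMF = exp(beta_TP)` applied draw by draw to the trophic-position slope.
#' Per-site slope draws are pooled by concatenation before exponentiation
#' (the "across all sites" summary); a per-site TMF table is attached.
#'
#' @param beta_draws Matrix of slope draws (columns = sites) as returned by
#'   `parameter_draws(fit, "^beta_tp")`, or a numeric vector of draws.
#' @param pooling `"concatenate"` (default) pools all sites' draws;
#'   `"mean"` averages sites within each draw first.
#' @return A `tmf_estimate`: `mean`, `ci` (central 95%), `draws`, and
#'   `per_site` (mean and 95% interval per column when a matrix was given).
#' @export
trophic_magnification_factor <- function(beta_draws,
                                         pooling = c("concatenate", "mean")) {
  pooling <- match.arg(pooling)
  if (is.vector(beta_draws)) beta_draws <- matrix(beta_draws, ncol = 1L)
  if (length(beta_draws) == 0L) stop("empty slope draws", call. = FALSE)
  pooled <- if (pooling == "mean" && ncol(beta_draws) > 1L)
    rowMeans(beta_draws) else as.vector(beta_draws)
  tmf <- exp(pooled)
  per_site <- NULL
  if (ncol(beta_draws) > 1L) {
    per_site <- data.frame(
      site = colnames(beta_draws) %||% paste0("site", seq_len(ncol(beta_draws))),
      tmf_mean = colMeans(exp(beta_draws)),
      tmf_lo95 = apply(exp(beta_draws), 2L, quantile, 0.025),
      tmf_hi95 = apply(exp(beta_draws), 2L, quantile, 0.975),
      stringsAsFactors = FALSE)
    rownames(per_site) <- NULL
  }
  structure(list(mean = mean(tmf),
                 ci = quantile(tmf, c(0.025, 0.975), names = FALSE),
                 draws = tmf, per_site = per_site, pooling = pooling),
            class = "tmf_estimate")
}

#' @export
print.tmf_estimate <- function(x, ...) {
  cat(sprintf("TMF %.2f (95%% CI %.2f-%.2f)%s\n", x$mean, x$ci[1L], x$ci[2L],
              if (x$mean < 1) " -- trophic dilution" else
                if (x$mean > 1) " -- biomagnification" else ""))
  invisible(x)
}

#' Species x site concentration summary table
#'
#' Posterior-mean trophic position and "true" particle concentration per
#' individual, per g wet weight and per g dry weight, averaged (and ranged)
#' over the individuals of each species at each site.
#'
#' @param fit Digestive-tract `mp_posterior`.
#' @param use `"lambda_sample"` (default: blank-free, the "true"
#'   concentration) or `"lambda_observed"`.
#' @return Data frame, one row per species x site, with mean and min-max range
#'   of `tp`, `per_ind`, `per_g_ww`, `per_g_dw`.
#' @export
species_site_summary <- function(fit, use = c("lambda_sample",
                                              "lambda_observed")) {
  stopifnot(inherits(fit, "mp_posterior"))
  use <- match.arg(use)
  md <- fit$data
  if (md$form != "digestive_tract")
    stop("summary table is defined for the digestive-tract model",
         call. = FALSE)
  lam <- colMeans(if (use == "lambda_sample") lambda_sample_draws(fit)
                  else lambda_observed_draws(fit))
  ## posterior-mean TP per specimen -> per observation
  pd <- parameter_draws(fit)
  base_cols <- grep("^d15n_base\\[", colnames(pd))
  dt_cols <- grep("^d15n_true\\[", colnames(pd))
  base_mean <- colMeans(pd[, base_cols, drop = FALSE])
  names(base_mean) <- sub("^d15n_base\\[(.*)\\]$", "\\1", names(base_mean))
  dt_mean <- colMeans(pd[, dt_cols, drop = FALSE])
  tp_spec <- scaled_trophic_position(
    dt_mean, base_mean[levels(md$site)][md$spec_site], md$trophic)
  tp_obs <- tp_spec[md$obs_specimen]

  ww <- md$tissue_ww_g
  dw <- md$tissue_dw_g
  if (is.null(ww) || is.null(dw) || anyNA(ww) || anyNA(dw))
    stop("the sample table passed to model_data() must carry `tissue_ww_g` ",
         "and `tissue_dw_g` for the summary table", call. = FALSE)

  d <- data.frame(species = as.character(md$species),
                  site = as.character(md$site),
                  tp = tp_obs, per_ind = lam,
                  per_g_ww = lam / ww, per_g_dw = lam / dw,
                  stringsAsFactors = FALSE)
  agg <- function(v) c(mean = mean(v), min = min(v), max = max(v))
  out <- do.call(rbind, lapply(split(d, list(d$species, d$site), drop = TRUE),
                               function(g) {
    data.frame(species = g$species[1L], site = g$site[1L], n = nrow(g),
               t(c(tp = agg(g$tp), per_ind = agg(g$per_ind),
                   per_g_ww = agg(g$per_g_ww), per_g_dw = agg(g$per_g_dw))),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$site, out$tp.mean), ]
  rownames(out) <- NULL
  attr(out, "rate_used") <- use
  out
}

#' Rockfish daily microplastic intake bounds
#'
#' Rockfish ingest between 0.5% and 3.7% of their body mass in food daily;
#' intake = ration fraction x body mass x prey particle concentration,
#' evaluated at the minimum and maximum ration across the supplied body-mass
#' range.
#'
#' @param prey_conc_per_g Prey particle concentration, particles per g wet
#'   weight (e.g. the transfer-model posterior mean per g).
#' @param body_mass_g Range (or vector) of rockfish body masses, g.
#' @param ration_range Daily ration as a fraction of body mass; default
#'   `c(0.005, 0.037)`.
#' @return Data frame with `ration`, `min_intake`, `max_intake`
#'   (particles per day across the body-mass range), one row per ration bound.
#' @export
rockfish_daily_intake <- function(prey_conc_per_g, body_mass_g,
                                  ration_range = c(0.005, 0.037)) {
  if (prey_conc_per_g < 0) stop("`prey_conc_per_g` must be >= 0",
                                call. = FALSE)
  if (any(body_mass_g <= 0)) stop("`body_mass_g` must be positive",
                                  call. = FALSE)
  if (any(ration_range <= 0) || any(ration_range >= 1) ||
      ration_range[1L] > ration_range[2L])
    stop("`ration_range` must be increasing fractions in (0, 1)",
         call. = FALSE)
  mrange <- range(body_mass_g)
  data.frame(ration = ration_range,
             min_intake = ration_range * mrange[1L] * prey_conc_per_g,
             max_intake = ration_range * mrange[2L] * prey_conc_per_g)
}
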