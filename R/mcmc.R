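## Posterior sampling for the blank-corrected hierarchical Poisson models.
## Blockwise adaptive random-walk Metropolis: within each block the component
## full conditionals are mutually independent given the rest of the state
## (disjoint likelihood terms, independent priors), so all components are
## proposed at once and accepted componentwise. Proposal scales adapt toward
## a 0.44 acceptance rate during burn-in only and are frozen afterwards.

#' Gelman-Rubin potential scale reduction factor
#'
#' \deqn{\hat R = \sqrt{\frac{\frac{n-1}{n} W + \frac{B}{n}}{W}}}
#' with `W` the mean within-chain variance and `B/n` the variance of the
#' chain means (`n` draws per chain). Values near 1 indicate the chains have
#' mixed; 1.01 is used as the convergence criterion downstream.
#'
#' @param chains A list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains))
    chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  if (n < 2L) stop("need at least 2 draws per chain", call. = FALSE)
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0)
    stop("constant chains: within-chain variance is zero, R-hat undefined",
         call. = FALSE)
  B_over_n <- var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

## one chain; returns draws of all scalar parameters plus lambda_sample
.run_chain <- function(spec, md, lb, chain_seed) {
  set.seed(chain_seed)
  has <- .form_has(md$form)
  sites <- levels(md$site)
  S <- md$n_site
  site_i <- as.integer(md$site)
  y <- md$y
  off <- md$off
  n <- length(y)
  gamma_free <- has$site_fixed && S > 1L

  if (has$species) {
    K <- nlevels(md$species)
    sp_i <- as.integer(md$species)
    sp_names <- levels(md$species)
  }
  if (has$gut) gut_i <- as.integer(md$gut)
  if (has$tp) {
    m <- length(md$specimen_id)
    spec_i <- md$obs_specimen
    spsite <- md$spec_site
    dobs <- md$d15n_obs
    msd <- md$measurement_sd
    b_shape <- vapply(md$baseline, `[[`, numeric(1), "alpha")
    b_rate <- vapply(md$baseline, `[[`, numeric(1), "beta")
    lim <- md$trophic$delta15n_lim
    kk <- md$trophic$k * log(md$trophic$log_base)
    tp_of <- function(d, base_s) (log(lim - base_s) - log(lim - d)) / kk + 2
  }

  safe_ll <- function(eta_vec) {
    l <- dpois(y, exp(eta_vec) + lb, log = TRUE)
    l[is.nan(l) | is.na(l)] <- -Inf
    l
  }
  group_sum <- function(x, g, G) {
    out <- numeric(G)
    t <- rowsum(x, g)
    out[as.integer(rownames(t))] <- t
    out
  }

  ## --- initialization from priors, retried when the density is non-finite
  alpha_site <- gamma_site <- beta <- alpha_gut <- NULL
  alpha_sp <- sigma <- base <- dtrue <- tp <- NULL
  for (try in 1:10) {
    if (has$site_intercept) alpha_site <- rnorm(S, 0, spec$prior_sd_alpha_site)
    if (has$site_fixed) gamma_site <- if (gamma_free) rnorm(S) else rep(0, S)
    if (has$species) {
      sigma <- rexp(1)
      alpha_sp <- rnorm(K, 0, sigma)
    }
    if (has$gut) alpha_gut <- rnorm(2)
    if (has$tp) {
      beta <- rnorm(S)
      base <- rgamma(S, b_shape, b_rate)
      base <- pmin(pmax(base, 0.1), lim - 0.5)
      dtrue <- pmin(dobs + rnorm(m, 0, msd), lim - 1e-3)
      tp <- tp_of(dtrue, base[spsite])
    }
    eta <- off + (if (has$site_intercept) alpha_site[site_i] else 0) +
      (if (has$site_fixed) gamma_site[site_i] else 0) +
      (if (has$species) alpha_sp[sp_i] else 0) +
      (if (has$gut) alpha_gut[gut_i] else 0) +
      (if (has$tp) beta[site_i] * tp[spec_i] else 0)
    ll <- safe_ll(eta)
    if (all(is.finite(ll))) break
    if (try == 10)
      stop("non-finite density at initialization after 10 retries",
           call. = FALSE)
  }

  ## --- adaptive step sizes per block
  steps <- list(alpha_site = rep(0.5, S), gamma_site = rep(0.3, S),
                alpha_sp = if (has$species) rep(0.3, K),
                beta = rep(0.2, S), alpha_gut = rep(0.3, 2), sigma = 0.5,
                base = rep(0.3, S), dtrue = if (has$tp) rep(msd, m),
                xg = 0.3, xgut = 0.3, slope_all = 0.2, slope_site = rep(0.2, S))
  acc_ct <- lapply(steps, function(s) if (!is.null(s)) numeric(length(s)))
  batch <- 50L

  ## generic update of a block entering eta additively via grouping g
  upd_linear <- function(name, vals, g, G, prior_sd, mult = NULL) {
    prop <- vals + rnorm(G) * steps[[name]]
    dv <- prop - vals
    delta <- if (is.null(mult)) dv[g] else dv[g] * mult
    eta_new <- eta + delta
    ll_new <- safe_ll(eta_new)
    dpost <- group_sum(ll_new - ll, g, G) +
      dnorm(prop, 0, prior_sd, log = TRUE) -
      dnorm(vals, 0, prior_sd, log = TRUE)
    dpost[is.na(dpost)] <- -Inf
    acc <- log(runif(G)) < dpost
    if (any(acc)) {
      sel <- acc[g]
      eta[sel] <<- eta_new[sel]
      ll[sel] <<- ll_new[sel]
      vals[acc] <- prop[acc]
    }
    acc_ct[[name]] <<- acc_ct[[name]] + acc
    vals
  }

  n_keep <- (spec$iterations - spec$burnin) %/% spec$thin
  par_names <- c(
    if (has$site_intercept) paste0("alpha_site[", sites, "]"),
    if (gamma_free) paste0("gamma_site[", sites, "]"),
    if (has$species) c(paste0("alpha_species[", sp_names, "]"),
                       "sigma_species"),
    if (has$tp) paste0("beta_tp[", sites, "]"),
    if (has$gut) c("alpha_gut[empty]", "alpha_gut[full]"),
    if (has$tp) c(paste0("d15n_base[", sites, "]"),
                  paste0("d15n_true[", md$specimen_id, "]")))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  lam_draws <- matrix(NA_real_, n_keep, n,
                      dimnames = list(NULL, md$sample_id))
  k_out <- 0L

  for (it in seq_len(spec$iterations)) {
    if (has$site_intercept)
      alpha_site <- upd_linear("alpha_site", alpha_site, site_i, S,
                               spec$prior_sd_alpha_site)
    if (gamma_free)
      gamma_site <- upd_linear("gamma_site", gamma_site, site_i, S,
                               spec$prior_sd_fixed)
    if (has$species)
      alpha_sp <- upd_linear("alpha_sp", alpha_sp, sp_i, K, sigma)
    if (has$gut)
      alpha_gut <- upd_linear("alpha_gut", alpha_gut, gut_i, 2L,
                              spec$prior_sd_fixed)
    if (has$tp)
      beta <- upd_linear("beta", beta, site_i, S, spec$prior_sd_fixed,
                         mult = tp[spec_i])

    if (has$species) {
      ## sigma_species: random walk on log(sigma) with Jacobian
      lsig <- log(sigma)
      lprop <- lsig + rnorm(1) * steps$sigma
      sprop <- exp(lprop)
      dpost <- dexp(sprop, 1, log = TRUE) - dexp(sigma, 1, log = TRUE) +
        lprop - lsig +
        sum(dnorm(alpha_sp, 0, sprop, log = TRUE)) -
        sum(dnorm(alpha_sp, 0, sigma, log = TRUE))
      if (is.finite(dpost) && log(runif(1)) < dpost) {
        sigma <- sprop
        acc_ct$sigma <- acc_ct$sigma + 1
      }
    }

    if (has$tp) {
      ## site baselines: change TP for each site's specimens
      prop <- base + rnorm(S) * steps$base
      valid <- prop > 0 & prop < lim - 1e-6
      prop_safe <- ifelse(valid, prop, base)
      tp_new <- tp_of(dtrue, prop_safe[spsite])
      eta_new <- eta + beta[site_i] * (tp_new[spec_i] - tp[spec_i])
      ll_new <- safe_ll(eta_new)
      dpost <- group_sum(ll_new - ll, site_i, S) +
        dgamma(prop_safe, b_shape, b_rate, log = TRUE) -
        dgamma(base, b_shape, b_rate, log = TRUE)
      dpost[!valid | is.na(dpost)] <- -Inf
      acc <- log(runif(S)) < dpost
      if (any(acc)) {
        sel <- acc[site_i]
        eta[sel] <- eta_new[sel]
        ll[sel] <- ll_new[sel]
        selm <- acc[spsite]
        tp[selm] <- tp_new[selm]
        base[acc] <- prop_safe[acc]
      }
      acc_ct$base <- acc_ct$base + acc

      ## latent true delta15N per specimen
      propd <- dtrue + rnorm(m) * steps$dtrue
      validd <- propd < lim - 1e-6
      propd_safe <- ifelse(validd, propd, dtrue)
      tp_new <- tp_of(propd_safe, base[spsite])
      eta_new <- eta + beta[site_i] * (tp_new[spec_i] - tp[spec_i])
      ll_new <- safe_ll(eta_new)
      dpostd <- group_sum(ll_new - ll, spec_i, m) +
        dnorm(propd_safe, dobs, msd, log = TRUE) -
        dnorm(dtrue, dobs, msd, log = TRUE)
      dpostd[!validd | is.na(dpostd)] <- -Inf
      accd <- log(runif(m)) < dpostd
      if (any(accd)) {
        sel <- accd[spec_i]
        eta[sel] <- eta_new[sel]
        ll[sel] <- ll_new[sel]
        tp[accd] <- tp_new[accd]
        dtrue[accd] <- propd_safe[accd]
      }
      acc_ct$dtrue <- acc_ct$dtrue + accd
    }

    ## directional moves along the confounded posterior ridges ------------
    ## (translation directions depend only on state blocks these moves do
    ## not update, so the proposals stay symmetric)
    if (has$species && gamma_free) {
      ## species intercepts vs site effects: likelihood-invariant exchange
      d <- rnorm(1) * steps$xg
      dpost <- sum(dnorm(alpha_sp + d, 0, sigma, log = TRUE)) -
        sum(dnorm(alpha_sp, 0, sigma, log = TRUE)) +
        sum(dnorm(gamma_site - d, 0, spec$prior_sd_fixed, log = TRUE)) -
        sum(dnorm(gamma_site, 0, spec$prior_sd_fixed, log = TRUE))
      if (is.finite(dpost) && log(runif(1)) < dpost) {
        alpha_sp <- alpha_sp + d
        gamma_site <- gamma_site - d
        acc_ct$xg <- acc_ct$xg + 1
      }
    }
    if (has$gut) {
      ## fullness intercepts vs species intercepts
      d <- rnorm(1) * steps$xgut
      dpost <- sum(dnorm(alpha_gut + d, 0, spec$prior_sd_fixed, log = TRUE)) -
        sum(dnorm(alpha_gut, 0, spec$prior_sd_fixed, log = TRUE)) +
        sum(dnorm(alpha_sp - d, 0, sigma, log = TRUE)) -
        sum(dnorm(alpha_sp, 0, sigma, log = TRUE))
      if (is.finite(dpost) && log(runif(1)) < dpost) {
        alpha_gut <- alpha_gut + d
        alpha_sp <- alpha_sp - d
        acc_ct$xgut <- acc_ct$xgut + 1
      }
    }
    if (has$tp) {
      tp_obs <- tp[spec_i]
      ## common slope shift compensated through the species intercepts
      tpbar_sp <- group_sum(tp_obs, sp_i, K) / pmax(tabulate(sp_i, K), 1L)
      d <- rnorm(1) * steps$slope_all
      eta_new <- eta + d * (tp_obs - tpbar_sp[sp_i])
      ll_new <- safe_ll(eta_new)
      dpost <- sum(ll_new - ll) +
        sum(dnorm(beta + d, 0, spec$prior_sd_fixed, log = TRUE)) -
        sum(dnorm(beta, 0, spec$prior_sd_fixed, log = TRUE)) +
        sum(dnorm(alpha_sp - d * tpbar_sp, 0, sigma, log = TRUE)) -
        sum(dnorm(alpha_sp, 0, sigma, log = TRUE))
      if (is.finite(dpost) && log(runif(1)) < dpost) {
        beta <- beta + d
        alpha_sp <- alpha_sp - d * tpbar_sp
        eta <- eta_new
        ll <- ll_new
        acc_ct$slope_all <- acc_ct$slope_all + 1
      }
      ## per-site slope shift compensated through the site effect
      if (gamma_free) {
        tpbar_site <- group_sum(tp_obs, site_i, S) /
          pmax(tabulate(site_i, S), 1L)
        dv <- rnorm(S) * steps$slope_site
        eta_new <- eta + dv[site_i] * (tp_obs - tpbar_site[site_i])
        ll_new <- safe_ll(eta_new)
        dpost <- group_sum(ll_new - ll, site_i, S) +
          dnorm(beta + dv, 0, spec$prior_sd_fixed, log = TRUE) -
          dnorm(beta, 0, spec$prior_sd_fixed, log = TRUE) +
          dnorm(gamma_site - dv * tpbar_site, 0, spec$prior_sd_fixed,
                log = TRUE) -
          dnorm(gamma_site, 0, spec$prior_sd_fixed, log = TRUE)
        dpost[is.na(dpost)] <- -Inf
        acc <- log(runif(S)) < dpost
        if (any(acc)) {
          sel <- acc[site_i]
          eta[sel] <- eta_new[sel]
          ll[sel] <- ll_new[sel]
          beta[acc] <- beta[acc] + dv[acc]
          gamma_site[acc] <- gamma_site[acc] - (dv * tpbar_site)[acc]
        }
        acc_ct$slope_site <- acc_ct$slope_site + acc
      }
    }

    ## adapt during burn-in only
    if (it <= spec$burnin && it %% batch == 0L) {
      for (nm in names(steps)) {
        if (is.null(steps[[nm]])) next
        rate <- acc_ct[[nm]] / batch
        steps[[nm]] <- pmin(pmax(steps[[nm]] * exp(rate - 0.44), 1e-4), 50)
        acc_ct[[nm]] <- acc_ct[[nm]] * 0
      }
    }

    if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
      k_out <- k_out + 1L
      draws[k_out, ] <- c(
        if (has$site_intercept) alpha_site,
        if (gamma_free) gamma_site,
        if (has$species) c(alpha_sp, sigma),
        if (has$tp) beta,
        if (has$gut) alpha_gut,
        if (has$tp) c(base, dtrue))
      lam_draws[k_out, ] <- exp(eta)
    }
  }
  list(params = draws, lambda = lam_draws)
}

#' Sample the posterior of a blank-corrected count model
#'
#' Runs `spec$chains` MCMC chains over the joint density of
#' [joint_logdensity()] and computes the Gelman-Rubin R-hat for every scalar
#' parameter. When any R-hat exceeds the threshold a warning advises
#' increasing the number of iterations until all values reach 1.01 or lower
#' (the fit is still returned).
#'
#' @param spec A [model_spec()].
#' @param data A [model_data()] object of the same form.
#' @param blank_model A [blank_rate()] model, or `NULL` for a naive
#'   (uncorrected) fit with the contamination rate fixed at 0.
#' @param seed Integer seed; chain `c` uses `seed + 1000 * c`.
#' @return An `mp_posterior`: per-chain parameter and `lambda_sample` draw
#'   matrices, the per-observation blank rates, R-hat per parameter, and the
#'   effective settings.
#' @export
sample_posterior <- function(spec, data, blank_model = NULL, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "model_data"))
  if (spec$form != data$form) stop("spec/data form mismatch", call. = FALSE)
  lb <- blank_lambda(blank_model, data$blank_key)
  chains <- lapply(seq_len(spec$chains), function(cc)
    .run_chain(spec, data, lb, chain_seed = seed + 1000L * cc))
  params <- lapply(chains, `[[`, "params")
  lambda <- lapply(chains, `[[`, "lambda")

  rhat <- vapply(colnames(params[[1L]]), function(p) {
    cols <- lapply(params, function(mat) mat[, p])
    if (all(vapply(cols, var, numeric(1)) == 0)) return(NA_real_)
    gelman_rubin(cols)
  }, numeric(1))
  bad <- names(rhat)[!is.na(rhat) & rhat > spec$rhat_threshold]
  if (length(bad) > 0L)
    warning("R-hat above ", spec$rhat_threshold, " for: ",
            paste(utils::head(bad, 8L), collapse = ", "),
            if (length(bad) > 8L) ", ..." else "",
            ". Increase the number of MCMC iterations until R-hat values ",
            "reach ", spec$rhat_threshold, " or lower.", call. = FALSE)

  structure(list(spec = spec, data = data, params = params, lambda = lambda,
                 lambda_blank = lb, blank_model = blank_model, rhat = rhat,
                 seed = seed,
                 settings = list(chains = spec$chains,
                                 iterations = spec$iterations,
                                 burnin = spec$burnin, thin = spec$thin)),
            class = "mp_posterior")
}

#' Pooled parameter draws
#' @param fit An `mp_posterior`.
#' @param pattern Optional regular expression selecting parameter names.
#' @return Matrix (draws x parameters), chains concatenated.
#' @export
parameter_draws <- function(fit, pattern = NULL) {
  stopifnot(inherits(fit, "mp_posterior"))
  mat <- do.call(rbind, fit$params)
  if (!is.null(pattern))
    mat <- mat[, grepl(pattern, colnames(mat)), drop = FALSE]
  mat
}

#' Pooled per-sample true-rate draws
#' @param fit An `mp_posterior`.
#' @return Matrix (draws x observations) of `lambda_sample`.
#' @export
lambda_sample_draws <- function(fit) {
  stopifnot(inherits(fit, "mp_posterior"))
  do.call(rbind, fit$lambda)
}

#' Pooled per-sample observed-rate draws
#'
#' `lambda_observed = lambda_sample + lambda_blanks`, exactly, draw by draw.
#' @param fit An `mp_posterior`.
#' @return Matrix (draws x observations).
#' @export
lambda_observed_draws <- function(fit) {
  ls <- lambda_sample_draws(fit)
  sweep(ls, 2L, fit$lambda_blank, "+")
}

#' @export
print.mp_posterior <- function(x, ...) {
  cat("Blank-corrected Poisson model fit ('", x$spec$form, "')\n", sep = "")
  cat(sprintf("  chains %d, iterations %d (burn-in %d, thin %d)\n",
              x$settings$chains, x$settings$iterations, x$settings$burnin,
              x$settings$thin))
  cat(sprintf("  %d observations, max R-hat %.4f\n",
              length(x$data$y), max(x$rhat, na.rm = TRUE)))
  invisible(x)
}
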