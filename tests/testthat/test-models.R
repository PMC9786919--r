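test_that("blank rates are per-key arithmetic means", {
  bm <- blank_rate(data.frame(blank_key = "digestive", count = c(0, 0, 3)))
  expect_equal(bm$lambda_blank, 1.0)
  bm <- blank_rate(data.frame(blank_key = "tow", count = c(0, 0, 0)))
  expect_equal(bm$lambda_blank, 0.0)

  set.seed(1)
  counts <- rpois(90, 0.24)
  bm <- blank_rate(data.frame(blank_key = "x", count = counts))
  expect_equal(bm$lambda_blank, 0.24, tolerance = 4 * sqrt(0.24 / 90) / 0.24)

  two <- blank_rate(data.frame(blank_key = c("a", "a", "b"),
                               count = c(1, 3, 5)))
  expect_equal(blank_lambda(two, c("b", "a", "a")), c(5, 2, 2))
  expect_equal(blank_lambda(NULL, c("a", "b")), c(0, 0))
  expect_error(blank_lambda(two, "c"), "no blank rate")
  expect_error(blank_rate(data.frame(blank_key = "a", count = -1)),
               "non-negative")
})

test_that("blank-corrected Poisson log likelihood matches the pmf", {
  expect_equal(poisson_blank_loglik(0, 1, 0), -1.0)
  expect_equal(poisson_blank_loglik(0, 0, 0.24), -0.24)
  expect_equal(poisson_blank_loglik(2, 1, 1), -2 + log(2), tolerance = 1e-12)
  expect_identical(poisson_blank_loglik(3, 0, 0), -Inf)
  expect_error(poisson_blank_loglik(-1, 1, 0), "non-negative")
  expect_error(poisson_blank_loglik(1, -0.1, 0), "lambda_sample")
})

test_that("linear predictors cover all six forms", {
  st <- list(alpha_site = c(A = -8), gamma_site = c(A = 0.2, B = 0),
             alpha_species = c(clam = 0.1, sole = -0.4),
             beta_tp = c(A = 0, B = 0.5),
             alpha_gut = c(empty = -1, full = 1))
  expect_equal(linear_predictor("seawater_tow",
                                list(site = "A", volume_l = 1000), st),
               log(1000) - 8)
  expect_equal(linear_predictor("seawater_jar", list(site = "A"), st), -8)
  expect_equal(linear_predictor("digestive_tract",
                                list(site = "A", species = "clam", tp = 3),
                                st), 0.3)
  expect_equal(linear_predictor("liver",
                                list(site = "B", species = "clam", tp = 3,
                                     tissue_ww_g = 2), st),
               log(2) + 0.1 + 1.5)
  expect_equal(linear_predictor("transfer",
                                list(site = "B", species = "sole",
                                     tissue_dw_g = 4), st), log(4) - 0.4)
  expect_equal(linear_predictor("gut_fullness",
                                list(site = "B", species = "sole",
                                     fullness = "full"), st), 0.6)
  ## vectorised over rows
  expect_equal(linear_predictor("seawater_jar",
                                data.frame(site = c("A", "A")), st),
               c(-8, -8))
  expect_error(linear_predictor("seawater_tow", list(site = "A"), st),
               "volume_l")
  expect_error(linear_predictor("digestive_tract",
                                list(site = "C", species = "clam", tp = 2),
                                st), "missing level")
})

test_that("model data validation reports all problems with row numbers", {
  s <- data.frame(sample_id = c("a", "b"), count = c(1, -1), site = "A",
                  volume_l = c(10, 0))
  err <- tryCatch(model_data("seawater_tow", s), error = conditionMessage)
  expect_match(err, "count")
  expect_match(err, "volume_l")
  expect_error(model_data("liver", data.frame(sample_id = "a", count = 1,
                                              site = "A")),
               "tissue_ww_g")
})

## a tiny digestive dataset used by the density oracle
tiny_md <- function() {
  samples <- data.frame(
    sample_id = paste0("d", 1:4), count = c(0L, 2L, 1L, 3L),
    site = c("A", "A", "B", "B"),
    species = c("clam", "star", "clam", "star"),
    specimen_id = paste0("sp", 1:4), blank_key = "digestive")
  iso <- data.frame(specimen_id = paste0("sp", 1:4),
                    species = samples$species, site = samples$site,
                    tissue = "body", d13c = -18,
                    d15n = c(9.4, 12.1, 10.0, 13.3))
  base <- data.frame(site = rep(c("A", "B"), each = 3),
                     d15n = c(9.1, 9.5, 9.3, 9.8, 10.2, 10.0))
  model_data("digestive_tract", samples, iso, base)
}

tiny_state <- function() {
  list(gamma_site = c(A = 0.2, B = -0.1),
       alpha_species = c(clam = 0.3, star = -0.2),
       sigma_species = 0.6,
       beta_tp = c(A = 0.4, B = 0.1),
       d15n_base = c(A = 9.3, B = 10.0),
       d15n_true = c(sp1 = 9.45, sp2 = 12.0, sp3 = 10.1, sp4 = 13.2))
}

test_that("joint log density equals the sum of independently computed terms", {
  md <- tiny_md()
  spec <- model_spec("digestive_tract")
  st <- tiny_state()
  bm <- blank_rate(data.frame(blank_key = "digestive", count = c(0, 1, 0)))

  ## term-by-term oracle, written out directly from the model definition
  pa <- fit_gamma_baseline(c(9.1, 9.5, 9.3))   # site A mussels
  pb <- fit_gamma_baseline(c(9.8, 10.2, 10.0)) # site B mussels
  lp <- dgamma(9.3, pa$alpha, pa$beta, log = TRUE) +
    dgamma(10.0, pb$alpha, pb$beta, log = TRUE) +
    sum(dnorm(c(9.45, 12.0, 10.1, 13.2), c(9.4, 12.1, 10.0, 13.3), 0.052,
              log = TRUE)) +
    sum(dnorm(c(0.2, -0.1), 0, 1, log = TRUE)) +      # gamma_site
    sum(dnorm(c(0.4, 0.1), 0, 1, log = TRUE)) +       # beta_tp
    dexp(0.6, 1, log = TRUE) +
    sum(dnorm(c(0.3, -0.2), 0, 0.6, log = TRUE))      # species effects
  k <- 0.315
  tp <- (log10(21.926 - c(9.3, 9.3, 10.0, 10.0)) -
           log10(21.926 - c(9.45, 12.0, 10.1, 13.2))) / k + 2
  eta <- c(0.3, -0.2, 0.3, -0.2) + c(0.4, 0.4, 0.1, 0.1) * tp +
    c(0.2, 0.2, -0.1, -0.1)
  lp <- lp + sum(dpois(c(0, 2, 1, 3), exp(eta) + 1 / 3, log = TRUE))

  expect_equal(joint_logdensity(spec, md, st, bm), lp, tolerance = 1e-10)

  ## support: latent delta15N at the limit
  st_bad <- tiny_state()
  st_bad$d15n_true["sp2"] <- 21.93
  expect_identical(joint_logdensity(spec, md, st_bad, bm), -Inf)
  st_bad2 <- tiny_state()
  st_bad2$sigma_species <- -1
  expect_identical(joint_logdensity(spec, md, st_bad2, bm), -Inf)

  ## with no blank term the density reduces to the ordinary Poisson GLMM
  lp0 <- lp - sum(dpois(c(0, 2, 1, 3), exp(eta) + 1 / 3, log = TRUE)) +
    sum(dpois(c(0, 2, 1, 3), exp(eta), log = TRUE))
  expect_equal(joint_logdensity(spec, md, st, NULL), lp0, tolerance = 1e-10)
})

test_that("model spec validates mcmc settings and supplies the defaults", {
  s <- model_spec("seawater_tow")
  expect_equal(c(s$iterations, s$burnin, s$thin), c(10000L, 500L, 5L))
  expect_equal(model_spec("digestive_tract")$thin, 2L)
  expect_equal(model_spec("gut_fullness")$iterations, 5000L)
  expect_error(model_spec("liver", iterations = 400, burnin = 500),
               "exceed")
  expect_error(model_spec("liver", chains = 1), "chains")
})
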