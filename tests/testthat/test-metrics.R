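# a hand-built posterior stub: constant draws, so every metric is arithmetic
stub_fit <- function(lam, site, species = NULL, form = "digestive_tract",
                     lam_blank = 0, n_draws = 200, extra = list()) {
  n <- length(lam)
  lmat <- matrix(rep(lam, each = n_draws), n_draws, n,
                 dimnames = list(NULL, sprintf("s%02d", seq_len(n))))
  structure(c(list(
    spec = model_spec(form),
    data = c(list(form = form, y = rep(0L, n),
                  sample_id = sprintf("s%02d", seq_len(n)),
                  site = factor(site), n_site = length(unique(site)),
                  species = if (!is.null(species)) factor(species),
                  trophic = trophic_params()), extra),
    params = list(matrix(0, n_draws, 1, dimnames = list(NULL, "x"))),
    lambda = list(lmat),
    lambda_blank = rep(lam_blank, n), rhat = c(x = 1),
    settings = list(chains = 1)), list()),
    class = "mp_posterior")
}

test_that("bioaccumulation factors are the documented arithmetic", {
  ## posterior mean 0.5 particles, 0.05 kg animal, seawater 1.48 per L
  animal <- stub_fit(lam = 0.5, site = "A", species = "clam")
  water <- stub_fit(lam = 1.48, site = "A", form = "seawater_jar")
  baf <- bioaccumulation_factor(animal, 0.05, water)
  expect_equal(baf$c_a, 10)
  expect_equal(baf$c_w, 1.48)
  expect_equal(baf$baf, 10 / 1.48, tolerance = 1e-12)

  ## C_a == C_w -> BAF exactly 1
  a2 <- stub_fit(lam = 1.48 * 0.05, site = "A", species = "clam")
  expect_equal(bioaccumulation_factor(a2, 0.05, water)$baf, 1)

  ## zero posterior mean -> BAF 0
  a3 <- stub_fit(lam = 0, site = "A", species = "clam")
  expect_equal(bioaccumulation_factor(a3, 0.05, water)$baf, 0)

  ## scale consistency: doubling mass halves C_a and BAF exactly
  b1 <- bioaccumulation_factor(animal, 0.05, water)
  b2 <- bioaccumulation_factor(animal, 0.10, water)
  expect_equal(b2$c_a, b1$c_a / 2)
  expect_equal(b2$baf, b1$baf / 2)

  ## blank-free switch uses lambda_sample and is recorded
  a4 <- stub_fit(lam = 0.5, site = "A", species = "clam", lam_blank = 0.25)
  b_obs <- bioaccumulation_factor(a4, 0.05, water)
  b_sam <- bioaccumulation_factor(a4, 0.05, water, use = "lambda_sample")
  expect_equal(b_obs$c_a, (0.5 + 0.25) / 0.05)
  expect_equal(b_sam$c_a, 0.5 / 0.05)
  expect_identical(attr(b_sam, "rate_used"), "lambda_sample")

  expect_error(bioaccumulation_factor(animal, -1, water), "positive")
  w0 <- stub_fit(lam = 0, site = "A", form = "seawater_jar")
  expect_error(bioaccumulation_factor(animal, 0.05, w0), "undefined")
})

test_that("trophic magnification factor transforms slope draws", {
  z <- trophic_magnification_factor(rep(0, 500))
  expect_equal(z$mean, 1)
  expect_equal(z$ci, c(1, 1))

  t3 <- trophic_magnification_factor(c(-1, 0, 1))
  expect_equal(t3$mean, (exp(-1) + 1 + exp(1)) / 3, tolerance = 1e-12)

  ## monotone shift: adding delta multiplies the mean by exp(delta) exactly
  set.seed(3)
  d <- rnorm(400, -0.6, 0.3)
  expect_equal(trophic_magnification_factor(d + 0.25)$mean,
               exp(0.25) * trophic_magnification_factor(d)$mean,
               tolerance = 1e-12)

  ## per-site table from a matrix of slopes
  m <- cbind(`beta_tp[A]` = rnorm(300, -0.6, 0.1),
             `beta_tp[B]` = rnorm(300, 0.1, 0.1))
  tm <- trophic_magnification_factor(m)
  expect_equal(nrow(tm$per_site), 2)
  expect_equal(length(tm$draws), 600)  # pooled by concatenation
  expect_error(trophic_magnification_factor(numeric(0)), "empty")
})

test_that("species-site summary matches a brute-force recomputation", {
  sim <- simulate_foodweb(tiny_config(seed = 19))
  fit <- fit_digestive(sim, blank_rate(sim$blanks), seed = 5,
                       iterations = 1200)
  tab <- species_site_summary(fit)

  ## brute force from the draws and the model data
  md <- fit$data
  lam <- colMeans(lambda_sample_draws(fit))
  cell <- paste(as.character(md$species), as.character(md$site))
  expect_equal(tab$per_ind.mean,
               as.numeric(tapply(lam, cell, mean)[paste(tab$species,
                                                        tab$site)]),
               tolerance = 1e-12)
  i <- which(tab$species == "blue_mussel" & tab$site == "Coles Bay")
  sel <- cell == "blue_mussel Coles Bay"
  expect_equal(tab$per_g_ww.mean[i], mean(lam[sel] / md$tissue_ww_g[sel]),
               tolerance = 1e-12)
  expect_equal(tab$per_g_dw.max[i], max(lam[sel] / md$tissue_dw_g[sel]),
               tolerance = 1e-12)
  ## single-individual cells collapse their range
  expect_true(all(tab$per_ind.min <= tab$per_ind.mean &
                    tab$per_ind.mean <= tab$per_ind.max))
})

test_that("one specimen's arithmetic: 0.6 particles in 0.5 g ww", {
  a <- stub_fit(lam = 0.6, site = "A", species = "clam",
                extra = list(tissue_ww_g = 0.5, tissue_dw_g = 0.1,
                             spec_site = 1L, obs_specimen = 1L,
                             specimen_id = "sp1", d15n_obs = 10,
                             baseline = list(A = baseline_prior(9.5, 0.5))))
  a$params <- list(matrix(c(9.5, 10), 200, 2, byrow = TRUE,
                          dimnames = list(NULL, c("d15n_base[A]",
                                                  "d15n_true[sp1]"))))
  tab <- species_site_summary(a)
  expect_equal(tab$per_g_ww.mean, 1.2)
  expect_equal(tab$n, 1L)
  expect_equal(tab$per_ind.min, tab$per_ind.max)
})

test_that("rockfish daily intake bounds are ration x mass x concentration", {
  expect_equal(rockfish_daily_intake(0, c(100, 400))$max_intake, c(0, 0))
  di <- rockfish_daily_intake(0.01, 200, ration_range = c(0.005, 0.037))
  expect_equal(di$min_intake[1], 0.01)
  di2 <- rockfish_daily_intake(0.01, c(200, 500))
  expect_equal(di2$min_intake, c(0.005, 0.037) * 200 * 0.01)
  expect_equal(di2$max_intake, c(0.005, 0.037) * 500 * 0.01)
  expect_error(rockfish_daily_intake(0.01, 200, ration_range = c(0.1, 1.2)),
               "ration")
  expect_error(rockfish_daily_intake(-1, 200), "prey_conc")
})
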