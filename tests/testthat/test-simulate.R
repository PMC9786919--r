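test_that("invalid configurations are rejected with field names", {
  expect_error(simulation_config(lambda_blank = -1), "lambda_blank")
  expect_error(simulation_config(baseline_sd = c(0, 1, 1)), "baseline_sd")
  expect_error(simulation_config(
    particle_features = list(labelled_fraction = 1.2)), "labelled_fraction")
  sp <- default_species_table()
  sp$tp[1] <- 7
  expect_error(simulation_config(species = sp), "trophic position")
  expect_error(simulation_config(baseline_mu = c(25, 9, 9)), "delta15n_lim")
})

test_that("the same seed reproduces identical tables", {
  cfg <- tiny_config(seed = 31)
  s1 <- simulate_foodweb(cfg)
  s2 <- simulate_foodweb(cfg)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$isotopes, s2$isotopes)
  expect_identical(s1$blanks, s2$blanks)
  expect_identical(simulate_particle_table(s1), simulate_particle_table(s2))
  s3 <- simulate_foodweb(tiny_config(seed = 32))
  expect_false(identical(s1$samples$count, s3$samples$count))
})

test_that("generated tables satisfy the structural invariants", {
  sim <- simulate_foodweb(tiny_config(seed = 5))
  expect_true(all(sim$samples$count >= 0 &
                    sim$samples$count == round(sim$samples$count)))
  expect_true(all(is.finite(sim$isotopes$d15n)))
  expect_true(all(sim$blanks$count >= 0))
  expect_true(all(sim$truth$lambda$lambda_sample > 0))
  ## truth dimensions match the emitted tables
  expect_equal(nrow(sim$truth$lambda), nrow(sim$samples))
  expect_setequal(sim$truth$specimens$specimen_id,
                  unique(stats::na.omit(sim$samples$specimen_id)))
})

test_that("count means converge to exp(gamma_site) in the degenerate design", {
  ## no blanks, no trophic slope, no species heterogeneity:
  ## digestive counts are Poisson(exp(gamma_site))
  cfg <- simulation_config(species = default_species_table()[1:4, ],
                           beta_tp = 0, sigma_species = 0,
                           lambda_blank = 0, isotope_spread = 0,
                           n_per_species_site = 900, n_water_per_site = 2,
                           seed = 17)
  sim <- simulate_foodweb(cfg)
  dig <- sim$samples[sim$samples$sample_type == "digestive", ]
  m <- tapply(dig$count, dig$site, mean)[cfg$sites]
  lam <- exp(cfg$gamma_site)
  se <- sqrt(lam / 3600)
  expect_true(all(abs(m - lam) < 4 * se))
})

test_that("blank counts are Poisson at the configured contamination rate", {
  cfg <- simulation_config(species = default_species_table()[1:4, ],
                           lambda_blank = 0.25, samples_per_run = 1,
                           n_per_species_site = 40, seed = 9)
  sim <- simulate_foodweb(cfg)
  n <- nrow(sim$blanks)
  expect_gt(n, 1000)
  expect_equal(mean(sim$blanks$count), 0.25,
               tolerance = 4 * sqrt(0.25 / n) / 0.25)
  ## Poisson mean/variance equality within sampling error
  expect_equal(var(sim$blanks$count) / mean(sim$blanks$count), 1,
               tolerance = 0.15)
})

test_that("ground truth determines the expectation of every observable", {
  ## deterministic truth (sigma = 0, no isotope spread): the analytic
  ## expectation exp(beta*TP + gamma) + lambda_blank is recomputed here
  ## independently and compared to the empirical mean over replicate seeds
  mean_counts <- NULL
  expected <- NULL
  for (s in 1:20) {
    cfg <- simulation_config(species = default_species_table()[1:8, ],
                             beta_tp = 0.3, sigma_species = 0,
                             isotope_spread = 0, lambda_blank = 0.2,
                             n_per_species_site = 25, n_water_per_site = 2,
                             seed = 400 + s)
    sim <- simulate_foodweb(cfg)
    dig <- sim$samples[sim$samples$sample_type == "digestive", ]
    if (is.null(expected)) {
      tr <- sim$truth$specimens
      i <- match(dig$specimen_id, tr$specimen_id)
      si <- match(dig$site, cfg$sites)
      expected <- exp(0.3 * tr$tp_true[i] + cfg$gamma_site[si]) + 0.2
      ## and the generator's own record agrees with the brute-force version
      ec <- expected_counts(sim$truth)
      expect_equal(ec$expected_count[match(dig$sample_id, ec$sample_id)],
                   expected, tolerance = 1e-12)
      mean_counts <- numeric(length(expected))
    }
    mean_counts <- mean_counts + dig$count / 20
  }
  expect_equal(mean(mean_counts), mean(expected), tolerance = 0.03)
  ## standardised by the Monte-Carlo SE of a 20-replicate Poisson mean
  z <- (mean_counts - expected) / sqrt(expected / 20)
  expect_lt(mean(abs(z)), 1.5)
  expect_lt(max(abs(z)), 5)
})

test_that("particle tables respect labelling and concordance settings", {
  cfg <- tiny_config(seed = 2, particle_features = list(labelled_fraction = 1))
  pt <- simulate_particle_table(simulate_foodweb(cfg), cfg)
  expect_false(any(pt$label == "unknown"))

  cfg <- tiny_config(seed = 2, particle_features = list(concordance = 1))
  pt <- simulate_particle_table(simulate_foodweb(cfg), cfg)
  expect_identical(pt$expert_guess, pt$true_label)

  ## empirical concordance at the default 0.79, large table
  cfg <- simulation_config(species = default_species_table()[1:6, ],
                           n_per_species_site = 25,
                           particle_features = list(natural_rate = 12),
                           seed = 8)
  pt <- simulate_particle_table(simulate_foodweb(cfg), cfg)
  n <- nrow(pt)
  expect_gt(n, 5000)
  agree <- mean(pt$expert_guess == pt$true_label)
  expect_equal(agree, 0.79, tolerance = 4 * sqrt(0.79 * 0.21 / n) / 0.79)
  ## labelled fraction near its default
  expect_equal(mean(pt$label != "unknown"), 0.69, tolerance = 0.05)
  ## lengths confined to the detection window
  expect_true(all(pt$length_um >= 100 & pt$length_um <= 5000))
})

test_that("rockfish stomach simulation follows its configured rates", {
  ## prey rate of zero: no prey particles anywhere
  cfg <- tiny_config(seed = 3, rockfish = list(prey_rate = 0))
  st <- simulate_rockfish_stomachs(cfg)
  expect_true(all(st$prey_count == 0))

  ## no fullness effect: full and empty gut-count means agree
  cfg <- tiny_config(seed = 4, rockfish = list(fullness_effect = 0,
                                               gut_rate_empty = 0.6,
                                               n_per_site = 300))
  st <- simulate_rockfish_stomachs(cfg)
  m <- tapply(st$gut_count, st$fullness, mean)
  expect_equal(unname(m["full"] - m["empty"]), 0, tolerance = 0.15)

  ## mean prey count converges to the configured 0.55 per stomach
  cfg <- tiny_config(seed = 5, rockfish = list(prey_rate = 0.55, p_full = 1,
                                               n_per_site = 400))
  st <- simulate_rockfish_stomachs(cfg)
  expect_gt(nrow(st), 1000)
  expect_equal(mean(st$prey_count), 0.55,
               tolerance = 4 * sqrt(0.55 / nrow(st)) / 0.55)
})
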