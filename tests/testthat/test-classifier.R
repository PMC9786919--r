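# helper: particle frames built in code
toy_particles <- function(n, seed, signal = c("expert", "none", "separable")) {
  signal <- match.arg(signal)
  set.seed(seed)
  truth <- sample(c("synthetic", "natural"), n, replace = TRUE)
  guess <- switch(signal,
    separable = truth,
    expert = ifelse(runif(n) < 0.79, truth,
                    ifelse(truth == "synthetic", "natural", "synthetic")),
    none = sample(c("synthetic", "natural"), n, replace = TRUE))
  data.frame(
    particle_id = sprintf("p%05d", seq_len(n)),
    sample_id = sample(sprintf("s%02d", 1:12), n, replace = TRUE),
    sample_type = sample(c("blank", "tow", "digestive"), n, replace = TRUE),
    size_fraction = sample(c("100-150um", "150um-1mm"), n, replace = TRUE),
    shape = sample(c("fiber", "fragment"), n, replace = TRUE),
    color = sample(c("clear", "blue", "black"), n, replace = TRUE),
    length_um = rlnorm(n, log(500), 0.7),
    expert_guess = guess, label = truth,
    stringsAsFactors = FALSE)
}

test_that("a perfectly separable table is learned almost exactly", {
  d <- toy_particles(400, seed = 1, signal = "separable")
  fit <- train_particle_classifier(d, n_trees = 300, seed = 2)
  expect_gt(fit$report$oob$accuracy, 0.95)
  ## the informative predictor dominates the importance ranking
  expect_identical(names(fit$report$importance)[1], "expert_guess")
})

test_that("pure-noise features give chance-level out-of-bag accuracy", {
  d <- toy_particles(600, seed = 3, signal = "none")
  fit <- train_particle_classifier(d, n_trees = 500, seed = 4)
  expect_equal(fit$report$oob$accuracy, 0.5, tolerance = 0.2)
})

test_that("report fractions recompute exactly from the confusion table", {
  d <- toy_particles(500, seed = 5, signal = "expert")
  fit <- train_particle_classifier(d, n_trees = 400, seed = 6)
  for (which in c("oob", "resub")) {
    r <- fit$report[[which]]
    tab <- r$confusion
    expect_identical(r$accuracy,
                     (tab["synthetic", "synthetic"] +
                        tab["natural", "natural"]) / sum(tab))
    expect_identical(r$sensitivity,
                     tab["synthetic", "synthetic"] / sum(tab["synthetic", ]))
    expect_identical(r$specificity,
                     tab["natural", "natural"] / sum(tab["natural", ]))
    ## confusion margins equal the class counts
    expect_equal(sum(tab["synthetic", ]), sum(d$label == "synthetic"))
  }
})

test_that("training rejects degenerate inputs", {
  d <- toy_particles(50, seed = 7, signal = "expert")
  d$label <- "synthetic"
  expect_error(train_particle_classifier(d), "single class")
  d2 <- toy_particles(50, seed = 7, signal = "expert")
  d2$label[1] <- "unknown"
  expect_error(train_particle_classifier(d2), "unknown")
})

test_that("classification fills unknowns only, deterministically", {
  train <- toy_particles(300, seed = 8, signal = "separable")
  fit <- train_particle_classifier(train, n_trees = 300, seed = 9)

  ## empty unknown set: table returned untouched
  out <- classify_unknowns(fit, train)
  expect_identical(out$label, train$label)
  expect_false(any(out$label_imputed))

  ## unknowns identical to a labelled synthetic training row -> synthetic
  mixed <- train
  syn_rows <- which(train$label == "synthetic")[1:20]
  mixed$label[syn_rows] <- "unknown"
  out <- classify_unknowns(fit, mixed)
  expect_true(all(out$label[syn_rows] == "synthetic"))
  expect_true(all(out$label_imputed[syn_rows]))
  ## previously labelled rows never relabelled
  keep <- setdiff(seq_len(nrow(mixed)), syn_rows)
  expect_identical(out$label[keep], train$label[keep])

  ## unseen categorical level is signalled, not silently dropped
  bad <- mixed[syn_rows, ]
  bad$color <- "chartreuse"
  expect_error(classify_unknowns(fit, bad), "unseen level")
})

test_that("classified fraction tracks the labelled fraction on full data", {
  cfg <- simulation_config(species = default_species_table()[1:6, ],
                           n_per_species_site = 15,
                           particle_features = list(natural_rate = 3),
                           seed = 12)
  pt <- simulate_particle_table(simulate_foodweb(cfg), cfg)
  lab <- pt[pt$label != "unknown", ]
  fit <- train_particle_classifier(lab, n_trees = 500, seed = 13)
  out <- classify_unknowns(fit, pt)
  frac_known <- mean(lab$label == "synthetic")
  frac_assigned <- mean(out$label[out$label_imputed] == "synthetic")
  expect_equal(frac_assigned, frac_known, tolerance = 0.12)
})

test_that("per-sample counts pool synthetic particles across fractions", {
  p <- data.frame(
    particle_id = sprintf("p%02d", 1:10),
    sample_id = c(rep("s1", 4), rep("s2", 5), "s3"),
    size_fraction = c("100-150um", "150um-1mm", "150um-1mm", ">1mm",
                      rep("100-150um", 5), ">1mm"),
    label = c("synthetic", "synthetic", "synthetic", "natural",
              "synthetic", "natural", "natural", "synthetic", "natural",
              "natural"),
    stringsAsFactors = FALSE)
  counts <- aggregate_sample_counts(p, c("s1", "s2", "s3", "s_empty"))
  expect_equal(counts$mp_count[match(c("s1", "s2", "s3", "s_empty"),
                                     counts$sample_id)],
               c(3L, 2L, 0L, 0L))
  ## conservation: totals equal the number of synthetic particles
  expect_equal(sum(counts$mp_count), sum(p$label == "synthetic"))

  expect_error(aggregate_sample_counts(p, c("s1", "s2")), "nonexistent")
  p$label[1] <- "unknown"
  expect_error(aggregate_sample_counts(p, c("s1", "s2", "s3")), "unknown")
})
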