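## Random-forest classification of visually sorted particles whose chemical
## identity could not be confirmed by spectroscopy. Predictors: expert guess,
## sample type, size fraction, shape, colour, and length; response: the
## spectroscopy label (synthetic vs natural).

.classifier_features <- c("expert_guess", "sample_type", "size_fraction",
                          "shape", "color", "length_um")

.as_factor_frame <- function(records, levels = NULL) {
  d <- records[, .classifier_features, drop = FALSE]
  for (v in setdiff(.classifier_features, "length_um")) {
    if (is.null(levels)) d[[v]] <- factor(d[[v]])
    else {
      unseen <- setdiff(unique(as.character(d[[v]])), levels[[v]])
      if (length(unseen) > 0L)
        stop("unseen level(s) in `", v, "` at predict time: ",
             paste(unseen, collapse = ", "), call. = FALSE)
      d[[v]] <- factor(d[[v]], levels = levels[[v]])
    }
  }
  d
}

.report_from_confusion <- function(tab) {
  ## rows = truth, cols = predicted; "synthetic" is the positive class
  tp <- tab["synthetic", "synthetic"]; fn <- tab["synthetic", "natural"]
  tn <- tab["natural", "natural"];    fp <- tab["natural", "synthetic"]
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / sum(tab), confusion = tab)
}

#' Train the particle classifier
#'
#' Fits a random forest (1000 trees, two variables per split by default) to
#' spectroscopy-labelled particles. Performance is reported both out-of-bag
#' (the default, honest estimate) and by resubstitution on the training rows,
#' together with the variable-importance ranking (when the expert guess is
#' strongly concordant with the labels it is expected to rank first).
#'
#' @param records Particle data frame with columns `expert_guess`,
#'   `sample_type`, `size_fraction`, `shape`, `color`, `length_um`, and
#'   `label` in `{"synthetic", "natural"}` (no `"unknown"` rows).
#' @param n_trees Number of trees (default 1000).
#' @param vars_per_split Variables tried at each split (`mtry`, default 2).
#' @param seed Integer seed for the forest.
#' @return A `particle_classifier`: the fitted forest, factor levels of the
#'   training schema, and a `report` list with `oob` and `resub` performance
#'   (each with `sensitivity`, `specificity`, `accuracy`, `confusion`) and
#'   `importance` (decreasing mean decrease in Gini).
#' @export
train_particle_classifier <- function(records, n_trees = 1000,
                                      vars_per_split = 2, seed = 1L) {
  need <- c(.classifier_features, "label")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("particle table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lab <- records$label
  if (any(!lab %in% c("synthetic", "natural")))
    stop("training labels must be 'synthetic' or 'natural' (drop unknowns ",
         "before training)", call. = FALSE)
  if (length(unique(lab)) < 2L)
    stop("training data contain a single class; need both 'synthetic' and ",
         "'natural'", call. = FALSE)
  if (any(records$length_um <= 0))
    stop("`length_um` must be positive", call. = FALSE)

  x <- .as_factor_frame(records)
  y <- factor(lab, levels = c("natural", "synthetic"))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    mtry = vars_per_split, importance = TRUE)

  conf_oob <- table(truth = y, predicted = fit$predicted)[
    c("synthetic", "natural"), c("synthetic", "natural")]
  pred_resub <- predict(fit, x)
  conf_res <- table(truth = y, predicted = pred_resub)[
    c("synthetic", "natural"), c("synthetic", "natural")]
  imp <- fit$importance[, "MeanDecreaseGini"]
  report <- list(oob = .report_from_confusion(conf_oob),
                 resub = .report_from_confusion(conf_res),
                 importance = sort(imp, decreasing = TRUE))

  structure(list(forest = fit,
                 levels = lapply(x[setdiff(.classifier_features, "length_um")],
                                 levels),
                 n_trees = n_trees, vars_per_split = vars_per_split,
                 seed = seed, report = report,
                 version = as.character(packageVersion("mpfoodweb"))),
            class = "particle_classifier")
}

#' Assign synthetic/natural labels to unknown particles
#'
#' Particles that already carry a spectroscopy label are never relabelled;
#' `"unknown"` rows receive the forest's majority vote. Ties are broken toward
#' `"natural"` by default (conservative for contamination claims).
#'
#' @param model A [train_particle_classifier()] fit.
#' @param records Particle table; rows with `label == "unknown"` are
#'   classified.
#' @param tie_break Class assigned when the vote is exactly split.
#' @return `records` with `label` filled in and a logical column
#'   `label_imputed` marking classifier-assigned rows.
#' @export
classify_unknowns <- function(model, records,
                              tie_break = c("natural", "synthetic")) {
  stopifnot(inherits(model, "particle_classifier"))
  tie_break <- match.arg(tie_break)
  out <- records
  out$label_imputed <- FALSE
  unk <- which(records$label == "unknown")
  if (length(unk) == 0L) return(out)
  x <- .as_factor_frame(records[unk, , drop = FALSE], model$levels)
  p_syn <- predict(model$forest, x, type = "prob")[, "synthetic"]
  lab <- ifelse(p_syn > 0.5, "synthetic",
                ifelse(p_syn < 0.5, "natural", tie_break))
  out$label[unk] <- lab
  out$label_imputed[unk] <- TRUE
  out
}

#' Per-sample synthetic particle counts
#'
#' Pools classified particles across size fractions: one row per sample with
#' the number of particles labelled `"synthetic"`. Samples with no particles
#' at all appear with a count of 0.
#'
#' @param particles Fully labelled particle table (no `"unknown"` left).
#' @param sample_ids Character vector of all sample ids in the study (the
#'   sample universe; defines the output rows).
#' @return Data frame `sample_id`, `mp_count`.
#' @export
aggregate_sample_counts <- function(particles, sample_ids) {
  if (anyDuplicated(sample_ids))
    stop("`sample_ids` must be unique", call. = FALSE)
  dangling <- setdiff(unique(particles$sample_id), sample_ids)
  if (length(dangling) > 0L)
    stop("particles reference nonexistent sample id(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  if (any(particles$label == "unknown"))
    stop("particle table still contains 'unknown' labels; run ",
         "classify_unknowns() first", call. = FALSE)
  syn <- particles[particles$label == "synthetic", , drop = FALSE]
  counts <- table(factor(syn$sample_id, levels = sample_ids))
  data.frame(sample_id = sample_ids, mp_count = as.integer(counts),
             stringsAsFactors = FALSE)
}
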