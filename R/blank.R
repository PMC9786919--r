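## Probabilistic background-contamination correction: observed counts are
## Poisson with mean lambda_sample + lambda_blanks, the blank rate being the
## mean count of procedural blanks run alongside each kind of sample.

#' Blank contamination rates
#'
#' The contamination rate for each blank key (by default the sample type) is
#' the arithmetic mean of the procedural-blank counts carrying that key.
#'
#' @param blanks Data frame with columns `blank_key` and `count`
#'   (non-negative integers), one row per procedural blank.
#' @return A `blank_model`: data frame `blank_key`, `lambda_blank`, `n_blanks`,
#'   with the source counts kept as an attribute.
#' @export
blank_rate <- function(blanks) {
  if (!all(c("blank_key", "count") %in% names(blanks)))
    stop("`blanks` needs columns `blank_key` and `count`", call. = FALSE)
  if (nrow(blanks) == 0L) stop("empty blank table", call. = FALSE)
  if (!is_count_vector(blanks$count))
    stop("blank counts must be non-negative integers", call. = FALSE)
  agg <- aggregate(count ~ blank_key, data = blanks,
                   FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(blank_key = agg$blank_key,
                    lambda_blank = agg$count[, 1L],
                    n_blanks = as.integer(agg$count[, 2L]),
                    stringsAsFactors = FALSE)
  attr(out, "source_counts") <- split(blanks$count, blanks$blank_key)
  class(out) <- c("blank_model", "data.frame")
  out
}

#' Look up the blank rate for a vector of keys
#' @param model A [blank_rate()] model, or `NULL` for no correction.
#' @param keys Character vector of blank keys.
#' @return Numeric vector of contamination rates (0 when `model` is `NULL`).
#' @export
blank_lambda <- function(model, keys) {
  if (is.null(model)) return(rep(0, length(keys)))
  stopifnot(inherits(model, "blank_model"))
  i <- match(keys, model$blank_key)
  if (anyNA(i))
    stop("no blank rate for key(s): ",
         paste(unique(keys[is.na(i)]), collapse = ", "), call. = FALSE)
  model$lambda_blank[i]
}

#' Blank-corrected Poisson log likelihood
#'
#' Log Poisson probability of a count whose mean is the sum of the true sample
#' rate and the blank contamination rate.
#'
#' @param count Non-negative integer count(s).
#' @param lambda_sample True sample rate(s), >= 0.
#' @param lambda_blank Contamination rate(s), >= 0.
#' @return Log density; `-Inf` when the count is positive but the total rate
#'   is zero.
#' @export
poisson_blank_loglik <- function(count, lambda_sample, lambda_blank) {
  if (any(count < 0) || any(count != round(count)))
    stop("`count` must be non-negative integers", call. = FALSE)
  if (any(lambda_sample < 0)) stop("`lambda_sample` must be >= 0",
                                   call. = FALSE)
  if (any(lambda_blank < 0)) stop("`lambda_blank` must be >= 0",
                                  call. = FALSE)
  dpois(count, lambda_sample + lambda_blank, log = TRUE)
}
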