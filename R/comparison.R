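# Posterior contrasts between independently fitted conditions. Because each
# condition is fitted in its own model, difference posteriors pair draws at
# random (fixed seed) under an independence assumption; sample-mean-C
# contrasts are participant-matched within each paired draw.

#' Region of practical equivalence
#'
#' @param lower lower bound (may be `-Inf`); in Hz for capacity contrasts.
#' @param upper upper bound, finite.
#' @return object of class `rope_spec`.
#' @export
rope_spec <- function(lower = -Inf, upper = 5) {
  if (!is.finite(upper) || !(lower < upper)) stop("need lower < upper, finite upper")
  structure(list(lower = lower, upper = upper), class = "rope_spec")
}

#' Default ROPE for attentional-weight contrasts
#'
#' Weights within 0.025 of the even split 0.5 are treated as practically
#' equivalent to uniform attention.
#'
#' @return a [rope_spec()] on the weight scale, [0.475, 0.525].
#' @export
rope_spec_weight <- function() rope_spec(0.475, 0.525)

#' Posterior difference of a quantity between two condition fits
#'
#' Computes per-draw differences A - B of the chosen quantity. For
#' `sample_mean_C` the difference is participant-matched: per paired draw,
#' the average over participants of C_i^A - C_i^B (in Hz). Draws are paired
#' at random across the two fits (both were sampled independently); with
#' unequal draw counts the larger set is subsampled without replacement.
#'
#' @param fit_a,fit_b `tvatoj_fit` objects for the two conditions.
#' @param quantity `"sample_mean_C"`, `"population_C"`, or `"mean_w"`.
#' @param seed integer seed for the draw pairing.
#' @param mass HDI mass for the summary.
#' @return object of class `contrast_result`: `difference_draws`, `mean`,
#'   `hdi_low`, `hdi_high`, `quantity`, `conditions`.
#' @export
condition_difference <- function(fit_a, fit_b,
                                 quantity = c("sample_mean_C",
                                              "population_C", "mean_w"),
                                 seed = 1L, mass = 0.95) {
  quantity <- match.arg(quantity)
  if (quantity == "sample_mean_C" &&
      !identical(fit_a$participants, fit_b$participants)) {
    stop("participant sets differ between fits")
  }
  if (quantity == "sample_mean_C") {
    # participants x pooled-draws matrices, Hz
    da <- t(hz(matrix(fit_a$C, ncol = dim(fit_a$C)[3])))
    db <- t(hz(matrix(fit_b$C, ncol = dim(fit_b$C)[3])))
    pair <- .pair_draws(ncol(da), ncol(db), seed)
    diff_draws <- colMeans(da[, pair$a, drop = FALSE] -
                           db[, pair$b, drop = FALSE])
  } else {
    a <- posterior_draws(fit_a, quantity)
    b <- posterior_draws(fit_b, quantity)
    pair <- .pair_draws(length(a), length(b), seed)
    diff_draws <- a[pair$a] - b[pair$b]
  }
  h <- hdi(diff_draws, mass)
  structure(list(difference_draws = diff_draws, mean = mean(diff_draws),
                 hdi_low = h[1], hdi_high = h[2], mass = mass,
                 quantity = quantity,
                 conditions = c(fit_a$condition, fit_b$condition)),
            class = "contrast_result")
}

# pairing for two independently sampled draw sets: a common random
# permutation (any fixed matching of independent draws is exchangeable);
# with unequal counts the larger set is subsampled without replacement
.pair_draws <- function(n_a, n_b, seed) {
  withr_seed(seed, {
    if (n_a == n_b) {
      p <- sample.int(n_a)
      list(a = p, b = p)
    } else {
      m <- min(n_a, n_b)
      list(a = sample(n_a, m), b = sample(n_b, m))
    }
  })
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast %s - %s (%s): mean %.4g, %d%% HDI [%.4g, %.4g]\n",
              x$conditions[1], x$conditions[2], x$quantity, x$mean,
              round(100 * x$mass), x$hdi_low, x$hdi_high))
  invisible(x)
}

#' Posterior-mass ratio above vs within a ROPE
#'
#' Ratio of the posterior mass strictly above the ROPE's upper bound to the
#' mass inside (lower, upper]. When no draws fall inside the ROPE the ratio
#' is undefined and an "all-above" flag is returned instead of a number.
#'
#' @param contrast a `contrast_result`, or a numeric draw vector.
#' @param rope a [rope_spec()].
#' @return list with `ratio` (numeric or `Inf` when flagged), `all_above`
#'   (logical), `n_above`, `n_within`, `n_below`.
#' @export
rope_ratio <- function(contrast, rope = rope_spec()) {
  draws <- if (inherits(contrast, "contrast_result")) {
    contrast$difference_draws
  } else as.numeric(contrast)
  if (length(draws) == 0L) stop("no draws")
  stopifnot(inherits(rope, "rope_spec"))
  n_above <- sum(draws > rope$upper)
  n_within <- sum(draws > rope$lower & draws <= rope$upper)
  n_below <- length(draws) - n_above - n_within
  if (n_within == 0L) {
    return(list(ratio = Inf, all_above = TRUE, n_above = n_above,
                n_within = 0L, n_below = n_below))
  }
  list(ratio = n_above / n_within, all_above = FALSE, n_above = n_above,
       n_within = n_within, n_below = n_below)
}

#' Qualitative evidence category for a posterior-odds ratio
#'
#' Conventional classification ladder for evidence strength: ratios of 1 are
#' no evidence; (1, 3] anecdotal; (3, 10] moderate; (10, 30] strong;
#' (30, 100] very strong; above 100 extreme. Ratios below 1 are labelled for
#' the complementary direction by the reciprocal.
#'
#' @param ratio non-negative ratio, or the list returned by [rope_ratio()].
#' @return character label; reciprocal categories get the suffix
#'   `" (favors within)"`.
#' @export
evidence_label <- function(ratio) {
  if (is.list(ratio)) {
    if (isTRUE(ratio$all_above)) return("extreme (all draws above)")
    ratio <- ratio$ratio
  }
  if (!is.finite(ratio) || ratio < 0) {
    if (is.infinite(ratio) && ratio > 0) return("extreme (all draws above)")
    stop("ratio must be non-negative")
  }
  ladder <- function(r) {
    if (r <= 3) "anecdotal" else if (r <= 10) "moderate"
    else if (r <= 30) "strong" else if (r <= 100) "very strong"
    else "extreme"
  }
  if (ratio == 1) return("no evidence")
  if (ratio > 1) ladder(ratio) else paste0(ladder(1 / ratio), " (favors within)")
}
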