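# Non-model behavioral analyses: categorization contingency tables,
# careless-responder exclusion, deferred-response ("show again later")
# usage, and the capacity-difference vs judgment-performance correlation.

# round half-up at `digits` decimals (report parity; R's round() rounds
# half-to-even)
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Contingency tables of categorization correctness
#'
#' Builds frequency tables of correct vs false categorization responses,
#' split by stimulus color and optionally by the width-to-height-ratio
#' difficulty, with row totals and row percentages (rounded half-up to two
#' decimals).
#'
#' @param trials trial table with columns `stimulus_color`,
#'   `ratio_difficulty` (optional for the color-only table) and
#'   `query_correct`; rows with `NA` query outcomes are dropped.
#' @param by `"color"` or `"color_difficulty"`.
#' @return data frame with columns `color` (and `difficulty`), `n_false`,
#'   `n_correct`, `total`, `pct_false`, `pct_correct`.
#' @export
contingency_tables <- function(trials, by = c("color", "color_difficulty")) {
  by <- match.arg(by)
  q <- trials[!is.na(trials$query_correct), , drop = FALSE]
  if (nrow(q) == 0L) stop("no query outcomes present")
  keys <- if (by == "color") list(color = q$stimulus_color)
          else list(color = q$stimulus_color,
                    difficulty = q$ratio_difficulty)
  agg <- stats::aggregate(cbind(n_correct = q$query_correct,
                                total = rep(1L, nrow(q))),
                          by = keys, FUN = sum)
  agg$n_false <- agg$total - agg$n_correct
  agg$pct_correct <- round_half_up(100 * agg$n_correct / agg$total)
  agg$pct_false <- round_half_up(100 * agg$n_false / agg$total)
  cols <- c(names(keys), "n_false", "n_correct", "total",
            "pct_false", "pct_correct")
  ord <- if (by == "color") order(agg$color)
         else order(agg$color, agg$difficulty)
  out <- agg[ord, cols]
  rownames(out) <- NULL
  out
}

#' Contingency table from raw counts
#'
#' Same report layout as [contingency_tables()] but starting from already
#' tabulated counts (e.g. a printed table entered directly).
#'
#' @param counts data frame with grouping columns plus `n_false` and
#'   `n_correct`.
#' @return `counts` with added `total`, `pct_false`, `pct_correct`.
#' @export
contingency_from_counts <- function(counts) {
  stopifnot(all(c("n_false", "n_correct") %in% names(counts)))
  counts$total <- counts$n_false + counts$n_correct
  counts$pct_false <- round_half_up(100 * counts$n_false / counts$total)
  counts$pct_correct <- round_half_up(100 * counts$n_correct / counts$total)
  counts
}

#' Flag careless responders from order-judgment accuracy
#'
#' A response is correct when it names the truly first stimulus (probe for
#' negative SOAs, reference for positive; SOA 0 has no defined correct
#' answer and is excluded). Accuracy is pooled within each absolute-SOA
#' level. A participant is flagged as careless when, at every nonzero
#' |SOA| level, an exact two-sided binomial test against chance (0.5) is
#' non-significant. The familywise level `alpha` is split evenly across the
#' |SOA| levels (Bonferroni), so "indistinguishable from chance everywhere"
#' is tested as a single claim per participant.
#'
#' @param trials trial table with `participant`, `soa_ms`, `probe_first`.
#' @param alpha familywise significance level, default 0.05.
#' @return data frame (one row per participant x |SOA| level) of class
#'   `exclusion_report` with attributes; columns `participant`, `abs_soa`,
#'   `n`, `n_correct`, `accuracy`, `p_value`, plus per-participant `flagged`
#'   in `attr(, "flags")` (data frame `participant`, `flagged`,
#'   `assessable`).
#' @export
exclude_careless <- function(trials, alpha = 0.05) {
  nz <- trials[trials$soa_ms != 0, , drop = FALSE]
  all_ids <- unique(trials$participant)
  if (nrow(nz) == 0L) stop("trials include no nonzero SOAs")
  correct <- ifelse(nz$soa_ms < 0, nz$probe_first == 1L,
                    nz$probe_first == 0L)
  lev <- abs(nz$soa_ms)
  agg <- stats::aggregate(cbind(n_correct = as.integer(correct),
                                n = rep(1L, nrow(nz))),
                          by = list(participant = nz$participant,
                                    abs_soa = lev),
                          FUN = sum)
  n_levels <- length(unique(agg$abs_soa))
  alpha_level <- alpha / n_levels
  agg$accuracy <- agg$n_correct / agg$n
  agg$p_value <- mapply(function(k, n) {
    stats::binom.test(k, n, 0.5)$p.value
  }, agg$n_correct, agg$n)
  flags <- do.call(rbind, lapply(all_ids, function(id) {
    rows <- agg[agg$participant == id, , drop = FALSE]
    if (nrow(rows) == 0L) {
      data.frame(participant = id, flagged = FALSE, assessable = FALSE)
    } else {
      data.frame(participant = id,
                 flagged = all(rows$p_value > alpha_level),
                 assessable = TRUE)
    }
  }))
  agg <- agg[order(agg$participant, agg$abs_soa), ]
  rownames(agg) <- NULL
  structure(agg, flags = flags, alpha = alpha,
            alpha_per_level = alpha_level,
            class = c("exclusion_report", "data.frame"))
}

#' Participants flagged as careless
#'
#' @param report an `exclusion_report` from [exclude_careless()].
#' @return character vector of flagged participant ids.
#' @export
flagged_participants <- function(report) {
  flags <- attr(report, "flags")
  flags$participant[flags$flagged]
}

#' Summary of "show again later" usage
#'
#' @param trials trial table with a `sal_used` column (NA off query trials).
#' @return list: `n_users` (participants with >= 1 use), `mean_uses` among
#'   users (`NA` when none), `min_uses`, `max_uses`, `opportunities` (query
#'   judgments per participant, the denominator the usage range refers to).
#' @export
sal_usage_summary <- function(trials) {
  if (!"sal_used" %in% names(trials)) stop("no sal_used column present")
  on_q <- !is.na(trials$sal_used)
  uses <- tapply(trials$sal_used[on_q], trials$participant[on_q], sum)
  opp <- tapply(trials$sal_used[on_q], trials$participant[on_q], length)
  users <- uses[uses > 0]
  list(n_users = length(users),
       mean_uses = if (length(users)) mean(users) else NA_real_,
       min_uses = if (length(users)) min(users) else NA_integer_,
       max_uses = if (length(users)) max(users) else NA_integer_,
       opportunities = if (length(opp)) round(mean(opp)) else 0L)
}

#' Correlate capacity differences with judgment performance
#'
#' Pearson correlation between per-participant capacity-difference point
#' estimates and categorization accuracy, with an optional Bayes factor for
#' a non-zero correlation under a uniform prior on the correlation
#' coefficient (Jeffreys's exact integral form).
#'
#' @param c_diff numeric vector of per-participant C differences.
#' @param performance matched numeric vector of judgment accuracy.
#' @param bayes_factor also compute BF10.
#' @return list with `r`, `n`, and optionally `bf10` and `prior`.
#' @export
correlate_diff_performance <- function(c_diff, performance,
                                       bayes_factor = TRUE) {
  if (length(c_diff) != length(performance)) stop("vectors must match")
  if (length(c_diff) < 3) stop("need at least 3 participants")
  if (stats::sd(c_diff) == 0 || stats::sd(performance) == 0) {
    stop("zero-variance input")
  }
  r <- stats::cor(c_diff, performance)
  out <- list(r = r, n = length(c_diff))
  if (bayes_factor) {
    out$bf10 <- .correlation_bf10(r, length(c_diff))
    out$prior <- "uniform on rho in (-1, 1)"
  }
  out
}

# BF10 for a Pearson correlation under a uniform prior on rho: marginal
# likelihood ratio integral( f(r | rho) drho ) / f(r | 0), with the
# sampling density approximated through the exact likelihood kernel
# (1 - rho^2)^((n-1)/2) / (1 - rho * r)^(n - 3/2) (Jeffreys's form).
.correlation_bf10 <- function(r, n) {
  kernel <- function(rho) {
    exp(((n - 1) / 2) * log1p(-rho^2) - (n - 3 / 2) * log1p(-rho * r))
  }
  num <- stats::integrate(kernel, -1, 1)$value / 2  # uniform prior density 1/2
  num / kernel(0)
}
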