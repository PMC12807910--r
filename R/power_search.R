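# Simulation-based Bayesian power search: for each candidate sample size,
# repeatedly simulate two conditions at configured true parameters, fit each
# with a reduced-fidelity profile, and ask whether the capacity-contrast HDI
# excludes a minimal meaningful difference. Power is the success fraction
# with a Beta(1, 1)-posterior credible interval.

#' Power-search configuration
#'
#' @param pop_a,pop_b [population_spec()]s for the two conditions being
#'   contrasted (their `C_mu` difference is the true effect).
#' @param design a [design_spec()]; its `n_participants` is overridden by
#'   each candidate n.
#' @param candidate_n strictly increasing integer sample sizes.
#' @param replicates simulated datasets per candidate n.
#' @param exclude_below success requires the contrast HDI to lie entirely
#'   above this bound (Hz); the minimal difference considered
#'   indistinguishable from zero.
#' @param target_power required success probability.
#' @param fit a [fit_config()] for the inner fits (reduced fidelity by
#'   default).
#' @param hdi_mass HDI mass for the success rule.
#' @param seed master seed.
#' @return object of class `power_config`.
#' @export
power_config <- function(pop_a, pop_b, design = design_spec(),
                         candidate_n = c(10, 20, 40),
                         replicates = 20, exclude_below = 0,
                         target_power = 0.8,
                         fit = fit_config("power"),
                         hdi_mass = 0.95, seed = 1L) {
  stopifnot(inherits(pop_a, "population_spec"),
            inherits(pop_b, "population_spec"),
            inherits(design, "design_spec"), inherits(fit, "fit_config"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.unsorted(candidate_n, strictly = TRUE)) {
    stop("candidate_n must be strictly increasing")
  }
  structure(list(pop_a = pop_a, pop_b = pop_b, design = design,
                 candidate_n = as.integer(candidate_n),
                 replicates = as.integer(replicates),
                 exclude_below = exclude_below,
                 target_power = target_power, fit = fit,
                 hdi_mass = hdi_mass, seed = as.integer(seed)),
            class = "power_config")
}

# one simulate -> fit -> evaluate replicate; returns "success", "failure",
# or "fit_error"
.power_replicate <- function(config, n, seed) {
  seeds <- derive_seeds(seed, 5)
  # one single-condition design per arm: the contrast is between the two
  # configured populations, each generating one condition's data
  arm_design <- function(cond) {
    d <- config$design
    d$n_participants <- n
    d$conditions <- cond
    d
  }
  conds <- rep_len(config$design$conditions, 2)
  sim <- function(pop, cond, s1, s2) {
    d <- arm_design(cond)
    params <- simulate_participants(pop, d, s1)
    params$careless <- FALSE  # power target is the attentive population
    simulate_trials(params, d, s2)
  }
  res <- tryCatch({
    ta <- sim(config$pop_a, conds[1], seeds[1], seeds[2])
    tb <- sim(config$pop_b, conds[2], seeds[3], seeds[4])
    cfg <- config$fit; cfg$seed <- seeds[5]
    fa <- fit_tva_toj(ta, cfg)
    fb <- fit_tva_toj(tb, cfg)
    ct <- condition_difference(fa, fb, "sample_mean_C", seed = seeds[5],
                               mass = config$hdi_mass)
    if (ct$hdi_low > config$exclude_below) "success" else "failure"
  }, error = function(e) "fit_error")
  res
}

# highest-density interval of a Beta(a, b) posterior; contains the mode
# (a-1)/(a+b-2), which equals the success fraction under the uniform prior
.beta_hdi <- function(a, b, mass = 0.95) {
  width <- function(p) {
    stats::qbeta(p + mass, a, b) - stats::qbeta(p, a, b)
  }
  if (a <= 1) return(c(0, stats::qbeta(mass, a, b)))
  if (b <= 1) return(c(stats::qbeta(1 - mass, a, b), 1))
  opt <- stats::optimize(width, c(0, 1 - mass))
  c(stats::qbeta(opt$minimum, a, b), stats::qbeta(opt$minimum + mass, a, b))
}

#' Run the power search
#'
#' @param config a [power_config()].
#' @param verbose print progress per candidate n.
#' @return object of class `power_result`: data frame `per_n` (columns `n`,
#'   `successes`, `failures`, `fit_errors`, `replicates`, `power`,
#'   `ci_low`, `ci_high`) plus `minimum_n` (smallest n whose power estimate
#'   meets the target, `NA` when none does) and the config. The credible
#'   interval is the 95% highest-density interval of the Beta(1 + s, 1 + f)
#'   posterior (uniform prior), which always contains the success fraction;
#'   fit errors are reported separately and excluded from the power
#'   denominator.
#' @export
run_power_search <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "power_config"))
  rep_seeds <- matrix(
    derive_seeds(config$seed, config$replicates * length(config$candidate_n)),
    nrow = config$replicates)
  per_n <- lapply(seq_along(config$candidate_n), function(ci) {
    n <- config$candidate_n[ci]
    out <- vapply(seq_len(config$replicates), function(r) {
      .power_replicate(config, n, rep_seeds[r, ci])
    }, character(1))
    s <- sum(out == "success"); f <- sum(out == "failure")
    err <- sum(out == "fit_error")
    denom <- s + f
    pw <- if (denom > 0) s / denom else NA_real_
    ci95 <- if (denom > 0) .beta_hdi(1 + s, 1 + f, 0.95)
            else c(NA_real_, NA_real_)
    if (verbose) {
      message(sprintf("n = %d: power %.2f [%.2f, %.2f] (%d errors)",
                      n, pw, ci95[1], ci95[2], err))
    }
    data.frame(n = n, successes = s, failures = f, fit_errors = err,
               replicates = config$replicates, power = pw,
               ci_low = ci95[1], ci_high = ci95[2])
  })
  per_n <- do.call(rbind, per_n)
  meets <- which(!is.na(per_n$power) & per_n$power >= config$target_power)
  structure(list(per_n = per_n,
                 minimum_n = if (length(meets)) per_n$n[min(meets)] else NA_integer_,
                 config = config),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  print(x$per_n, row.names = FALSE)
  cat(sprintf("minimum n meeting target power %.2f: %s\n",
              x$config$target_power,
              ifelse(is.na(x$minimum_n), "none found", x$minimum_n)))
  invisible(x)
}
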