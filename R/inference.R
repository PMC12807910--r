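# Hierarchical Bayesian estimation of attentional capacity and weight.
#
# Priors (non-centered): C_mu ~ Normal(-3, 1) on log capacity per ms (median
# about 49.8 Hz), C_sigma ~ HalfNormal(0.5), C_e[i] ~ Normal(0, 1) with
# C_i = exp(C_mu + C_sigma * C_e[i]); w_i ~ Beta(1, 1), no pooling across
# participants for w. Likelihood: per (participant, SOA) cell, the
# probe-first count is binomial with the closed-form race probability.
# Sampling is MCMC via JAGS (rjags); diagnostics via coda.

.jags_model_string <- "
model {
  Cmu ~ dnorm(-3, 1)
  Csigma ~ dnorm(0, 4) T(0,)
  for (i in 1:I) {
    Ce[i] ~ dnorm(0, 1)
    C[i] <- exp(Cmu + Csigma * Ce[i])
    w[i] ~ dbeta(1, 1)
  }
  for (j in 1:J) {
    vp[j] <- C[pid[j]] * w[pid[j]]
    vr[j] <- C[pid[j]] * (1 - w[pid[j]])
    praw[j] <- ifelse(soa[j] < 0,
      1 - exp(-vp[j] * abs(soa[j])) + exp(-vp[j] * abs(soa[j])) * w[pid[j]],
      exp(-vr[j] * abs(soa[j])) * w[pid[j]])
    p[j] <- max(1.0E-12, min(1 - 1.0E-12, praw[j]))
    k[j] ~ dbin(p[j], n[j])
  }
}"

.jags_prior_string <- "
model {
  Cmu ~ dnorm(-3, 1)
  Csigma ~ dnorm(0, 4) T(0,)
  for (i in 1:I) {
    Ce[i] ~ dnorm(0, 1)
    C[i] <- exp(Cmu + Csigma * Ce[i])
    w[i] ~ dbeta(1, 1)
  }
}"

#' Sampler configuration
#'
#' The `full` profile mirrors the study analysis (4 chains, 16,000 warm-up
#' iterations, 24,000 retained draws); the `test` profile (2 chains, 500
#' warm-up, 1,000 draws) is for desk-scale validation and CI, and the `power`
#' profile (1 chain, 300 warm-up, 600 draws) for the inner loop of the power
#' search.
#'
#' @param profile one of "full", "test", "power", or "custom".
#' @param chains,tuning_draws,posterior_draws MCMC dimensions (per chain for
#'   draws); override the profile when given.
#' @param seed integer seed for the sampler RNG.
#' @param rhat_threshold,ess_threshold convergence gates for
#'   [check_diagnostics()].
#' @return object of class `fit_config`.
#' @export
fit_config <- function(profile = c("test", "full", "power", "custom"),
                       chains = NULL, tuning_draws = NULL,
                       posterior_draws = NULL, seed = 1L,
                       rhat_threshold = 1.01, ess_threshold = 400) {
  profile <- match.arg(profile)
  def <- switch(profile,
    full  = list(chains = 4L, tune = 16000L, draws = 24000L),
    test  = list(chains = 2L, tune = 500L,   draws = 1000L),
    power = list(chains = 1L, tune = 300L,   draws = 600L),
    custom = list(chains = 2L, tune = 500L,  draws = 1000L))
  cfg <- list(profile = profile,
              chains = as.integer(chains %||% def$chains),
              tuning_draws = as.integer(tuning_draws %||% def$tune),
              posterior_draws = as.integer(posterior_draws %||% def$draws),
              seed = as.integer(seed),
              rhat_threshold = rhat_threshold,
              ess_threshold = ess_threshold)
  if (cfg$chains < 1 || cfg$tuning_draws < 1 || cfg$posterior_draws < 1) {
    stop("chains, tuning_draws and posterior_draws must be positive")
  }
  structure(cfg, class = "fit_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# aggregate a trial table into per-(participant, SOA) binomial cells
aggregate_counts <- function(trials) {
  stopifnot(all(c("participant", "soa_ms", "probe_first") %in% names(trials)))
  agg <- stats::aggregate(
    cbind(k_probe_first = trials$probe_first,
          n_trials = rep(1L, nrow(trials))),
    by = list(participant = trials$participant, soa = trials$soa_ms),
    FUN = sum)
  agg[order(agg$participant, agg$soa), ]
}

#' Fit the hierarchical TVA-TOJ model to one condition's trials
#'
#' @param trials trial table for a single condition (columns `participant`,
#'   `soa_ms`, `probe_first`); pass each condition separately.
#' @param config a [fit_config()].
#' @param prior_only if TRUE, sample from the priors alone (the likelihood is
#'   dropped); used for prior-predictive checks.
#' @param quiet suppress JAGS progress output.
#' @return object of class `tvatoj_fit`: posterior arrays `C_mu`, `C_sigma`
#'   (iterations x chains), `C`, `w` (iterations x chains x participant,
#'   events/ms for C), participant ids, diagnostics, the data cells, and the
#'   config.
#' @export
fit_tva_toj <- function(trials, config = fit_config(), prior_only = FALSE,
                        quiet = TRUE) {
  stopifnot(inherits(config, "fit_config"))
  if (!prior_only) {
    if (nrow(trials) == 0L) stop("no trials supplied")
    if (length(unique(trials$condition %||% "")) > 1L) {
      stop("fit one condition at a time; split the table by condition")
    }
    cells <- aggregate_counts(trials)
    n_soa <- tapply(cells$soa, cells$participant,
                    function(s) length(unique(s)))
    if (any(n_soa < 2)) {
      stop("every participant needs trials at >= 2 distinct SOAs")
    }
    participants <- sort(unique(cells$participant))
    dat <- list(I = length(participants), J = nrow(cells),
                pid = match(cells$participant, participants),
                soa = cells$soa, n = cells$n_trials, k = cells$k_probe_first)
    model_str <- .jags_model_string
  } else {
    participants <- sort(unique(trials$participant))
    if (length(participants) == 0L) participants <- sprintf("p%02d", 1:8)
    cells <- NULL
    dat <- list(I = length(participants))
    model_str <- .jags_prior_string
  }
  inits <- lapply(seq_len(config$chains), function(ch) {
    # fold the (possibly large) seed and chain index into the 31-bit range
    s <- (as.numeric(config$seed) * 1000 + ch) %% 2147483646 + 1
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = as.integer(s))
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = config$chains,
                          n.adapt = max(100L, config$tuning_draws %/% 2L),
                          quiet = quiet)
  pb <- if (quiet) "none" else "text"
  stats::update(jm, config$tuning_draws, progress.bar = pb)
  samp <- rjags::coda.samples(jm, c("Cmu", "Csigma", "C", "w"),
                              n.iter = config$posterior_draws,
                              progress.bar = pb)
  fit <- .fit_from_mcmc(samp, participants, config)
  fit$cells <- cells
  fit$condition <- if (!is.null(trials$condition)) {
    unique(trials$condition)[1]
  } else NA_character_
  fit$prior_only <- prior_only
  fit
}

# reshape a coda mcmc.list into named posterior arrays + diagnostics
.fit_from_mcmc <- function(samp, participants, config) {
  mats <- lapply(samp, as.matrix)
  vn <- colnames(mats[[1]])
  n_it <- nrow(mats[[1]]); n_ch <- length(mats)
  pick <- function(pattern) {
    cols <- grep(pattern, vn, value = TRUE)
    arr <- array(NA_real_, c(n_it, n_ch, length(cols)))
    for (ch in seq_len(n_ch)) arr[, ch, ] <- mats[[ch]][, cols]
    dimnames(arr) <- list(NULL, NULL, participants)
    arr
  }
  scalar <- function(name) {
    sapply(mats, function(m) m[, name])  # iterations x chains
  }
  diag_vars <- c("Cmu", "Csigma")
  sub <- samp[, diag_vars, drop = FALSE]
  rhat <- tryCatch(
    coda::gelman.diag(sub, multivariate = FALSE,
                      autoburnin = FALSE)$psrf[, 1],
    error = function(e) stats::setNames(rep(NA_real_, 2), diag_vars))
  ess <- coda::effectiveSize(sub)
  structure(list(C_mu = scalar("Cmu"), C_sigma = scalar("Csigma"),
                 C = pick("^C\\["), w = pick("^w\\["),
                 participants = participants,
                 diagnostics = list(rhat = rhat, ess = ess),
                 config = config),
            class = "tvatoj_fit")
}

#' @export
print.tvatoj_fit <- function(x, ...) {
  cat(sprintf("Hierarchical TVA-TOJ fit: %d participants, %d chains x %d draws\n",
              length(x$participants), ncol(x$C_mu), nrow(x$C_mu)))
  s <- summarize_posterior(x, "population_C")
  cat(sprintf("  population C: %.1f Hz [%.1f, %.1f]\n",
              s$mean, s$hdi_low, s$hdi_high))
  s <- summarize_posterior(x, "mean_w")
  cat(sprintf("  mean w: %.3f [%.3f, %.3f]\n", s$mean, s$hdi_low, s$hdi_high))
  invisible(x)
}

#' Convergence gate
#'
#' Declares a fit converged only when all monitored split-chain R-hat values
#' are below the configured threshold and effective sample sizes above it.
#' Non-convergence is reported with a warning, never silently.
#'
#' @param fit a `tvatoj_fit`.
#' @param warn emit a warning when the gate fails.
#' @return logical.
#' @export
check_diagnostics <- function(fit, warn = TRUE) {
  rhat <- fit$diagnostics$rhat; ess <- fit$diagnostics$ess
  ok <- all(is.na(rhat) | rhat < fit$config$rhat_threshold) &&
        all(ess > fit$config$ess_threshold)
  if (!ok && warn) {
    warning(sprintf(
      "convergence gate failed: max rhat %.3f, min ess %.0f",
      max(rhat, na.rm = TRUE), min(ess)), call. = FALSE)
  }
  ok
}

#' Extract a scalar posterior quantity as a draw vector
#'
#' Quantities: `"population_C"` — exp(C_mu), the location of the capacity
#' lognormal, in Hz; `"sample_mean_C"` — per-draw average of the individual
#' C_i, in Hz; `"C_mu"`, `"C_sigma"` — raw hyperparameters (log-ms scale);
#' `"mean_w"` — per-draw average of the individual w_i; `"C[i]"` / `"w[i]"`
#' — an individual participant, selected via `participant`.
#'
#' @param fit a `tvatoj_fit`.
#' @param quantity character label, see above.
#' @param participant participant id for individual quantities.
#' @return numeric vector of pooled (all-chain) draws.
#' @export
posterior_draws <- function(fit, quantity, participant = NULL) {
  flat <- function(a) as.vector(a)  # iterations x chains -> pooled
  idx <- function() {
    if (is.null(participant)) stop("participant required for this quantity")
    i <- match(participant, fit$participants)
    if (is.na(i)) stop("unknown participant: ", participant)
    i
  }
  switch(quantity,
    population_C  = hz(exp(flat(fit$C_mu))),
    sample_mean_C = hz(apply(fit$C, c(1, 2), mean)) |> as.vector(),
    C_mu          = flat(fit$C_mu),
    C_sigma       = flat(fit$C_sigma),
    mean_w        = as.vector(apply(fit$w, c(1, 2), mean)),
    C             = hz(as.vector(fit$C[, , idx()])),
    w             = as.vector(fit$w[, , idx()]),
    stop("unknown quantity label: ", quantity))
}

#' Highest-density interval of a draw vector
#'
#' Narrowest contiguous interval of the sorted draws containing the stated
#' probability mass (exact for unimodal posteriors).
#'
#' @param draws numeric vector.
#' @param mass probability mass, default 0.95.
#' @return numeric length-2 vector (lower, upper).
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(length(draws) >= 1, mass > 0, mass <= 1)
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Summarize a posterior quantity
#'
#' @inheritParams posterior_draws
#' @param mass HDI probability mass.
#' @return object of class `posterior_summary`: list with `quantity`,
#'   `draws`, `mean`, `hdi_low`, `hdi_high`, `mass`.
#' @export
summarize_posterior <- function(fit, quantity, participant = NULL,
                                mass = 0.95) {
  d <- posterior_draws(fit, quantity, participant)
  h <- hdi(d, mass)
  structure(list(quantity = quantity, draws = d, mean = mean(d),
                 hdi_low = h[1], hdi_high = h[2], mass = mass),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.4g, %d%% HDI [%.4g, %.4g] (%d draws)\n",
              x$quantity, x$mean, round(100 * x$mass), x$hdi_low,
              x$hdi_high, length(x$draws)))
  invisible(x)
}

#' Per-participant posterior table
#'
#' Forest-plot-style summary: one row per participant with posterior mean
#' and HDI of the chosen individual quantity.
#'
#' @param fit a `tvatoj_fit`.
#' @param quantity `"C"` (Hz) or `"w"`.
#' @param mass HDI mass.
#' @return data frame with `participant`, `mean`, `hdi_low`, `hdi_high`,
#'   `condition`.
#' @export
participant_table <- function(fit, quantity = c("w", "C"), mass = 0.95) {
  quantity <- match.arg(quantity)
  rows <- lapply(fit$participants, function(p) {
    s <- summarize_posterior(fit, quantity, participant = p, mass = mass)
    data.frame(participant = p, mean = s$mean, hdi_low = s$hdi_low,
               hdi_high = s$hdi_high, condition = fit$condition,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior- (or prior-) predictive check
#'
#' Simulates replicate probe-first counts from posterior draws through the
#' race likelihood and reports, per (participant, SOA) cell, the observed
#' proportion, the central 95% predictive interval, and overall coverage
#' (fraction of cells whose observation falls inside its interval).
#'
#' @param fit a fitted `tvatoj_fit` (with data cells).
#' @param n_rep number of replicate datasets.
#' @param seed integer seed.
#' @param interval central predictive mass.
#' @return list with `cells` (data frame incl. `obs_prop`, `pred_low`,
#'   `pred_high`, `inside`) and `coverage` (scalar).
#' @export
predictive_check <- function(fit, n_rep = 500, seed = 1L, interval = 0.95) {
  if (is.null(fit$cells)) stop("fit has no data cells (prior-only fit?)")
  cells <- fit$cells
  pid <- match(cells$participant, fit$participants)
  n_draws <- prod(dim(fit$C)[1:2])
  withr_seed(seed, {
    take <- sample.int(n_draws, n_rep, replace = n_rep > n_draws)
    Cm <- matrix(fit$C, nrow = n_draws)[take, , drop = FALSE]
    wm <- matrix(fit$w, nrow = n_draws)[take, , drop = FALSE]
    reps <- sapply(seq_len(n_rep), function(r) {
      p <- p_probe_first_cw(Cm[r, pid], wm[r, pid], cells$soa)
      stats::rbinom(nrow(cells), cells$n_trials, p) / cells$n_trials
    })  # cells x n_rep
    alpha <- (1 - interval) / 2
    qs <- t(apply(reps, 1, stats::quantile, probs = c(alpha, 1 - alpha)))
    cells$obs_prop <- cells$k_probe_first / cells$n_trials
    cells$pred_low <- qs[, 1]; cells$pred_high <- qs[, 2]
    cells$inside <- cells$obs_prop >= cells$pred_low &
                    cells$obs_prop <= cells$pred_high
    list(cells = cells, coverage = mean(cells$inside))
  })
}

#' Prior draws of an individual capacity
#'
#' Samples C_i implied by the non-centered prior (for checking equivalence
#' with the direct lognormal); returned in events/ms.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector.
#' @export
prior_capacity_draws <- function(n, seed = 1L) {
  withr_seed(seed, {
    C_mu <- stats::rnorm(n, -3, 1)
    C_sigma <- abs(stats::rnorm(n, 0, 0.5))
    Ce <- stats::rnorm(n)
    exp(C_mu + C_sigma * Ce)
  })
}
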