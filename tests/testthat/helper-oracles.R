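# Independent oracles and small fixtures shared across tests.

# Monte-Carlo exponential-race oracle: probe and reference encoding times
# are onset + Exponential(rate); the probe onset leads by |soa| when
# soa < 0, trails by soa when soa > 0. Estimates P(probe encoded first).
mc_race_oracle <- function(v_p, v_r, soa, n_draws = 1e6) {
  t_probe <- max(0, soa) + stats::rexp(n_draws, v_p)
  t_ref <- max(0, -soa) + stats::rexp(n_draws, v_r)
  p_hat <- mean(t_probe < t_ref)
  se <- sqrt(p_hat * (1 - p_hat) / n_draws)
  list(p = p_hat, se = se)
}

# grid-search maximum-likelihood oracle over (C, w)
grid_ml_oracle <- function(counts, C_grid, w_grid) {
  ll <- outer(C_grid, w_grid,
              Vectorize(function(C, w) toj_log_likelihood(counts, C, w)))
  idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  list(C = C_grid[idx[1]], w = w_grid[idx[2]])
}

# design grid used throughout
design_soas <- c(-100, -50, -50 / 3, 0, 50 / 3, 50, 100)

# trial table for one participant responding Bernoulli(0.5) at the
# experiment-2 per-SOA counts
make_flat_responder <- function(id = "p01") {
  n_per <- c(28L, 40L, 48L, 48L, 48L, 40L, 28L)
  soa <- rep(design_soas, n_per)
  data.frame(participant = id, experiment = 2L, condition = "2correct",
             soa_ms = soa,
             probe_first = stats::rbinom(length(soa), 1L, 0.5),
             stringsAsFactors = FALSE)
}

# trial table for one genuine race-model responder at the Exp-2 design
make_genuine_responder <- function(id = "p01", C_hz = 50, w = 0.5) {
  n_per <- c(28L, 40L, 48L, 48L, 48L, 40L, 28L)
  soa <- rep(design_soas, n_per)
  p <- p_probe_first_cw(per_ms(C_hz), w, soa)
  data.frame(participant = id, experiment = 2L, condition = "2correct",
             soa_ms = soa,
             probe_first = stats::rbinom(length(soa), 1L, p),
             stringsAsFactors = FALSE)
}

# printed categorization counts shipped with the package
categorization_counts <- function() {
  utils::read.csv(system.file("extdata", "categorization_counts.csv",
                              package = "tvatoj"),
                  stringsAsFactors = FALSE)
}

# quick small-scale fit used by several tests (cached per session)
.cached_small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- population_spec(C_mu = log(0.05), C_sigma = 0.25,
                             careless_fraction = 0)
      des <- design_spec(2, n_participants = 8)
      sim <- simulate_experiment(pop, des, seed = 42, queries = FALSE,
                                 sal = FALSE)
      tr <- sim$trials[sim$trials$condition == "2correct", ]
      cache <<- fit_tva_toj(tr, fit_config("test", seed = 42))
    }
    cache
  }
})
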