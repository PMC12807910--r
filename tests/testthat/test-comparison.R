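# Condition contrasts, ROPE ratios, evidence categories.

# minimal fit-like objects for contrast mechanics (draws filled by hand)
fake_fit <- function(C_hz, w, participants = c("p01", "p02"),
                     n_it = 200, n_ch = 2, jitter = 0, seed = 1) {
  set.seed(seed)
  np <- length(participants)
  Ca <- array(per_ms(C_hz) + jitter * rnorm(n_it * n_ch * np),
              c(n_it, n_ch, np), dimnames = list(NULL, NULL, participants))
  wa <- array(w + jitter * rnorm(n_it * n_ch * np), c(n_it, n_ch, np),
              dimnames = list(NULL, NULL, participants))
  structure(list(C_mu = matrix(log(per_ms(C_hz)), n_it, n_ch),
                 C_sigma = matrix(0.1, n_it, n_ch), C = Ca, w = wa,
                 participants = participants,
                 diagnostics = list(rhat = c(Cmu = 1, Csigma = 1),
                                    ess = c(Cmu = 1e4, Csigma = 1e4)),
                 config = fit_config("test"), condition = "X"),
            class = "tvatoj_fit")
}

test_that("identical posteriors give a zero difference, swapped ones negate", {
  f <- fake_fit(50, 0.5, jitter = 0.002)
  d0 <- condition_difference(f, f, "sample_mean_C", seed = 2)
  expect_true(all(d0$difference_draws == 0))
  expect_equal(c(d0$hdi_low, d0$hdi_high), c(0, 0))
  g <- fake_fit(55, 0.5, jitter = 0.002, seed = 9)
  ab <- condition_difference(f, g, "sample_mean_C", seed = 3)
  ba <- condition_difference(g, f, "sample_mean_C", seed = 3)
  expect_equal(ab$difference_draws, -ba$difference_draws)
  expect_error(condition_difference(
    f, fake_fit(50, 0.5, participants = c("q1", "q2")), "sample_mean_C"),
    "participant sets differ")
})

test_that("contrast of fits recovers a known capacity difference", {
  des <- design_spec(2, n_participants = 10)
  mk <- function(C_hz, seed) {
    pop <- population_spec(C_mu = log(per_ms(C_hz)), C_sigma = 0.2,
                           careless_fraction = 0)
    params <- simulate_participants(pop, des, seed)
    params <- params[params$condition == "2correct", ]
    tr <- simulate_trials(params, design_spec(2, n_participants = 10,
                                              conditions = "2correct"),
                          seed + 1)
    list(fit = fit_tva_toj(tr, fit_config("test", seed = seed)),
         true_mean = mean(hz(params$C)))
  }
  fa <- mk(55, 101); fb <- mk(50, 202)
  truth <- fa$true_mean - fb$true_mean
  ct <- condition_difference(fa$fit, fb$fit, "sample_mean_C", seed = 5)
  expect_lt(abs(ct$mean - truth), 5)
  expect_gt(ct$hdi_high, ct$hdi_low)
})

test_that("rope ratio counts mass above vs within and flags degeneracy", {
  expect_equal(rope_ratio(c(0, 0, 10, 10), rope_spec(-Inf, 5))$ratio, 1)
  r <- rope_ratio(c(6, 7, 8, 9), rope_spec(-Inf, 5))
  expect_true(r$all_above)
  expect_identical(r$n_within, 0L)
  # normal CDF oracle: draws ~ N(6, 4^2), ROPE (-inf, 5]
  set.seed(77)
  d <- rnorm(1e6, 6, 4)
  expected <- pnorm(0.25) / pnorm(-0.25)  # 1.4919
  got <- rope_ratio(d, rope_spec(-Inf, 5))$ratio
  expect_lt(abs(got - expected), 0.01)
  expect_error(rope_ratio(numeric(0)), "no draws")
  # widening the ROPE upward never increases the ratio
  uppers <- c(2, 4, 6, 8)
  ratios <- sapply(uppers, function(u) rope_ratio(d, rope_spec(-Inf, u))$ratio)
  expect_true(all(diff(ratios) <= 0))
})

test_that("evidence ladder maps ratios to the conventional categories", {
  expect_equal(evidence_label(1.49), "anecdotal")
  expect_equal(evidence_label(1), "no evidence")
  expect_equal(evidence_label(15), "strong")
  expect_equal(evidence_label(45), "very strong")
  expect_equal(evidence_label(500), "extreme")
  expect_equal(evidence_label(0.2), "moderate (favors within)")
  expect_match(evidence_label(rope_ratio(c(6, 7), rope_spec(-Inf, 5))),
               "all draws above")
})

test_that("weight contrasts use the weight-scale ROPE", {
  rw <- rope_spec_weight()
  expect_equal(c(rw$lower, rw$upper), c(0.475, 0.525))
  f <- fake_fit(50, 0.55, jitter = 0.01)
  d <- posterior_draws(f, "mean_w") - 0.5
  rr <- rope_ratio(d + 0.5, rw)
  expect_gt(rr$ratio, 1)  # most mass above 0.525 for w near 0.55
})
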