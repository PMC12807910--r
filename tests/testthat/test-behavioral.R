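# Behavioral side-analyses: contingency tables, careless exclusion,
# deferred-response usage, correlation.

test_that("contingency arithmetic reproduces the printed report percentages", {
  counts <- categorization_counts()
  tab <- contingency_from_counts(counts)
  get <- function(col, dif) tab[tab$color == col & tab$difficulty == dif, ]
  expect_equal(get("blue", "easy")$pct_correct, 70.25)
  expect_equal(get("blue", "easy")$pct_false, 29.75)
  expect_equal(get("blue", "hard")$pct_correct, 68.32)
  expect_equal(get("red", "easy")$pct_correct, 67.91)
  expect_equal(get("red", "hard")$pct_correct, 57.03)
  expect_equal(get("red", "hard")$total, 1950)
  # color margins
  by_color <- aggregate(cbind(n_false, n_correct) ~ color, counts, sum)
  ct <- contingency_from_counts(by_color)
  expect_equal(ct$pct_correct[ct$color == "blue"], 69.29)
  expect_equal(ct$pct_false[ct$color == "blue"], 30.71)  # = 1212/3946
  expect_equal(ct$pct_correct[ct$color == "red"], 62.51)
  expect_equal(ct$total, c(3946, 3932))
})

test_that("contingency tables from trials count and percentage correctly", {
  toy <- data.frame(participant = "p1", stimulus_color = "blue",
                    ratio_difficulty = "easy",
                    query_correct = rep(1L, 10))
  t1 <- contingency_tables(toy, by = "color")
  expect_equal(t1$pct_correct, 100)
  expect_equal(t1$pct_false, 0)
  expect_error(contingency_tables(
    data.frame(query_correct = NA_integer_)), "no query outcomes")
  # row percentages always sum to 100 within rounding
  sim <- simulate_experiment(population_spec(careless_fraction = 0),
                             design_spec(2, n_participants = 8), seed = 2)
  tt <- contingency_tables(sim$trials, by = "color_difficulty")
  expect_true(all(abs(tt$pct_correct + tt$pct_false - 100) <= 0.01))
  expect_equal(sum(tt$total), sum(!is.na(sim$trials$query_correct)))
})

test_that("exclusion rule flags chance responders and spares genuine ones", {
  set.seed(55)
  n_rep <- 150
  flagged_chance <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    rep_trials <- make_flat_responder()
    flagged_chance[r] <- "p01" %in%
      flagged_participants(exclude_careless(rep_trials))
  }
  expect_gte(mean(flagged_chance), 0.95)
  flagged_genuine <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    rep_trials <- make_genuine_responder(C_hz = 50, w = 0.5)
    flagged_genuine[r] <- "p01" %in%
      flagged_participants(exclude_careless(rep_trials))
  }
  expect_lt(mean(flagged_genuine), 0.05)
})

test_that("exclusion rule edge cases behave as documented", {
  set.seed(8)
  # perfect responder is never flagged
  perfect <- make_genuine_responder()
  perfect$probe_first <- as.integer(perfect$soa_ms < 0)
  rep1 <- exclude_careless(perfect)
  expect_length(flagged_participants(rep1), 0)
  # chance only at small |SOA| but sharp at 100 ms: not flagged
  mixed <- make_genuine_responder()
  small <- abs(mixed$soa_ms) < 100
  mixed$probe_first[small] <- rbinom(sum(small), 1, 0.5)
  big <- abs(mixed$soa_ms) == 100
  mixed$probe_first[big] <- ifelse(
    rbinom(sum(big), 1, 0.95) == 1, as.integer(mixed$soa_ms[big] < 0),
    as.integer(mixed$soa_ms[big] >= 0))
  expect_length(flagged_participants(exclude_careless(mixed)), 0)
  # a participant with only zero-SOA trials is unassessable, not excluded
  zero_only <- data.frame(participant = c(rep("pz", 10), rep("p01", 10)),
                          soa_ms = c(rep(0, 10), rep(c(-100, 100), 5)),
                          probe_first = rbinom(20, 1, 0.5))
  repz <- exclude_careless(zero_only)
  flags <- attr(repz, "flags")
  expect_false(flags$assessable[flags$participant == "pz"])
  expect_false(flags$flagged[flags$participant == "pz"])
  expect_error(exclude_careless(
    data.frame(participant = "p", soa_ms = 0, probe_first = 1L)),
    "nonzero")
})

test_that("deferred-response summary reports users, mean, and range", {
  base <- data.frame(participant = rep(c("a", "b", "c"), each = 420),
                     is_query_trial = TRUE)
  base$sal_used <- 0L
  base$sal_used[base$participant == "a"][1] <- 1L
  base$sal_used[base$participant == "b"][1:56] <- 1L
  s <- sal_usage_summary(base)
  expect_equal(s$n_users, 2)
  expect_equal(s$mean_uses, 28.5)
  expect_equal(c(s$min_uses, s$max_uses), c(1, 56))
  expect_equal(s$opportunities, 420)
  none <- base; none$sal_used <- 0L
  s0 <- sal_usage_summary(none)
  expect_equal(s0$n_users, 0)
  expect_true(is.na(s0$mean_uses))
})

test_that("capacity-performance correlation behaves on knowns and nulls", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlate_diff_performance(x, x, bayes_factor = FALSE)$r, 1)
  expect_equal(correlate_diff_performance(x, -x, bayes_factor = FALSE)$r, -1)
  expect_error(correlate_diff_performance(rep(1, 5), x), "zero-variance")
  set.seed(99)
  inside <- replicate(2000, {
    abs(cor(rnorm(49), rnorm(49))) < 0.3
  })
  expect_gte(mean(inside), 0.95)
  # Bayes factor: small for a near-zero correlation, large for a strong one
  expect_lt(correlate_diff_performance(seq_len(49) + rnorm(49, 0, 20),
                                       rnorm(49))$bf10, 2)
  r_big <- correlate_diff_performance(x, x + rnorm(5, 0, 0.1))
  expect_gt(r_big$bf10, 3)
  expect_match(r_big$prior, "uniform")
})
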