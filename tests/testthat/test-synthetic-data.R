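# Synthetic-experiment generator: design fidelity, population structure,
# determinism, query and careless-responding mechanics.

test_that("default designs carry the study SOA grids and trial counts", {
  d1 <- design_spec(1)
  expect_equal(d1$soa_grid, c(-100, -50, -50 / 3, 0, 50 / 3, 50, 100))
  expect_equal(d1$trials_per_soa, rep(20L, 7))
  expect_equal(d1$conditions, c("BlueBlue", "RedRed", "BlueRed"))
  d2 <- design_spec(2)
  expect_equal(d2$trials_per_soa, c(28L, 40L, 48L, 48L, 48L, 40L, 28L))
  expect_equal(sum(d2$trials_per_soa), 280L)
  expect_error(design_spec(2, n_participants = 0), "positive")
})

test_that("generated tables match the design cell counts exactly", {
  pop <- population_spec(careless_fraction = 0)
  des <- design_spec(2, n_participants = 5)
  params <- simulate_participants(pop, des, seed = 3)
  trials <- simulate_trials(params, des, seed = 4)
  expect_equal(nrow(trials), 5 * 3 * 280)
  tab <- table(trials$condition, trials$soa_ms)
  for (cc in des$conditions) {
    expect_equal(as.vector(tab[cc, as.character(sort(des$soa_grid))]),
                 5L * des$trials_per_soa[order(des$soa_grid)])
  }
})

test_that("capacities are lognormal with the configured parameters", {
  des <- design_spec(2, n_participants = 4000)
  # degenerate population: everyone shares exp(C_mu)
  p0 <- simulate_participants(population_spec(C_sigma = 0,
                                              careless_fraction = 0),
                              design_spec(2, n_participants = 10), seed = 1)
  expect_true(all(p0$C == exp(log(0.11))))
  pop <- population_spec(C_mu = -3, C_sigma = 0.5, careless_fraction = 0)
  params <- simulate_participants(pop, des, seed = 2)
  one_cond <- params[params$condition == "2correct", ]
  se <- 0.5 / sqrt(4000)
  expect_lt(abs(mean(log(one_cond$C)) - (-3)), 3 * se)
  expect_true(all(params$C > 0))
})

test_that("identical seeds give identical tables, different seeds differ", {
  pop <- population_spec()
  des <- design_spec(2, n_participants = 6)
  a <- simulate_experiment(pop, des, seed = 9)
  b <- simulate_experiment(pop, des, seed = 9)
  expect_identical(a, b)
  c3 <- simulate_experiment(pop, des, seed = 10)
  expect_false(identical(a$trials$probe_first, c3$trials$probe_first))
})

test_that("simulated probe-first proportions track the race model", {
  des <- design_spec(2, n_participants = 36,
                     soa_grid = c(-100, 0), trials_per_soa = c(300L, 300L),
                     conditions = "2correct")
  pop <- population_spec(C_mu = log(0.05), C_sigma = 0,
                         w_by_condition = c(`2correct` = 0.5),
                         careless_fraction = 0)
  params <- simulate_participants(pop, des, seed = 5)
  trials <- simulate_trials(params, des, seed = 6)
  for (s in c(-100, 0)) {
    sel <- trials$soa_ms == s
    n <- sum(sel)
    p_true <- p_probe_first_cw(0.05, 0.5, s)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(mean(trials$probe_first[sel]) - p_true), 3 * se + 1e-9)
  }
})

test_that("query outcomes follow the class-specific accuracies", {
  des <- design_spec(2, n_participants = 30)
  pop <- population_spec(careless_fraction = 0)
  params <- simulate_participants(pop, des, seed = 1)
  trials <- simulate_trials(params, des, seed = 2)
  # all-correct degenerate model
  all1 <- simulate_queries(trials, difficulty_model(
    accuracy = c(blue_easy = 1, blue_hard = 1, red_easy = 1, red_hard = 1)),
    seed = 3)
  expect_true(all(all1$query_correct[all1$is_query_trial] == 1L))
  # default accuracies: per-class empirical rates within 3 binomial SEs
  q <- simulate_queries(trials, seed = 4)
  qq <- q[q$is_query_trial, ]
  acc <- difficulty_model()$accuracy
  for (cls in names(acc)) {
    parts <- strsplit(cls, "_")[[1]]
    sel <- qq$stimulus_color == parts[1] & qq$ratio_difficulty == parts[2]
    n <- sum(sel)
    se <- sqrt(acc[[cls]] * (1 - acc[[cls]]) / n)
    expect_lt(abs(mean(qq$query_correct[sel]) - acc[[cls]]), 3 * se)
  }
  # experiment-1 emulation queries about a quarter of trials
  des1 <- design_spec(1, n_participants = 20)
  t1 <- simulate_trials(simulate_participants(pop2 <- population_spec(
    w_by_condition = c(BlueBlue = 0.5, RedRed = 0.5, BlueRed = 0.45),
    careless_fraction = 0), des1, 1), des1, 2)
  q1 <- simulate_queries(t1, seed = 5)
  frac <- mean(q1$is_query_trial)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(q1)))
})

test_that("careless injection makes order judgments chance at every SOA", {
  des <- design_spec(2, n_participants = 4)
  pop <- population_spec(careless_fraction = 0)
  trials <- simulate_trials(simulate_participants(pop, des, 1), des, 2)
  unchanged <- inject_careless(trials, fraction = 0, seed = 3)
  expect_identical(unchanged$probe_first, trials$probe_first)
  care <- inject_careless(trials, fraction = 1, seed = 3)
  nz <- care[abs(care$soa_ms) == 100, ]
  correct <- ifelse(nz$soa_ms < 0, nz$probe_first == 1L,
                    nz$probe_first == 0L)
  se <- sqrt(0.25 / nrow(nz))
  expect_lt(abs(mean(correct) - 0.5), 3 * se)
})

test_that("deferred-response usage is sparse and summarizable", {
  des <- design_spec(2, n_participants = 49)
  pop <- population_spec(careless_fraction = 0)
  sim <- simulate_experiment(pop, des, seed = 13)
  s <- sal_usage_summary(sim$trials)
  expect_lt(s$n_users, 49)
  expect_gt(s$n_users, 0)
  expect_true(s$mean_uses >= s$min_uses && s$mean_uses <= s$max_uses)
})
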