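#!/usr/bin/env Rscript
# Simulate the two synthetic experiments the downstream analyses consume.
#
# Experiment 1 emulation: three stimulus comparisons (BlueBlue, RedRed,
# BlueRed), 20 trials per SOA per comparison, 32 participants, a quarter of
# trials followed by a categorization query. The BlueRed weight is set below
# 0.5 (easier blue reference attracts attention away from the red probe).
#
# Experiment 2 emulation: three classification-correctness conditions
# (2correct, 2false, 1each), counts (28,40,48,48,48,40,28) per SOA, 49
# participants, capacities near 112/106/107 Hz, every trial followed by a
# judgment, sparse "show again later" usage, and 2/51 careless responders.

library(tvatoj)

seed <- 20260929L
dir.create("results", showWarnings = FALSE)

pop1 <- population_spec(
  C_mu = log(per_ms(110)), C_sigma = 0.25,
  w_by_condition = c(BlueBlue = 0.51, RedRed = 0.51, BlueRed = 0.45),
  careless_fraction = 0)
exp1 <- simulate_experiment(pop1, design_spec(1), seed = seed, sal = FALSE)
write_trials(exp1$trials, "results/exp1_trials.csv")

pop2 <- population_spec(
  C_mu = log(per_ms(c(`2correct` = 112, `2false` = 106, `1each` = 107))),
  C_sigma = 0.25,
  w_by_condition = c(`2correct` = 0.5, `2false` = 0.5, `1each` = 0.5),
  careless_fraction = 2 / 51)
exp2 <- simulate_experiment(pop2, design_spec(2), seed = seed + 1)
write_trials(exp2$trials, "results/exp2_trials.csv")

write_run_config(run_config(seed = seed), "results/run_config.txt")

cat(sprintf("experiment 1: %d trials, %d participants, %d query trials\n",
            nrow(exp1$trials), length(unique(exp1$trials$participant)),
            sum(exp1$trials$is_query_trial)))
cat(sprintf("experiment 2: %d trials, %d participants (%d simulated careless)\n",
            nrow(exp2$trials), length(unique(exp2$trials$participant)),
            length(unique(exp2$trials$participant[exp2$trials$careless_truth]))))
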