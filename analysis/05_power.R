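#!/usr/bin/env Rscript
# Simulation-based power search: what sample size detects a 6 Hz capacity
# difference (the scale of the 2correct-2false effect) with the contrast
# HDI excluding zero? Reduced-fidelity fits inside the loop; a confirmation
# run at the test profile for the selected n.
#
# Problem sizes here are desk-scale (a coarse n grid, 12 replicates); the
# power numbers carry Beta-posterior HDIs that reflect exactly that.

library(tvatoj)

seed <- 20261002L
pop_at <- function(C_hz) {
  population_spec(C_mu = log(per_ms(C_hz)), C_sigma = 0.25,
                  w_by_condition = c(`2correct` = 0.5, `2false` = 0.5),
                  careless_fraction = 0)
}
des <- design_spec(2, conditions = c("2correct", "2false"))

cfg <- power_config(pop_at(112), pop_at(106), des,
                    candidate_n = c(10, 25, 45), replicates = 12,
                    exclude_below = 0, target_power = 0.8, seed = seed)
res <- run_power_search(cfg, verbose = TRUE)
print(res)
write.csv(res$per_n, "results/power_curve.csv", row.names = FALSE)

if (!is.na(res$minimum_n)) {
  confirm <- power_config(pop_at(112), pop_at(106), des,
                          candidate_n = res$minimum_n, replicates = 12,
                          exclude_below = 0, target_power = 0.8,
                          fit = fit_config("test"), seed = seed + 1)
  cres <- run_power_search(confirm)
  cat("confirmation at test-profile fidelity:\n")
  print(cres)
  write.csv(cres$per_n, "results/power_confirmation.csv", row.names = FALSE)
}
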