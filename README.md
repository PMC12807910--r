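# tvatoj

Hierarchical Bayesian estimation of visual attention parameters from
temporal-order judgments (TOJ), based on the Theory of Visual Attention
(TVA).

In a TVA-TOJ experiment, two stimuli — a *probe* and a *reference* —
flicker with a signed stimulus-onset asynchrony (SOA; negative = probe
leads) and the observer reports which flickered first. Modelling encoding
as a fixed-capacity exponential race, the probability of a "probe first"
response is

    P(probe first) = 1 − exp(−v_p·|SOA|) + exp(−v_p·|SOA|)·v_p/(v_p+v_r)   (SOA < 0)
    P(probe first) = exp(−v_r·|SOA|)·v_p/(v_p+v_r)                         (SOA ≥ 0)

with v_p = C·w and v_r = C·(1−w): **C** is the overall attentional
capacity (reported in Hz) and **w** the attentional weight of the probe.
Probe-first counts per SOA cell are binomial, and C varies across
participants via a non-centered lognormal hierarchy
(C_mu ~ Normal(−3, 1), C_sigma ~ HalfNormal(0.5),
C_i = exp(C_mu + C_sigma·C_e[i]); w_i ~ Beta(1, 1)), sampled by MCMC
(JAGS).

The package is an end-to-end analysis kit:

* `p_probe_first()`, `reparameterize()`, `toj_log_likelihood()` — the
  closed-form race model;
* `simulate_experiment()` and friends — synthetic studies matching the
  two study designs (SOA grids, trial counts, careless responders,
  categorization queries, deferred-response usage);
* `fit_tva_toj()`, `summarize_posterior()`, `predictive_check()` —
  hierarchical estimation with HDI summaries and convergence gates;
* `condition_difference()`, `rope_ratio()`, `evidence_label()` —
  posterior condition contrasts against a region of practical
  equivalence (default (−∞, 5] Hz for capacity differences);
* `contingency_tables()`, `exclude_careless()`, `sal_usage_summary()`,
  `correlate_diff_performance()` — behavioral side-analyses;
* `run_power_search()` — simulation-based power over sample sizes.

The numbered drivers in `analysis/` run the whole workflow on synthetic
data (`01_simulate.R` → `05_power.R`), writing tables under `results/`.

## Worked example

Simulate a 20-participant study at 112 vs 106 Hz true capacity, fit two
conditions, and contrast them:

```r
library(tvatoj)
pop <- population_spec(
  C_mu = log(per_ms(c(`2correct` = 112, `2false` = 106, `1each` = 107))),
  C_sigma = 0.25, careless_fraction = 0)
sim <- simulate_experiment(pop, design_spec(2, n_participants = 20), seed = 1)
fit <- fit_tva_toj(sim$trials[sim$trials$condition == "2correct", ],
                   fit_config("test", seed = 1))
fit
#> Hierarchical TVA-TOJ fit: 20 participants, 2 chains x 1000 draws
#>   population C: 114.5 Hz [98.6, 130.3]
#>   mean w: 0.506 [0.488, 0.521]

fit_b <- fit_tva_toj(sim$trials[sim$trials$condition == "2false", ],
                     fit_config("test", seed = 2))
ct <- condition_difference(fit, fit_b, "sample_mean_C", seed = 3)
ct
#> contrast 2correct - 2false (sample_mean_C): mean 6.928, 95% HDI [-4.882, 18.38]

rr <- rope_ratio(ct, rope_spec(-Inf, 5))
evidence_label(rr)
#> [1] "anecdotal"
```

The fit recovers the generating capacity (112 Hz true, posterior
114.5 Hz with the truth well inside the HDI) and an even attentional
split (w ≈ 0.5). The contrast's posterior mean of ~7 Hz matches the 6 Hz
generating difference; with only 20 participants its 95% HDI still spans
zero, and the posterior mass above the 5 Hz practical-equivalence bound
is 1.65 times the mass within it — anecdotal evidence for a real
capacity difference.

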