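---
title: "Estimating attentional capacity and weight from temporal-order judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating attentional capacity and weight from temporal-order judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvatoj)
```

## The model

The Theory of Visual Attention (TVA) treats visual encoding as a
fixed-capacity race: every stimulus in the field races for representation
in visual short-term memory at an exponential rate, and the rates of all
stimuli sum to the observer's attentional capacity *C*. In a two-stimulus
temporal-order judgment (TOJ), a *probe* and a *reference* each flicker
once, separated by a stimulus-onset asynchrony (SOA, negative when the
probe leads), and the observer reports which flickered first. The probe's
encoding rate is $v_p = C\,w$ and the reference's $v_r = C\,(1 - w)$, where
$w \in (0,1)$ is the attentional weight of the probe — the share of
capacity it receives.

With exponential encoding times, the probability of judging the probe
first has a closed form with three regimes. When the probe leads
(SOA $< 0$), either the probe finishes within its head start
($1 - e^{-v_p|SOA|}$), or both race together and the probe wins by the
Luce choice ratio $v_p/(v_p + v_r) = w$:

$$P(\text{probe first}) =
\begin{cases}
1 - e^{-v_p|SOA|} + e^{-v_p|SOA|}\,\dfrac{v_p}{v_p+v_r}, & SOA < 0,\\[1ex]
e^{-v_r|SOA|}\,\dfrac{v_p}{v_p+v_r}, & SOA \ge 0.
\end{cases}$$

The boundary SOA $= 0$ is assigned to the second branch; both branches
give $w$ there, so the function is continuous, and it decreases
monotonically from 1 to 0 in the signed SOA. Ties in the continuous race
have probability zero, so no tie-breaking rule is needed. The function is
exposed as `p_probe_first()` (rate parameterization) and
`p_probe_first_cw()` (capacity/weight parameterization):

```{r}
p_probe_first_cw(per_ms(80), 0.5, c(-100, 0, 100))
```

**Units.** SOAs are in milliseconds, so rates are per-millisecond
internally; reported capacities are multiplied by 1000 and quoted in Hz
(`hz()` / `per_ms()` convert). This pairing is what makes the prior below
land on a capacity median of about 50 Hz, the right order of magnitude for
flicker-event processing.

Counts of probe-first responses per (participant, SOA) cell are modelled
as binomial with the closed-form success probability — the maximum-entropy
choice for two-alternative counts.

## Hierarchical estimation

Capacity varies across observers on a multiplicative scale, so the model
places a lognormal population on it, written non-centered for better
sampler geometry:

$$C_\mu \sim \mathrm{Normal}(-3, 1),\quad
C_\sigma \sim \mathrm{HalfNormal}(0.5),\quad
C_{e[i]} \sim \mathrm{Normal}(0, 1),\quad
C_i = e^{C_\mu + C_\sigma C_{e[i]}},$$

with an independent flat $w_i \sim \mathrm{Beta}(1,1)$ per participant (no
pooling on weights). `prior_capacity_draws()` exposes the implied prior on
$C_i$; a test verifies it against the analytically integrated lognormal
mixture. Each experimental condition is fitted independently — the
hierarchy carries no condition index, matching how the estimates are
reported per condition.

Sampling is MCMC via JAGS (`rjags`), with convergence monitored through
split-chain $\hat R$ and effective sample size (`coda`); `fit_tva_toj()`
warns — never silently passes — when $\hat R \ge 1.01$ or ESS $\le 400$.
Three profiles are provided (`fit_config()`): `full` (4 chains, 16,000
warm-up, 24,000 draws) for study-grade runs, `test` (2 × 500/1,000) which
is accurate to a few percent on these models and finishes in seconds, and
`power` (1 × 300/600) for the inner loop of the power search. Probabilities
are clamped to $[10^{-12}, 1-10^{-12}]$ before the binomial log-mass so
extreme proposals cannot produce $-\infty$.

Two population-level capacity summaries are exposed because they answer
different questions: `population_C` is the posterior of $e^{C_\mu}$ (the
location of the capacity lognormal — where a *new* sample would center,
hence wider intervals), while `sample_mean_C` averages the fitted $C_i$
per draw (the capacity of *this* sample — narrower intervals). Both have
the same central tendency; tests assert the interval ordering.

**HDI convention.** All intervals are highest-density intervals at 95%
mass by default (the mass is an argument everywhere): the narrowest
contiguous interval of the sorted draws containing the stated mass, exact
for unimodal posteriors.

## Contrasts, ROPE, and evidence

Conditions are fitted independently, so `condition_difference()` pairs
draws across two fits through a common random permutation (seeded): any
fixed matching of independently sampled draws is exchangeable, and a
common permutation keeps the identity contrast exactly zero and the
swapped contrast an exact negation. The headline contrast is the averaged
individual capacity difference: per paired draw, the mean over
participants of $C_i^A - C_i^B$, in Hz.

Evidence about a contrast is summarized against a region of practical
equivalence (ROPE). For capacity differences the default ROPE is
$(-\infty, 5]$ Hz — differences below 5 Hz are treated as practically
null — and `rope_ratio()` reports the posterior mass strictly above the
ROPE divided by the mass within it. When no draw falls inside, an
"all-above" flag is returned instead of a division by zero. The ratio maps
onto the conventional evidence ladder (`evidence_label()`: 1–3 anecdotal,
3–10 moderate, 10–30 strong, 30–100 very strong, >100 extreme; ratios
below 1 are labelled by their reciprocal for the complementary direction).
Whether boundary draws count as "above" is decided by strict inequality —
a probability-zero event for continuous posteriors. Weight contrasts use a
ROPE of $[0.475, 0.525]$ around the uniform split.

## The synthetic-experiment generator

`simulate_experiment()` produces complete synthetic studies so every
downstream stage is testable without external data. The default designs
are the two study layouts: seven one-frame SOAs on a 60 Hz display
($-100, -50, -50/3, 0, 50/3, 50, 100$ ms — the one-frame SOA is stored as
the exact ratio $50/3$, not its rounded decimal), 20 trials per SOA per
comparison for three comparisons (experiment 1, 32 participants), and
counts $(28, 40, 48, 48, 48, 40, 28)$ per classification-correctness
condition (experiment 2, 49 participants, 280 trials per condition each).

Generator defaults were fixed once, as the conditions the analyses are
validated under:

* capacities lognormal with $C_\sigma = 0.3$ (a ±35% typical spread,
  realistic for capacity heterogeneity) around condition locations near
  110 Hz for the experiment-2 emulation;
* condition-level weights (flat across participants by default — recovery
  checks are cleanest against a known shared truth; per-participant Beta
  jitter is available via `w_concentration`);
* a careless fraction of $2/51$: those participants respond
  Bernoulli(0.5) at every SOA;
* categorization-query accuracies ordered blue-easy ≥ blue-hard ≥
  red-easy ≥ red-hard (defaults 0.7025, 0.6832, 0.6791, 0.5703), with a
  query on 25% of trials in the experiment-1 emulation and on every trial
  in the experiment-2 emulation;
* sparse deferral ("show again later") usage: roughly a quarter of
  participants have a nonzero per-opportunity rate (mean 0.024), the rest
  never use it.

What the generator deliberately does **not** emulate: block structure and
trial-order effects (the binomial likelihood is exchangeable within a
cell), response times, learning across the familiarization phase, lapses
other than fully careless responding, and any dependence of the TOJ
response on the categorization query. Passing recovery tests therefore
show that the estimation machinery is correct *for the assumed generative
model* — they cannot certify robustness to serial dependence, lapse
mixtures, or drift that real data may contain.

## Careless-responder exclusion

"Responding at chance at every SOA" is operationalized per participant:
order-judgment accuracy (naming the truly first stimulus; SOA 0 excluded
as undefined) is pooled within each $|SOA|$ level and tested against 0.5
with an exact two-sided binomial test. The participant is flagged only
when **every** level is non-significant. Because that is one claim per
participant tested across several levels, the familywise level
$\alpha = 0.05$ is split across levels (Bonferroni): per-level testing at
the full $\alpha$ would mislabel a truly careless responder as attentive
whenever a single level fluctuates into significance, capping sensitivity
near 0.9 at these trial counts, whereas the familywise rule flags chance
responders in about 97% of replicates while flagging genuine responders
(50 Hz, $w = 0.5$) in far fewer than 5% — both rates are verified by
simulation in the test suite. Participants with no nonzero-SOA trials are
reported as unassessable, not excluded.

## Power search

`run_power_search()` estimates, for each candidate sample size, the
probability that the capacity-contrast HDI excludes a configured minimal
difference, by repeated simulate–fit–contrast cycles (reduced-fidelity
fits inside the loop; `analysis/05_power.R` confirms the selected $n$ at
the test profile). Success counts get a Beta(1, 1) posterior whose 95%
highest-density interval is reported — the HDI always contains the Beta
mode, which equals the observed success fraction. Fit failures are counted
and reported separately, never silently mapped to successes or failures.
The two arms draw their participant populations independently, so the
power estimates include between-sample capacity noise; the true effect
sizes are configuration, not fitted quantities — no published effect
configuration exists to reproduce, so the shipped driver uses a 6 Hz
capacity difference at $C_\sigma = 0.25$ as a plausible target.

## Numerical and design notes

* SOA ingestion (`read_trials()`) snaps values within 0.5 ms onto the
  exact design grid, so rounded frame durations (16.67, 17) normalize to
  $50/3$; larger deviations are schema errors.
* Report percentages round half-up at two decimals
  (`contingency_from_counts()`), matching how such tables are printed;
  R's default half-to-even rounding would differ on boundary cases.
* All simulation functions take explicit integer seeds and restore the
  caller's RNG state; sub-seeds are derived reproducibly and folded into
  the 31-bit range JAGS accepts.
* The optional correlation Bayes factor uses a uniform prior on the
  correlation coefficient (Jeffreys's integral form) and records the prior
  in its output; other default priors will give somewhat different values.
* Problem sizes in the shipped tests and drivers are desk-scale by
  design: test-profile fits (seconds per condition), 12–20 replicates in
  operating-characteristic and power loops, and $2\times10^5$–$10^6$ draws
  in Monte-Carlo oracles. The full profile reproduces study-grade
  inference at proportionally longer runtimes.

## Known limitations

The model assumes exponential encoding races with no decision bias, no
lapse parameter, and weights constant within a condition block. Fits are
per condition, so cross-condition correlations in capacity are not
modelled and contrasts rely on independence pairing. Very accurate
responders push capacity estimates into a regime where a single error
moves $C$ substantially, inflating interval widths at high capacity.
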