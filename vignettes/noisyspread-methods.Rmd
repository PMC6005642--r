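---
title: "Methods: models, estimators, and numerical choices in noisyspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and numerical choices in noisyspread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisyspread)
```

# The model

`noisyspread` studies rumor spreading in a well-mixed population of `n`
agents, `s` of which are sources that know a binary correct opinion.
Agents communicate passively: each continuously displays one message from
a finite alphabet of size `k`, and observations pass through a
row-stochastic noise matrix `P` whose entry `P[m, m']` is the probability
that a displayed `m` is received as `m'`. The noise is *delta-uniform*
when every entry is at least `delta`; since rows sum to one this forces
`delta <= 1/k`. Two stock constructions cover the regimes of interest:

* `build_confusion("uniform", k, delta)` — the symmetric matrix with all
  off-diagonal entries equal to `delta`. This is the canonical
  delta-uniform matrix: the definition only constrains entries from
  below, and the symmetric choice attains the constraint with equality
  off the diagonal while staying row-stochastic for every
  `delta <= 1/k`. At `delta = 1/k` all rows are identical and
  observations are pure noise.
* `build_confusion("neighbor", k, leak)` — tridiagonal support: symbols
  can only be confused with their immediate neighbours. Only the support
  pattern is essential for the fast-spreading regime; a single symmetric
  leak parameter is the minimal parameterisation that realises it, and
  entries off the tridiagonal are exactly zero, so the matrix is not
  delta-uniform for any positive delta.

Row sums are validated to `1e-9` (floating-point hygiene; constructors
are exact and user CSV matrices are expected to be written with at least
12 significant digits, which the round-tripping writer guarantees).

# Interaction engines

Four engines share one protocol contract (`new_spread_protocol`): an
`init`/`display`/`update`/`output` quadruple operating on the whole
population at once. Semantics deliberately fixed here:

* **Synchrony.** In round models all observations use displays frozen at
  the round start and all updates apply simultaneously.
* **Self-inclusion.** "A uniformly random agent" includes the observer
  itself (uniform over all `n`); an engine flag (`include_self = FALSE`)
  excludes it. Self-observations carry no information for sensible
  protocols, and the uniform-over-all reading keeps the arithmetic of the
  broadcast reduction exact.
* **Indexing.** Rounds, steps and agents are 1-based; the broadcast lift
  stores the step-`i` sample with agent `(i mod n) + 1`, so over a round
  of exactly `n` steps each agent keeps precisely one independent uniform
  sample of the previous round's configuration. `lift_to_parallel()`
  implements this schedule; the distributional equality of lifted
  broadcast rounds and parallel rounds is checked by a two-sample
  Kolmogorov–Smirnov comparison over 2,000 runs at `n = 5` (the
  convergence-round distribution is discrete, which only makes the KS
  test conservative).
* **Sources are immutable**; their displays are protocol-defined, and
  non-source state never reads the correct opinion.
* **Silence** (`NA` display) exists only in the push engine: a pushed
  message is noised through `P`, but the absence of a message is
  delivered reliably. Pull engines reject silent displays.
* **Reproducibility.** All randomness flows through R's RNG; every
  engine takes a `seed`. Noise sampling uses one uniform per draw via a
  row-wise inverse CDF, so paired-seed runs remain aligned: under
  `delta = 1/k` noise, runs that differ only in the correct opinion
  produce byte-identical non-source traces — the zero-information
  control.

`max_rounds` defaults to `50 n`, safely above the linear-regime times at
the scales the package targets.

# Protocols

**Attracting-sink relay** (`make_sink_protocol`, odd `k`): sources
display their endpoint; everyone else displays the middle symbol until
first observing an endpoint, which they adopt permanently. Two open
points are resolved as package choices: (i) before adoption an agent's
output is a fair coin drawn at initialisation, which makes the error
probability well defined at every round without consuming RNG draws
asynchronously; (ii) the first adoption is permanent (monotone dynamics);
`adoption = "latest"` is available for sensitivity analysis. With
multiple observations per round the first endpoint in sample order wins.

**Static display + exact observer** (`make_static_display`,
`bayes_update`, `certainty_time`): sources display a fixed opinion
symbol, non-sources a fixed default. Under broadcast-PULL the observation
process is then i.i.d. from the mixture
`Q_b = ((n-s)/n) P[default, ] + (s/n) P[opinion_b, ]`, the exact
posterior is a product of mixture likelihoods, and `certainty_time`
simulates the first passage of the log-posterior across the confidence
threshold (default 2/3, the conventional "moderately sure" level) as a
blocked cumulative sum. The fully adaptive, history-dependent posterior
is exercised in the enumeration machinery instead — same mathematics,
tractable exactly at small horizons.

**Two-stage push booster** (`make_push_boost`): stage 1 spreads guesses,
stage 2 amplifies them; output is the current guess, with a fair coin for
agents never contacted. Two design points were genuinely open and were
settled by analysis plus simulation:

* *Stage-2 aggregation.* Resetting each agent's guess to the majority of
  messages received in the current round alone is a contraction toward
  chance: in-degrees are approximately Poisson(1), and a majority of one
  noisy copy has exactly the copy's reliability, so the population
  fraction correct stalls near 1/2. The default is therefore a
  cumulative tally of all stage-2 messages (`boost = "round"` retains
  the per-round variant for comparison).
* *Stage-1 spreading.* Relayed adoption chains reach everyone quickly but
  with per-hop reliability decay `(1 - 2*noise)` per hop, leaving stage-2
  seeded close to chance — and a cumulative-majority stage 2 then
  amplifies whatever direction early randomness produced, occasionally
  herding the entire population onto the wrong opinion. With
  `warmup = "source_only"` all non-sources stay silent during stage 1, so
  the stage-2 seed consists purely of direct source contacts (about one
  per round, each correct with probability `1 - noise`), which makes the
  consensus direction highly reliable at the cost of early growth. This
  silence-until-reliable gating is exactly the facet of push
  communication that noise cannot corrupt.

A round-budget observation worth recording: for all agents to end correct,
each agent needs enough post-consensus messages for a per-agent error
around `1/(10 n)`; at `n = 1000` and noise 0.1 that is roughly 14 reliable
messages, while supply is at most one message per agent per round and
informing the population consumes ~13 rounds. Budgets of about 50 rounds
(still logarithmic in `n`, with a modest constant) therefore reach
all-correct reliably, whereas a 30-round budget cannot, whatever the
variant — the acceptance script reports both operating points, and the
pull-side certainty time at matched parameters exceeds either by three
orders of magnitude.

# Distinguishing machinery

`process_pair` represents the two observation processes an agent must
tell apart as conditional next-outcome distributions given the full
history — multi-valued coins whose bias drifts with wear. All analysis is
by exhaustive enumeration, guarded at `k^t <= 1e6` histories:

* `pair_params`: `eps` is the maximum ℓ1 distance between the two
  conditional distributions over histories reachable with positive
  probability under either hypothesis (histories impossible under both
  are excluded; the per-outcome ℓ∞ version is reported alongside), and
  `delta` the minimum conditional outcome probability.
* `chain_rule_kl` computes `KL(P0(<=t) || P1(<=t))` as the sum over steps
  of the expected conditional divergence, and `joint_kl_oracle`
  recomputes it from the explicit joints; the two agree to `1e-10` across
  a randomized battery of history-dependent pairs, which is the
  correctness argument for the chain-rule implementation. KL is in nats
  throughout. A conditional probability that is zero under hypothesis 1
  but positive under hypothesis 0 yields an `Inf` sentinel.
* `kl_budget_bound` evaluates `t * eps^2 / delta` with constant 1,
  justified per step by KL ≤ chi-square ≤ (ℓ1 gap)² / (min probability);
  tests assert it only as an inequality over the battery.
* `error_lower_bounds` supplies two certifiably valid uniform-prior
  bounds — Pinsker-based `(1 - sqrt(KL/2))/2` and Bretagnolle–Huber
  `exp(-KL)/4` — both dominated by the exact `bayes_error_oracle`
  (`sum min(prior*p1, (1-prior)*p0)` over sequences). Two bounds are
  exposed deliberately: the square-root bound is tight near
  indistinguishability, the exponential one stays informative for large
  divergences.

The worked two-coin example (`worn_coin_pair`) pins the conditional
distributions after the history H,T,T,H,T,T at `(0.51, 0.49)` versus
`(0.43, 0.57)` — one-step ℓ1 gap 0.16 — via a linear wear rule on the
head/tail imbalance, clamped to `[0.05, 0.95]`; only those two
conditionals are anchored, the dynamics elsewhere being the simplest
consistent choice.

# Closed-form bounds and scaling

`pull_round_bound` evaluates `n*delta/(s^2 (1 - delta*k)^2)` (with an
`Inf` sentinel at `delta*k = 1`), `detectable_pull_round_bound` its cube
root (the weaker bound when sources are recognisable on sight),
`process_gap_theory` the per-observation gap `s(1 - delta*k)/n`, and
`sample_complexity` the `delta/eps^2` observation scale. All are
order-of-magnitude expressions evaluated with constant 1 and used only
for scaling comparisons and one-sided checks with loose constants; the
constraint `s/n < delta` under which they are informative is surfaced as
a warning, with the unknown constant set to 1, not enforced.

`scaling_experiment` fits the log-log slope of mean certainty time
against `n` by ordinary least squares, excluding censored runs with a
warning. The study condition used in tests: uniform noise `delta = 0.3`,
`k = 2`, `s = 1`, `n in {20, 40, 80, 160}`, 300 repetitions — the slope
lands near 2, the quadratic broadcast-step law, and both drift- and
diffusion-dominated threshold crossings scale the same way, so the
exponent is insensitive to the 2/3 threshold.

# The behavioural noise estimator

The estimator mirrors a recruitment-chamber analysis: interactions are
labelled by the initiating ant's speed — messages 'a': [1, 10), 'b':
[10, 20), 'c': [20, ∞) cm/s, half-open by convention since the ranges'
boundary rule is not fixed by the data description — and the response of
initially stationary receivers (pre-interaction speed < 1 cm/s,
consistent with the 'a' bin's lower edge; configurable) is discretised
into response bins, by default the same three plus a
"remained stationary" bin below 1 cm/s. With equal message priors,
`p_i(v) = p(v|i) / sum_k p(v|k)` is the posterior that response `v` came
from message `i`, the overlap is `delta(i, j) = sum_v p(v|j) p_i(v)`, and
the noise level is the minimum overlap. Each overlap column sums to one
by construction (the identity `sum_i p_i(v) = 1` under the weighted sum),
which is asserted on every estimate. Response bins with zero mass under
all messages are dropped — they contribute nothing and would divide by
zero. Because the response discretisation is not canonical, estimates
are bin-sensitive and are always reported alongside the bin
specification.

Supporting statistics: `message_separation_tests` (pairwise Wilcoxon
rank-sum on receiver post-speeds — the alphabet-size justification: true
message classes separate, oversplit half-bins do not);
`interaction_rate` with the both-participants convention
(`2 * interactions / (group * minutes)` — stated prominently since the
per-ant phrasing alone does not fix the factor 2);
`return_time_pdf` against the uniform-mixing geometric law
`P(m) = ((g-2)/(g-1))^(m-1)/(g-1)`; and `recruitment_times` (second
nest-mate exit minus informed entry, censoring experiments with fewer
than two exits, Kolmogorov–Smirnov across group-size ranges, default
split 2–5 versus 6–10).

# Synthetic data: what it emulates and what it does not

`behavioral_truth()` fixes the generator's ground truth: uniform random
partner choice within groups of 6, a Poisson interaction clock matching
0.82 interactions per ant per minute (the empirically reported rate for
this kind of confined recruitment arena), receivers initially stationary
with probability 0.8, equal message frequencies, and response
distributions whose analytic overlap minimum is ≈ 0.30 — the moderate-
noise regime the estimator is meant to operate in (with three messages
the theoretical maximum is 1/3). Recruitment logs draw lognormal exit
delays with a higher scale for larger groups (means 60 s versus 130 s,
sdlog 0.45), an effect size at which the two-group comparison has
comfortable power at 24 experiments.

The generator reproduces the statistical structure the estimator assumes
— conditional response distributions, uniform mixing, stationarity
filtering — with known ground truth, so estimator-recovery tests verify
the estimation pipeline, not the biology. Real interaction data differ in
ways the generator deliberately omits: temporal dependence between
successive interactions, heterogeneous individuals, drifting activity
levels, and continuous (rather than bin-uniform) speed distributions.
Passing recovery tests therefore demonstrates correctness of the
formulas and code, and nothing about how well three speed bins capture
real ant communication.

# Study conditions used by the tests and acceptance script

Problem sizes were chosen as the smallest that cleanly exhibit each
regime: worked checks are exact; the KL battery uses 12 randomized pairs
at horizons 5–6; certainty scaling uses `n ≤ 160` with 300 repetitions;
the sink dichotomy uses `n = 100`, 200 runs against a `10·log2(n)` round
budget; the reduction check uses `n = 5` with 2,000 runs per model; the
push demonstration uses `n = 1000` with 100 runs; estimator recovery uses
~10,000 stationary records per message. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch under a
caller-supplied seed.

# Known limitations

* Enumeration-based quantities are exact but limited to small horizons
  (`k^t <= 1e6`); long-horizon KL growth is bounded, not enumerated.
* The closed-form bounds carry constant 1; they order scenarios and
  scales but are not sharp thresholds.
* The push booster is a demonstrator of the reliable-silence mechanism,
  not an optimal protocol; its all-correct time at `n = 1000` is about
  50 rounds, and no variant in this simple family reaches all-correct
  within a 30-round budget (see the round-budget analysis above).
* The delta estimator's value is response-bin dependent; comparisons
  across datasets require identical bin specifications.
* Time-varying noise matrices and per-pair asymmetric channels are out of
  scope; `P` is global and time-invariant.
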