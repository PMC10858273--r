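---
title: "Models and methods for triadic ultimatum-game analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for triadic ultimatum-game analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific choices behind `triadug`: the
experimental design it encodes, the generative assumptions of its
agent simulator, the model suite and its priors, the resampling null,
and the numerical decisions a reader needs to interpret results. It
states no empirical findings beyond what the package's tests and
acceptance script themselves compute.

## The experiment

A *triad* is one responder plus two proposers playing 16 sessions of 8
trials. On each trial a proposer can push 1–8 grapes (of 8 available)
to the responder; her own payoff if accepted is `8 - offer`. In the 8
*dyadic* control sessions only one proposer acts per trial (each makes
4 offers, alternating every two trials), so the responder accepts or
rejects a single standing offer. In the 8 *triadic* sessions both
proposers offer and the responder can accept exactly one offer; the
rejected proposer earns nothing. Triadic sessions contain a contiguous
block of 4 *simultaneous* trials (neither proposer sees the other's
offer) and a block of 4 *consecutive* trials (the second proposer sees
the standing first offer before offering).

`generate_design()` reproduces the aggregate counterbalancing
constraints of this design exactly: alternation of conditions from a
configurable starting block, side swaps every two sessions (each
proposer sits left in 8 sessions, 4 dyadic + 4 triadic per side),
simultaneous-first order in 4 of 8 triadic sessions, each proposer
first on 2 of 4 consecutive trials per session and leading the block
in 4 sessions, and each proposer opening 4 of 8 dyadic sessions. Only
these aggregate counts are binding; the concrete orderings (strict
alternation of condition blocks, an L-O-O-L first-mover pattern within
consecutive blocks, alternating block leaders and dyadic openers) are
this package's deterministic choices among the schedules satisfying
them, and `verify_design()` re-checks every count so alternative
schedules can be audited.

## The agent simulator

The synthetic-data generator is first-class, tested code: it defines
the conditions under which the model suite is exercised.

* `propose_minimal()` — always 1 grape; the rational proposer of the
  classical dyadic game.
* `propose_reluctant_increase(start = 1, step_up = 1,
  p_decrease_after_accept = 0.25)` — escalates only after rejection,
  capped at 8; repeats (or with the stated probability lowers by 1,
  floored at 1) after acceptance. This is the "reluctantly increasing"
  archetype used in the power analysis.
* `propose_outbidder(share_threshold = 4)` — in the consecutive second
  position with visible first offer `f`, offers `f + 1` whenever the
  residual share `8 - (f + 1)` is at least the threshold; otherwise
  falls back (default: reluctant). At the default threshold it outbids
  exactly first offers 0–3, which is the motivational-threshold
  behaviour the stratified outbid model should resolve.
* `respond_maximizer(weber_w, side_bias = 0.5)` — accepts the larger
  offer, erring with probability `0.5 * exp(-(1 - r) / weber_w)` where
  `r` is the smaller/larger offer ratio. The exponential-in-`1 - r`
  form is this package's choice of a ratio-dependent (Weber-like)
  error; the default `weber_w = 0.25` in `simulate_study()` makes
  errors all but vanish for ratios below about one half, so
  discrimination failures concentrate on hard, similar-offer pairs.
  `weber_w = 0` gives an exact maximizer. Lone sent offers are always
  accepted; exact ties are broken by `side_bias`.

Proposer memory resets at session boundaries by default, matching the
models' treatment of each session's first trial as predecessor-free.
Strategies may emit "no offer" (recorded as 0 and excluded from all
model responses) with probability `p_no_offer`, default 0.

What the generator does *not* emulate: learning beyond the reluctant
rule, real response times, individual heterogeneity beyond the
strategy parameters, or attention/visibility effects. Passing tests on
simulated data therefore demonstrate that the estimation machinery
recovers known structure, not that real subjects behave like these
agents.

## The model suite

All six models are sampled with JAGS through `sample_posterior()`
(default 4 chains × 1000 post-warmup draws; every seed is recorded in
the returned fit).

**Total proportional offer.** Per proposer-session response
`y = (grapes sent) / (8 × opportunity trials)`, Beta likelihood with
`logit(mu) = beta0_c + beta1_c s_std + u_t` and
`log(phi) = gamma0_c + v_t`, condition-specific means, slopes and
precisions, and triad random effects on both parameters. The
first-half variant (trials 1–4, so each triadic session contributes a
purely simultaneous or purely consecutive half) adds a contrast
covariate coded 0 (dyadic), −0.5 (simultaneous), +0.5 (consecutive).
Reported summaries are posterior-*predictive* means and 95% HPD
intervals for a new triad at a uniformly drawn observed session, plus
the predictive difference between conditions — wide by construction,
since they include the Beta trial-to-trial variation.

**Escalation models.** Bernoulli mixed models with proposer random
intercepts: last-offer-higher-than-first per proposer-session
(session × game-type interaction); offer higher than the proposer's
own previous offer; and offer at least the previously accepted
(winning) offer, the latter two on triadic trials with a same-session
predecessor and a previous-outcome × session interaction. For the
match-the-winner model the split variable is whether the previous
winner was the proposer's own offer, which (given an acceptance
occurred) coincides with the proposer's own previous offer being
accepted.

**Outbidding models.** On consecutive trials, "outbid" means the
second offer is *strictly* greater than the first; matching the winner
uses "greater or equal" — both follow the ordinary meaning of the
words. The simple model has only a session effect and second-proposer
random intercepts. The stratified model discards each session's first
trial (it needs the second proposer's previous outcome) and adds the
first offer as a monotonic ordinal effect, `- b * cumsum(zeta)[k]`
with `b >= 0` half-Normal(2) and `zeta` an 8-simplex with a flat
Dirichlet prior: the outbid probability is constrained to be
non-increasing in the first offer while the per-category drops are
free. Its random intercepts are second-proposer × responder pairs by
default, since outbidding plausibly varies with both identities;
unobserved first-offer categories are still predicted through the
monotonic chain but flagged as extrapolation. Summaries include
exceedance probabilities over chance (0.5 — the natural anchor for
"more likely than not to outbid") and over a supplied baseline table.

**Priors.** The package uses weakly-informative defaults, recorded in
every fit for auditability:
Normal(0, 2.5) on all logit/log-scale fixed effects, half-Normal(1) on
random-effect scales, half-Normal(2) on the monotonic magnitude, flat
Dirichlet on the simplex. With hundreds of trials per model these
priors are dominated by the likelihood; posterior summaries on any
given dataset are therefore expected to be close to, not identical
with, those from other prior choices.

## Numerical choices

* **Boundary handling.** Total proportional offers of exactly 0 or 1
  are possible; the Beta support is open, so responses are compressed
  as `(y (n - 1) + 0.5) / n` with `n` the number of proposer-sessions.
* **Precision guard.** The log-precision terms of the Beta model
  (`gamma0`, `u_phi`) are truncated to ±8 (so `phi` cannot exceed
  roughly `e^16`). This is far outside any scientifically plausible
  precision and only prevents the sampler from diverging when a
  condition's responses are (near-)constant — as happens with
  zero-noise synthetic agents; real data never sit there.
* **Session covariate.** Standardized to mean 0, SD 1 within the
  fitted data, for sampler geometry. Derived summaries are evaluated
  on the observed session grid, which makes them invariant to shifting
  session labels (tested).
* **HPD intervals.** `hpd_interval()` returns the shortest contiguous
  window over the sorted draws containing `ceiling(mass * n)` of them,
  verified against an exhaustive window search; for multimodal draws
  this is the shortest single interval, not the possibly disjoint HPD
  region. Ties in window width resolve to the lowest window.
* **Diagnostics.** Split-R-hat above 1.01 or effective sample size
  below 400 raises a classed warning, never a silent pass. The
  thresholds are package conventions.
* **Degenerate inputs.** Descriptive statistics return `NaN` (flagged
  undefined) when no qualifying trials exist; proposer-sessions with a
  single offer are dropped from the last-vs-first model with a
  warning; empty model datasets error.
* **Weighting defaults.** The baseline null weights first offers by
  `exp(-0.2 (trial - 1)) * exp(-0.2 (session - 1))` by default; only
  the *direction* of the weighting is scientifically fixed (early
  trials and sessions are better preference probes), the rate is
  exposed in configuration and reported alongside the table with the
  Kish effective sample size. The exact closed form
  `B_k = sum_{j > k} p_j` is the production path; the Monte-Carlo
  simulator reproduces it within reported binomial error and exists to
  mirror the resampling procedure and quantify simulation noise.
* **Proportional-offer denominator.** The per-proposer opportunity
  denominator (64 for a full triadic session, 32 dyadic; halved for
  first-half subsets) is the default, because per-trial averages then
  mean the same thing in both conditions; a session-level denominator
  (64 throughout) is available behind `denominator = "session"`.
* **Ties in acceptance accuracy.** Equal-offer triadic trials are
  excluded from the highest-offer acceptance denominator: "highest" is
  undefined on ties.

## Calibration and test scale

The test suite checks each model against data simulated from its own
generative process at the study's scale (7 triads × 16 sessions),
asserting ≥ 90% coverage of 95% HPD intervals for the generating fixed
effects, pooled over 20 replicates per model with reduced sampler
settings (2 chains × 400 draws) — sizes chosen to keep the default
suite at desk scale while leaving coverage estimates statistically
meaningful. The power-analysis checks use 4-triad scenarios with 20
replicates over a three-point effect grid (type-I control at the null
point, near-certain detection of an extreme dyadic/triadic contrast,
monotone power in between). `scripts/acceptance.R` re-runs the full
pipeline at 7 triads with the default sampler settings.

## Limitations

* The strategy zoo is a configurable stand-in for behaviour, not a
  fitted cognitive model; power estimates are conditional on it.
* With 7 triads, random-effect scales are weakly identified; the
  models deliberately include only triad (or proposer/pair)
  intercepts, and fits warn below 2 triads.
* The shortest-window HPD can differ from a disjoint HPD region on
  strongly multimodal posteriors; none of the suite's posteriors are
  multimodal in practice.
* Reproduction of externally deposited trial data requires a local
  copy and a schema dialect for it (`load_trials()`); the
  corresponding acceptance test documents the comparison and fails
  informatively when the deposit is absent.
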