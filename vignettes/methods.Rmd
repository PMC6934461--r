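---
title: "Methods: camera-trap social networks for red fox groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera-trap social networks for red fox groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Urban red foxes (*Vulpes vulpes*) forage alone but, at high density, live in
territorial groups around a dominant pair. Their social structure is hard to
observe directly: they are nocturnal, and not every animal can be collared.
Camera traps at provisioned food patches record *who* was *where* and
*when*; everything social must be inferred from temporal co-occurrence.
`foxsna` implements that inference chain:

1. photographs → **visits** (15-minute gap rule);
2. visits → **encounters** (temporal overlap of two foxes' visits at one
   patch) and **grouping events** (chains of pairwise-overlapping visits;
   the *gambit of the group*: all members of a spatiotemporal group are
   taken to be associating);
3. grouping events → **simple-ratio-index (SRI) networks**, one per
   territory and season, with one-day (noon-to-noon) sampling periods:
   `SRI = x / (x + yAB + yA + yB)` where `x` counts days a dyad shared a
   group and the `y` terms count days one or both were seen apart;
4. networks → global connectivity (unweighted/weighted density,
   transitivity), node position (strength, eigenvector centrality, Onnela
   weighted clustering), assortment by sex and status;
5. inference by **restricted data-stream permutation**: coefficients of
   models fitted to observed networks are compared against the same
   coefficients re-estimated on networks rebuilt from permuted group
   memberships, swapped only within territory and survey day.

## Survey structure and filters

Days run noon to noon so one nocturnal activity bout is one sampling period
(12:00:00 opens the new day). Surveys last 40 days and repeat in four
consecutive seasons. Filters follow the field protocol: cubs under five
months are excluded; contact rates use foxes seen on at least 5 days per
survey; network metrics use foxes seen on at least 5 days in a
patch-standardised dataset (the patches common to all four seasons of a
territory) so networks are comparable within territories. Residents are
foxes seen on at least 20 days per season that share at least 2 associations
with another resident; the circular clause is resolved by a monotone fixed
point (start from all foxes passing the day criterion, repeatedly drop foxes
without enough associations to current members). A fox resident in two
territories in one season is assigned to the territory with more days seen,
then alphabetically - the field protocol states only the one-territory
constraint, so the tie-break is ours.

## The synthetic world

Because the original field data are not redistributable, the package ships a
seeded generator (`scenario_config()`, `simulate_scenario()`) whose defaults
mirror the stated design: 7 territories, 4-6 monitored patches each, 40-day
surveys in four seasons, groups of 4-8 independent foxes led by one dominant
male and one dominant female, provisioning at 2-7 days/week, and intruding
non-residents (neighbours or strangers) that are male-biased in winter.

Two processes generate visits:

* **solo visits** - per fox, patch and day, a Poisson number of visits with
  a log-linear rate in sex, status and season (`effects`); the default
  baseline is 0.5 visits/patch/day with a winter deficit (-0.4), matching
  reduced winter foraging at patches;
* **grouping events** - per patch and day, a Poisson number (0.5/day) of
  social aggregations. A seed fox is drawn proportionally to social
  propensity and every other resident joins with probability
  `join_base * preference[seed, joiner] * exp(eta_seed + eta_joiner)`,
  where `eta` is the log-linear social propensity (`social_effects`) and
  `preference` is a symmetric dyadic weight in [0, 1]. Attendance intervals
  are drawn to overlap, so downstream grouping-event reconstruction recovers
  them. Making attendance proportional to the *product* of both members'
  gregariousness is a deliberate choice: individual-level social effects
  then act on group composition (who sits in small versus large groups),
  which is the only channel a margin-preserving permutation test can see
  (see below).

Visit durations are exponential (mean 600 s) truncated at 2 h. Photographs
are emitted on a grid denser than 15 minutes with one photo exactly at the
visit start and end, and ground-truth visits closer than 16 minutes are
merged, so `collapse_to_visits()` reconstructs the simulated visit set
*exactly*; the generator is usable as an oracle for the whole front end.
The generator states a world; it does not emulate patch geometry, weather,
camera failure, or misidentification, so a green test establishes
correctness of the inference chain, not robustness to field noise.

## Permutation inference

`restricted_swap()` performs checkerboard trial swaps: two groups from the
same territory and survey day, one random member of each; the pair is
exchanged only if each is absent from the other group. Every accepted swap
preserves all group sizes and each fox's daily group-membership counts.
Because group sizes are invariant, the proposal is symmetric and the chain's
stationary distribution is uniform over the margin-preserving class. Two
tempting variants are biased and were rejected (one after empirically
mis-calibrating the Manly/Bejder test): sampling the exchanged pair directly
from the checkerboard candidates over-weights states with few candidates,
and repeating proposals until one succeeds over-weights states by their
acceptance rate. A rejected trial therefore counts as a chain step.

`permutation_chain()` is cumulative: from the observed data it performs
`swaps_per_perm` trials, records the metric, and repeats `n_perm` times
(default 2000 x 10, the field-protocol setting). `P_rand` is the fraction of
null statistics strictly exceeding the observed one; two-tailed significance
at the 0.05 level means `P_rand` outside [0.025, 0.975]. *Chain length
matters*: the 10-swaps-per-sample setting was tuned (in the original
protocol's words, "required to stabilise P-values") to that study's data
volume. Our tests scale the trial count so that `n_perm * swaps_per_perm`
is a fixed multiple of the number of groups: at low ratios the sampled null
hugs the observed state and the tails of `P_rand` over-disperse
(anticonservative), so coefficient chains in the acceptance suite use a
trials-to-groups ratio of 40, the smallest power of the grid we examined at
which the acceptance suite's own 200-replicate calibration sits at the
nominal 5% level. Power configurations were paired, during design, with
null-world runs of the identical configuration to confirm their size.

**What the null preserves is what the test cannot detect.** A sex- or
season-specific deficit in *presence* (fewer visits, fewer days seen) is
reproduced exactly by every permuted dataset, because daily memberships are
margins. Only *composition* - who shares a group, and whether an
individual's memberships are disproportionately singletons - is testable.
The permutation metrics therefore target composition: the
`aggregate = "fox_season"` contact metric models total group-based contacts
per fox-survey with an offset of log(total memberships), i.e. social
selectivity per membership. `manly_bejder_test()` uses the SD of the SRI
(the classical preferred/avoided-companion statistic): preference structure
inflates the dispersion of dyadic indices relative to the swap null
(one-tailed, `P = Pr(null >= observed)`).

## Models

Daily contact rates (associations per fox, patch and day, zeros included)
are modelled as Poisson GLMMs with sighting frequency and the
sex x status x season interaction (`fit_model()`, backed by `lme4`,
maximum likelihood throughout); model reduction is stepwise with deviance
tests respecting marginality (`stepwise_reduce()`); post hoc cell contrasts
are Sidak-adjusted z-tests on the fixed-effect covariance
(`tukey_contrasts()`). Encounter durations, which are mostly recorded zeros
(start-only encounters are set to zero by protocol), use a two-part hurdle
(`fit_hurdle_duration()`): a logistic mixed model for zero versus positive
and a zero-truncated negative binomial with a log link for positive seconds,
both with a dyad random intercept; the truncated part is fitted by direct
maximum likelihood with Gauss-Hermite quadrature (15 nodes by default) over
the random effect, since no pre-installed fitter covers truncated NB mixed
models. Repeatability of network position uses intercept-only mixed models
with individual and territory random effects;
`ICC = var_ind / (var_ind + var_terr + var_res)`, classified low (< 0.3) /
moderate / high (> 0.7). When a dataset has a single territory the territory
component is dropped and reported as zero.

## Numerical choices and edge cases

* A gap of exactly 15 minutes *splits* visits (the protocol's ">= 15 min"
  reads the boundary as a separator); touching visits (zero overlap) count
  as encounters of 0 s.
* Midnight-spanning encounters belong to the period of their start
  ("before midnight" = clock time in [12:00, 24:00)); the before-midnight
  flag proxies food availability because households provision in the
  evening.
* Dyads with an empty SRI denominator get index 0.
* Eigenvector centrality takes the absolute leading eigenvector scaled to
  maximum 1 (a fixed per-network scale; cross-network comparability comes
  from identical construction, not normalisation). In disconnected networks
  scores concentrate on the dominant component.
* Onnela clustering normalises weights by the network maximum and is
  undefined (NA) for nodes of binary degree < 2; transitivity is computed on
  the binarised graph.
* `P_rand` ties (null equal to observed) count as not-greater.
* Wilcoxon effect size is `r = Z / sqrt(n)` with Z oriented on the reported
  `W = min(V+, V-)` (so r <= 0, magnitude = effect size).
* The days-between-associations extrapolation is `round(1 / rate)`.

## Test design (what the suite establishes)

Deterministic rules are tested against independent brute-force oracles:
gap-scan collapse, per-second co-presence counting, union-find interval
components, exhaustive per-day SRI tallies, triple-enumeration graph
metrics, shifted power iteration for eigenvectors, sign-enumeration
Wilcoxon. The acceptance suite additionally checks, end to end on simulated
worlds: the 600-second worked overlap example; reciprocal-rate
extrapolations; margin preservation over 10^4 swaps; metric-oracle agreement
on every graph topology with up to 6 nodes (random weights; random weights
avoid eigen-ties on symmetric topologies) plus 200 larger graphs; permutation
calibration at nominal alpha = 0.05 (200 null-world replicates at 500
permutations, both for a null model coefficient and the Manly/Bejder size)
and Manly/Bejder power >= 95% against two 3-fox cliques (preference 0.9
within, 0.05 between); recovery of a -0.5 winter social deficit for males
with significant `P_rand` in >= 90% of 50 replicates of the full 7-territory
design (a prospective power analysis chose the spring+winter subset and the
composition-targeting offset metric, and checked the identical
configuration against a null world); ICC recovery of variance fractions
0, 1/3 and 0.5 within +-0.05 at 200 individuals x 4 seasons. Simulation
sizes are scaled down from the protocol's 2000 permutations to 500 to fit a
serial-CPU budget; calibration does not depend on world size.

## Known limitations

* Data-stream permutations cannot detect effects expressed purely through
  sighting margins (by design); rate effects must touch group composition
  to be testable, and the vignetted power analysis applies to the
  generator's social model, not to arbitrary worlds.
* The cumulative chain is asymptotically exact but finite chains trade
  power against runtime through the trials-to-groups ratio.
* The hurdle fitter uses non-adaptive quadrature; with very large dyad
  variance (sigma >> 1) more nodes may be needed.
* Grouping events are chained within a survey day; a visit chain spanning
  the noon boundary is split at the day line (rare for nocturnal activity).
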