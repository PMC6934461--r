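# foxsna

Social network analysis of red fox (*Vulpes vulpes*) camera-trap detections
at provisioned food patches.

Urban foxes forage alone but live in territorial groups around a dominant
pair. Camera traps at food patches record identified photographs (who,
where, when); `foxsna` turns those detection streams into social inference:

* **visits** — photographs of a fox at a patch separated by ≥ 15 min are
  separate visits; survey days run noon-to-noon;
* **encounters** — temporal overlap of two foxes' visits at a patch
  (durations in seconds; start-only encounters are zeros);
* **grouping events** — chains of pairwise-overlapping visits (gambit of
  the group);
* **networks** — simple-ratio-index association matrices per territory and
  season, `SRI = x / (x + yAB + yA + yB)` over one-day sampling periods,
  with global metrics (unweighted/weighted density, transitivity), node
  metrics (strength, eigenvector centrality, Onnela weighted clustering)
  and discrete assortativity (sex, status);
* **inference** — restricted data-stream permutations (checkerboard swaps
  within territory and survey day), the Manly/Bejder test for non-random
  association (`P = Pr(SD_null >= SD_obs)`), permutation P-values for model
  coefficients (`P_rand = sum(beta_obs < beta_rand) / n`, two-tailed
  significance outside [0.025, 0.975]), Poisson GLMMs for daily contact
  rates, a truncated-negative-binomial hurdle for encounter durations, and
  ICC repeatability of network position;
* **synthetic data** — a seeded generator with known ground truth (7
  territories x four 40-day seasonal surveys, dominance-structured groups,
  dyadic preference, winter-male-biased intruders) so the whole pipeline is
  testable without field data.

## Worked example

```r
library(foxsna)
cfg    <- scenario_config(n_territories = 2, seed = 42)
bundle <- run_pipeline(cfg, n_perm = 500, verbose = FALSE)

head(bundle$summary$global[, c("territory", "season", "n_nodes",
                               "weighted_density", "mb_p", "nonrandom")])
#>   territory season n_nodes weighted_density  mb_p nonrandom
#> 1       T01 spring       8            0.303 0.902     FALSE
#> 2       T01 summer       8            0.326 0.228     FALSE
#> 3       T01 autumn       8            0.372 0.074     FALSE
#> 4       T01 winter       8            0.172 0.510     FALSE
#> 5       T02 autumn       8            0.380 0.002      TRUE
```

Weighted density is the mean association index of the network: foxes in T01
shared a group on roughly a third of the days either was seen in autumn, and
winter cohesion drops (0.172), the generator's stated winter deficit. `mb_p`
is the Manly/Bejder permutation P-value; only T02-autumn shows significantly
non-random association here (the default world has uniform dyadic
preference, so ~5% of networks flag by chance).

```r
head(subset(bundle$summary$nodes, resident), 3)
#>      fox territory season strength eigenvector clustering resident
#> 1 T01F01       T01 spring     2.25       0.926      0.731     TRUE
#> 2 T01F02       T01 spring     2.47       1.000      0.770     TRUE
#> 3 T01F03       T01 spring     2.25       0.928      0.732     TRUE

bundle$summary$icc
#>        metric   icc class
#> 1    strength 0.000   low
#> 2 eigenvector 0.275   low
#> 3  clustering 0.000   low
```

Strength is the sum of a fox's SRI edge weights (direct connectivity);
eigenvector centrality is scaled to a maximum of 1 per network; ICCs near
zero say individual network position is not repeatable across seasons in
this world (position varies more within than between individuals). A daily
contact rate `r` extrapolates to one association every `round(1/r)` days:

```r
days_between_associations(c(0.073, 0.037, 0.459, 0.237))
#> [1] 14 27  2  4
```

Permutation inference on a coefficient (is the sex effect on contacts
larger than expected given everyone's sighting history?):

```r
scn    <- simulate_scenario(cfg)
# ... build visits -> grouping events -> gbi_matrix(), then:
# metric <- make_contact_metric(scn$attributes, "sexM", aggregate = "fox_season")
# null   <- permutation_chain(gbi, metric, n_perm = 2000, swaps_per_perm = 10)
# p_rand(null)
```

## Command line

```sh
Rscript inst/cli/foxsna.R simulate --seed 1 --territories 7 --out sim/
Rscript inst/cli/foxsna.R run --seed 1 --n-perm 2000 --out results/
```

`run` accepts external CSVs (`--detections --attributes --calendar
--provisioning`) with ISO-8601 timestamps; outputs are delimited text,
GraphML networks and a JSON manifest.

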