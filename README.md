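# reefpred

Community-level simulation of gape-limited fish predation on coral reefs.

## The problem

Most reef fishes are eaten by other fishes, yet fish-on-fish predation is
almost never observed: strikes last milliseconds and piscivore guts are
usually empty. `reefpred` quantifies predation the other way around — by
simulation from a censused community. Every surveyed individual is converted
from total length (TL, cm) into the functional traits that decide whether a
predation event is physically possible:

* prey **body depth** `D`, a per-group power law
  `ln(D) = a_f + b_f·ln(L)` over the three prey functional groups
  (cryptobenthic, epibenthic, social);
* predator **gape** `G`, linear per predator functional group
  (grabbers, engulfers): `G = a_f + b_f·L`.

Random predator–prey pairings are then filtered through the feasibility
window on relative prey size, `0.14 ≤ D/G ≤ 0.7` (the band containing ~95%
of observed piscivory); pairings outside it are *forbidden links*. The
surviving pool of potential predation events is summarised by predator size
bin `b` and prey functional group `f` via the relative contribution

```
C[f,b] = A[f,b] / Σ_f A[f,b]
```

and compared against literature gut-content records — predator sizes imputed
uniformly from each study's reported size range, replicated 1,000 times —
using a kernel-density overlap coefficient `∫ min(f̂, ĝ)` and per-bin
envelope contrasts.

The package is for quantitative community ecologists who want a tested,
seed-reproducible version of this pipeline: survey standardisation,
trait conversion, Monte-Carlo pairing, diet metanalysis resampling and
simulated-vs-observed comparison, plus a synthetic-data generator so the
whole machinery runs and is testable without any field data.

## Worked example

```r
library(reefpred)

## traits: a 10 cm cryptobenthic fish is 2.26 cm deep; a 10 cm grabber
## opens 1.74 cm
prey_body_depth(10, "cryptobenthic")   # 2.258472
predator_gape(10, "grabber")           # 1.74

## a synthetic 5,000-fish community with the default composition
## (59/7/34% cryptobenthic/epibenthic/social prey, 5.4% predators)
comm <- generate_community(community_config(n_individuals = 5000), seed = 1)

## half a million attempted pairings in 50 replicates
pool <- simulate_events(comm, config = simulation_config(10000, 50), seed = 2)
pool
#> Potential predation event pool: 210372 feasible of 500000 attempted (acceptance 0.421)

summarize_sizes(pool, "predator")
#> $median 6.96   $mean 8.17   $interval_low 1.79   $interval_high 19.5

## observed events: synthetic gut records, sizes imputed from ranges
gut <- generate_gut_records(gut_config(n_records = 150), seed = 3)
obs <- draw_observed_sizes(gut, n_reps = 200, seed = 4)
ov  <- overlap_summary(pool$events$predator_tl, observed_size_distribution(obs))
#> overlap mean 0.245 (min 0.235, max 0.255), pooled 0.231
```

Read: in this synthetic community 42% of random pairings are
morphologically feasible; the median feasible predator is ~7 cm TL, and 95%
of potential events involve predators under ~20 cm — predation is a
small-fish process. The size distribution of simulated events overlaps the
(large-predator-biased) gut-content literature by only ~25%: most simulated
predation falls at sizes the literature rarely samples. Per-bin diet
composition comes from `prey_group_contributions(pool)` and
`observed_contributions(obs)`, contrasted with `compare_contributions()`.

Real survey data enter through CSVs (see the small synthetic examples in
`inst/extdata/`):

```r
survey <- read.csv(system.file("extdata", "synthetic_survey.csv", package = "reefpred"))
traits <- read.csv(system.file("extdata", "synthetic_traits.csv", package = "reefpred"))
comm <- standardize_community(survey, target_area_per_zone = 300, seed = 4)
comm <- classify_individuals(comm, traits)
run  <- run_pipeline(comm, read_gut_csv(system.file("extdata",
          "synthetic_gut_contents.csv", package = "reefpred")), seed = 7)
```

`run_pipeline()` executes every stage with per-stage seeds derived from one
global seed and returns sizes, contributions, overlap, contrasts and a
manifest; reruns are bit-identical.

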