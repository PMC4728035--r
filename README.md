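# spoorstats

Estimation of large-carnivore population density and size from vehicle-based
track (spoor) counts, with bootstrap precision analysis, linear
spoor-to-density calibration, rank-based comparison between land-use types,
and a simulator for parameter-recovery studies.

## The problem

Spoor counts are a cheap, widely used index of carnivore abundance in
southern African savannas: drive transects slowly in the early morning,
record every fresh track event (species, group size, position), discard
spoor older than 24 h or repeats of an already-recorded individual. The
density of spoor along roads is approximately proportional to the density of
the animals that made them, so an index survey can be converted into animals
per unit area through a calibration fitted against populations of known
density:

```
spoor density  S = 100 · n / L          (spoor per 100 km driven)
population density  D = max(0, (S − b) / a)   (animals per 100 km²)
population size  N = round(D · A / 100)       (A = stratum area, km²)
```

with per-species slope `a` (default 3.26; 1.90 for leopard) and intercept
`b` (default 0). Precision is assessed by bootstrapping *inter-spoor
intervals* — the gaps between consecutive spoor when transects are
concatenated — at growing sample sizes, yielding CI-vs-effort and
CV-vs-effort curves and an operational "how many spoor are enough" rule.
Spoor densities across land-use strata (private conservancy / resettlement /
communal) are compared with a tie-corrected Kruskal–Wallis test implemented
from first principles, and a proportional-loss scenario model extrapolates
the consequences of converting private wildlife land to other uses.

The package ships a worked 2008 survey from a south-eastern Zimbabwe
conservancy landscape (423 spoor over 955 km driven, three land-use types)
as plain-CSV data, plus a Poisson encounter-process simulator
(`simulate_survey()`) whose generating model is exactly the calibration's
inverse, so estimator correctness is testable against known truth.

## Worked example

```r
library(spoorstats)
ds <- filter_spoor(svc_survey())

effort_summary(ds)
#>            lut area_km2 transect_sum_km sample_penetration surveyed_km
#> 1      private     2530             348                7.3         696
#> 2 resettlement      960             149                6.4         149
#> 3     communal      984             110                8.9         110

round(density_matrix(ds), 2)
#>                private resettlement communal
#> lion              9.34         0.00        0
#> leopard          14.51         0.00        0
#> cheetah           1.44         0.00        0
#> wild_dog         18.53         0.00        0
#> spotted_hyaena   14.80         2.01        0
#> brown_hyaena      1.72         0.00        0

est <- estimate_table(ds, n_bootstrap = 1000, seed = 1)
subset(est, lut == "private", c(species, pop_density, pop_size))
#>           species pop_density pop_size
#> 1            lion   2.8647486       72
#> 2         leopard   7.6376286      193
#> 3         cheetah   0.4407306       11
#> 4        wild_dog   5.6854242      144
#> 5  spotted_hyaena   4.5395247      115
#> 6    brown_hyaena   0.5288767       13

compare_lut_densities(ds)
#> Kruskal-Wallis rank test (tie-corrected)
#>   H = 13.3609, df = 2, p = 0.001255
#>   group sizes: 6, 6, 6  tied groups: 1
```

Reading: on the private conservancy (2,530 km², 696 km surveyed) the survey
supports roughly 72 lion and 193 leopard; on resettlement land only spotted
hyaena remain (6 animals); communal land carries no detectable large
carnivores. Spoor densities differ significantly between land-use types.

Precision analysis for one species:

```r
iv <- inter_spoor_intervals(ds, "leopard", "private")
curve <- bootstrap_curve(iv, n_bootstrap = 1000, seed = 7)
stabilization_point(curve)   # sample size where the CV curve flattens
```

National-scale scenario:

```r
fr <- fraction_private_resettled(zimbabwe_ledger())  # 0.709
national_decline(decline_scenario("cheetah", share_private = 0.8,
                                  fraction_resettled = fr))
#> $per_species: cheetah 56.75  $mean: 56.75  $max: 56.75
```

## Command line

A thin CLI wraps the same functions (`inst/exec/spoorstats`):

```sh
spoorstats validate  survey_dir/
spoorstats metrics   survey_dir/ --out tables/
spoorstats estimate  survey_dir/ --bootstrap 1000 --seed 7 --out est.csv
spoorstats compare   survey_dir/ --out kw.json
spoorstats simulate  --config scenario.json --out sim_dir/ --seed 4
spoorstats run       --config run.json
```

Surveys are three CSVs (`records.csv`, `transects.csv`, `strata.csv`);
configs are JSON mirroring `simulation_config()` / `run_config()`.

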