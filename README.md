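# flywaylinks

Country-level migratory connectivity from bird-tracking records along the
African–Eurasian flyway.

Millions of landbirds and raptors breed in Europe and winter in sub-Saharan
Africa, and their conservation runs through country-level policy
instruments (the African–Eurasian Migratory Landbirds Action Plan and the
Raptors MOU). `flywaylinks` turns individual tracking records — one bird,
its breeding country, and the sub-Saharan country where it spent the
nonbreeding season — into the quantities those instruments can use:
migratory links between countries, their strengths, per-country and
per-species syntheses, knowledge-gap metrics, and priority lists for
future tracking. It is written for movement ecologists and conservation
scientists compiling multi-study tracking reviews.

## The model

A **population** is all individuals of a species breeding in one European
country. Populations with fewer than 3 migration records are excluded.
For a retained population with records $n_1, \dots, n_k$ across $k$
nonbreeding countries:

* each distinct (species, breeding country, nonbreeding country) triple is
  an **observed link** with record count $n_j$;
* **inferred links** fill geometric gaps: the minimum convex polygon of
  the nonbreeding-range centroids of observed countries is intersected
  with the species' nonbreeding range in every other country, and each
  intersected country gains a link whose record count is interpolated
  from neighbouring observed countries' record densities
  ($\widehat{n}_D = \overline{n_i / A_i} \cdot A_D$, areas measured as
  nonbreeding range within each country in an equal-area projection);
* **link strength** is $100 \, n_j / \sum_j n_j$ over the population's
  links (observed + interpolated), so strengths sum to 100% per
  population.

Downstream, strengths weighted by national shares of the European
population give the **importance** of each African country per species;
per-country recounts give connectivity summaries; the share of present
species without links gives the **gap percentage**; and for species with
decreasing European trend, a greedy largest-share-first rule selects the
countries needed to reach 50% coverage of each subregional population —
the **priorities for future tracking**.

A synthetic-world generator (Voronoi countries on two abstract continents,
Dirichlet-multinomial connectivity, biased tracking effort) makes the
whole pipeline testable without any third-party downloads. See the
methods vignette (`vignettes/flyway-connectivity.Rmd`) for the full
account of the model, the numerical choices and the generator's design.

## Worked example

The western-European breeding population of the European turtle dove
(*Streptopelia turtur*) is spread over seven countries, with tracking data
for France and the United Kingdom:

```r
library(flywaylinks)
ex <- example_turtle_dove()
shares <- population_shares(ex$populations, "turtle_dove", "european")
shares
#>   country pop_size share_pct
#> 1     ESP    73790     73.79
#> 2     FRA    24860     24.86
#> 3     PRT      880      0.88
#> 4     GBR      230      0.23
#> 5     BEL      180      0.18
#> 6     NLD       40      0.04
#> 7     LUX       20      0.02

select_priority_countries(shares, ex$tracked_countries, 50)
#>   country share_pct coverage_before coverage_after
#> 1     ESP     73.79           25.09          98.88
```

Tracked countries cover 25.1% of the subregional population — short of
the 50% target — and the greedy rule adds exactly Spain, after which
coverage is 98.9%: the turtle dove in Spain is a priority for future
tracking. Strengths work the same way at any sample size; a three-bird
population split 2:1 between Mauritania and Senegal gives:

```r
example_population_links(c(MRT = 2, SEN = 1))[, c(4, 6, 7)]
#>   nonbreeding_country record_count strength_pct
#> 1                 MRT            2     66.66667
#> 2                 SEN            1     33.33333
```

i.e. 66.7% / 33.3% — a reminder that strengths from tiny samples are
approximations, which is what the package's recovery experiment
quantifies (see `analysis/05_recovery.R`).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on the default
synthetic flyway and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # world, species, records
Rscript analysis/02_links.R               # observed + inferred links
Rscript analysis/03_synthesis.R           # connectivity, importance, trends
Rscript analysis/04_gaps_priorities.R     # gaps and priority combos
Rscript analysis/05_recovery.R            # strength-recovery validation
```

Each stage reads only files written by earlier stages, in the same CSV /
GeoJSON / YAML formats real data would use, and prints a short summary of
what it found.

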