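---
title: "Country-level migratory connectivity: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Country-level migratory connectivity: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywaylinks)
```

## The problem

Long-distance migratory landbirds and raptors of the African–Eurasian flyway
breed in Europe and spend the nonbreeding season in sub-Saharan Africa.
International instruments such as the African–Eurasian Migratory Landbirds
Action Plan and the Raptors MOU operate at the level of *countries*, so the
question this package answers is geopolitical rather than ecological: which
pairs of countries are connected by which bird populations, how strongly,
how well do we know it, and where should tracking effort go next?

The unit of input is a **migration record**: one tracked individual (by
light-level geolocator, satellite transmitter or GPS logger) with a known
breeding country in Europe and the sub-Saharan country where it spent most
of the nonbreeding season. A **population** is all conspecifics breeding in
one European country. A **migratory link** is a (species, breeding country,
nonbreeding country) edge, and its **strength** is the percentage of the
population's individuals assigned to that nonbreeding country.

## The link model

### Filtering

Populations with fewer than `min_records_per_population` records (default
3) are excluded everywhere. With one or two birds a strength estimate is
dominated by individual idiosyncrasy; three is the smallest sample for
which a split such as 2:1 is even expressible. The filter is a
configuration constant, not a tuning knob.

### Observed links

Each retained population contributes one observed link per distinct
nonbreeding country, weighted by its record count. Record counts over a
population's observed links always sum to the retained record count
(conservation), and this is asserted by tests.

### Inferred links

Tracking samples are small, so a population observed in countries B and C
was plausibly missed in a country D lying between them inside the species'
nonbreeding range. The inference step makes that precise:

1. For each observed country, anchor the link at the **area-weighted
   centroid of the species' nonbreeding range clipped to that country**,
   computed in an equal-area projection.
2. Build the **minimum convex polygon** (convex hull) of these centroids.
3. Every African country that is not observed, holds a positive-area part
   of the nonbreeding range, and whose range-within-country geometry
   intersects the hull (boundary contact counts) gains one *inferred* link.

Degenerate hulls are handled explicitly: with one observed country there is
nothing to interpolate between and no inference happens; with two (or any
collinear centroid set) the hull is the segment joining the extreme
centroids and intersection is tested against that segment.

### Interpolated record counts

Strengths need record counts for inferred links. These are transferred from
the **record density of neighbouring observed countries**: for each
observed country *i* sharing a boundary with the inferred country *D*,

\[ \mathrm{density}_i = \frac{\mathrm{records}_i}{\mathrm{area}_i}, \qquad
   \widehat{\mathrm{records}}_D = \overline{\mathrm{density}} \times
   \mathrm{area}_D, \]

where areas are the species' nonbreeding-range areas within each country.
When no observed country borders *D*, the two observed countries with
nearest range centroids act as neighbours, which makes the rule total
(inference guarantees at least two observed countries exist). The exact
published formulation of this interpolation lives in supplementary material
we do not reproduce; the density-transfer rule above is this package's
documented reading of "interpolated from the density of records in
neighbouring countries", and it is isolated behind one function
(`interpolate_record_count()`) so an alternative can be swapped in.
Interpolated counts are kept fractional: rounding would silently break the
normalisation invariant.

### Strengths

With all counts in place, strength is simply
`100 * record_count / sum(record_count)` over the population's links, so
strengths always sum to 100 per population (asserted to 1e-6). Strengths
are stored at full precision; the one-decimal presentation used in reports
is applied only at write time (`round_digits`).

## Syntheses

* `country_connectivity()` / `flyway_counts()`: per-country counts of
  links, species tracked and partner countries; links touch a European
  country on the breeding side and an African country on the nonbreeding
  side. All counts are plain recounts of the link table and are tested
  against independent recount oracles.
* `species_importance()`: each population's strengths are weighted by the
  share of the species' European population breeding in that country and
  summed per African country. The summed importance equals the summed
  share of the tracked populations — tracked mass is redistributed, never
  created — and this conservation is a test invariant.
* `cumulative_trends()`: studies are dated by publication year; an
  observed link by the earliest study contributing a record to its triple.
  An inferred link has no study of its own, so it is dated by the earliest
  study of its population — it exists only by virtue of the population's
  pooled records. Studies without a year are dropped with a warning.
* `fit_effort_curve()`: a Michaelis–Menten-type saturating curve
  `links = a n / (b + n)` fitted by Levenberg–Marquardt. The family is a
  design choice: links accumulate with records and saturate once every
  true nonbreeding country is sampled, and the published analysis we
  emulate discusses (non-)attainment of an asymptote, which this family
  expresses as `n >= 19 b` (95% of `a`). With noisy or flat data the two
  parameters can drift along a ridge; we therefore optimise the residual
  function directly rather than through an `nls`-style model object, and
  a links-constant input degenerates cleanly to `a = const, b = 0`.

## Gaps and priorities

A species is *present* in a European country when its population-table
entry has positive size, and in an African country when its nonbreeding
range overlaps the country with positive area (a boundary-point touch is
not presence). It is *tracked* in a country when any link — observed or
inferred — touches that country. The gap percentage is
`100 * (present - tracked) / present`.

Priorities target species with decreasing European trend. For each such
species and each subregion it occupies, coverage starts from the summed
shares of already-tracked countries; untracked countries are added
greedily in descending share order (ties by country code) until coverage
reaches the threshold (default 50%) or the subregion is exhausted. Greedy
largest-first is a design choice — the rule is stated as "countries needed
to complement existing studies" without an algorithm — and it is
deterministic and reproduces the published worked example (a
turtle-dove population 25.1% covered by France + UK, completed by Spain).
European shares come from national population sizes; African shares use
nonbreeding-range areas because no African national population sizes
exist. Species–country combinations are deduplicated across subregional
runs, so a country appears at most once per species.

Two schema decisions here: the population table carries a
`species_group` column (gap analysis needs a group for species that have
no tracking records at all, so the group cannot come from the record
table), and the trend flag is constant per species because it is a
European-level attribute.

## Geometry and numerics

* All polygon booleans go through the Clipper library (`polyclip`), with
  the nonzero fill rule and an explicit snapping grid of 1e-13 of the
  coordinate extent (the library default of ~1e-9 is too coarse for the
  package's 1e-9-relative area invariants).
* Areas and centroids are the shoelace and signed-area-weighted closed
  forms; holes carry negative signed area and subtract naturally.
* Geometry validity is enforced on ingest by re-expressing rings as the
  boundary of their nonzero-fill region (`geom_repair()`), the polygon
  analogue of a zero-width buffer; repairs are logged.
* Coordinates are WGS84 lon/lat; every area/centroid computation first
  applies the configured equal-area projection. The default `"cea"` is the
  Lambert cylindrical equal-area projection on a spherical earth (km
  units): degrees-as-planar areas would be biased poleward by `cos`
  latitude. `"planar"` is available for abstract/synthetic coordinates and
  for tests with closed-form expectations.
* Intersections between polygons that share boundaries (a range built as
  a union of countries against an adjacent country) can leave hairline
  slivers; any intersection below 1e-8 of the smaller operand's area is
  treated as empty (`area_positive()`). Without this, inference can emit
  spurious links carrying ~1e-9 records.
* Boundary-sharing adjacency (needed by the interpolation's neighbour
  rule) is estimated as `area(offset(A, delta) ∩ B) / delta`, which scales
  with the shared edge length, while a corner-only contact contributes
  O(delta); the threshold of `100 delta` separates the two regimes.
* Near-tied shares (equal-area countries differing at the 1e-13 snapping
  level) are ranked as exact ties, broken by country code, keeping the
  greedy selection deterministic.

## The synthetic world

Real inputs (compiled record tables, boundary and range polygons, national
population tables) are large third-party downloads, so every stage is
exercised on generated data with the same statistical structure:

* **Geography**: two disjoint rectangles tessellated into contiguous
  Voronoi countries around uniformly seeded points; subregions by
  quadrant. Voronoi cells partition the rectangle exactly (a test
  invariant at 1e-9 relative) and give a realistic contiguous adjacency
  graph.
* **Species**: contiguous unions of countries for breeding and
  nonbreeding ranges (sizes `1 + Poisson`), with a configurable
  probability of removing one interior country from a nonbreeding range —
  a geometric hole for the inference step to reason around. The defaults
  use a 3:1 landbird:raptor ratio and a 32% decreasing fraction,
  mirroring the real species list's proportions.
* **Populations**: log-normal national sizes (meanlog 10, sdlog 1.5 —
  national breeding populations spanning roughly 10^3–10^6).
* **Truth**: per population, nonbreeding proportions over the range's
  countries from a symmetric Dirichlet (concentration 0.8, giving a few
  dominant destinations per population as real strength tables show).
  Truth support never leaves the range, so inferred links can never point
  outside it — a cross-module test.
* **Records**: populations are tracked with probability shaped by
  per-subregion effort bias (western/central Europe over-sampled, eastern
  Europe under-sampled) and per-group bias (raptors over-sampled);
  tracked populations draw a negative-binomial record count (mu 8, size
  1.2 — matching the observed regime of roughly ten records per retained
  population while leaving substantial mass below 3 to exercise the
  filter), then i.i.d. multinomial nonbreeding countries from the truth.
  Raptor studies spread over 1996–2021 and satellite tags; landbird
  studies concentrate after 2010 and geolocators.

Seeds are split hierarchically (world / species / truth / records), so
changing the number of species never perturbs the geography, and identical
parameters plus seed give byte-identical record files.

What the generator does **not** emulate: positional error of geolocators,
nonbreeding-season mortality, within-country habitat structure, multi-country
itinerancy (each bird has exactly one nonbreeding country, classified
upstream), and real coastline geometry. Passing tests therefore validate
the *pipeline* — grouping, geometry, interpolation, normalisation,
selection — under the stated sampling model, not the fidelity of any real
tracking dataset.

## Validation strategy and problem sizes

The test suite runs the full engine over ~100 seeded small worlds (5–8
countries per continent, 3 species) checking normalisation, record
conservation, exact agreement of the inference step with a brute-force
hull-intersection oracle (naive hull, exhaustive polygon tests,
sampling-based touch detection), and range membership of inferred links.
The recovery experiment fixes one world and re-samples records: at 500
records per population over 200 replicates the median maximum absolute
strength error must stay within 5 percentage points (the acceptance
property; sampling theory puts the multinomial error near 2–3 points at
that size), while at 3 records per population errors of tens of points
illustrate the small-sample caveat that applies equally to published
strength estimates built on three birds. These sizes keep the whole suite
around a minute on one core while leaving every assertion at full
strength.

## Known limitations

* The interpolation formula is a documented stand-in (see above); its
  effect is confined to inferred links, which carry no observed records by
  definition.
* Strengths are directional (Europe → Africa). The reverse importance of a
  European country to an African nonbreeding population is deliberately
  not computed: tracking is initiated almost exclusively in Europe, so
  African-side representativeness is insufficient.
* Country-level aggregation ignores within-country distribution entirely;
  two populations wintering at opposite ends of a large country are
  indistinguishable here.
* The hull-based inference is planar after projection. For ranges
  spanning very large longitudes the cylindrical equal-area projection
  distorts hull shape; an equal-area azimuthal projection per species
  would be a refinement.
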