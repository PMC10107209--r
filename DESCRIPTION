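Package: flywaylinks
Title: Country-Level Migratory Connectivity from Bird-Tracking Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives, infers and quantifies country-to-country migratory
    links along the African-Eurasian flyway from individual bird-tracking
    records. Records (one tracked individual migrating from a European
    breeding country to a sub-Saharan African nonbreeding country) are
    grouped into national populations, filtered by a minimum sample size,
    and turned into observed links; missing links are inferred from the
    minimum convex polygon of nonbreeding-range centroids and their record
    counts interpolated from neighboring-country record densities; link
    strengths are the per-population percentage of records per nonbreeding
    country. The package aggregates links into country-, species- and
    flyway-level syntheses, quantifies per-country knowledge gaps, and
    selects priority species-country combinations for future tracking under
    a subregional population-coverage rule. A synthetic-world generator
    (Voronoi countries on abstract continents, Dirichlet-multinomial
    connectivity) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    deldir,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    minpack.lm,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
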