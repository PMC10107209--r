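# Country/species/flyway syntheses: shares, connectivity counts,
# importance, trends, effort curves.

test_that("population shares reproduce the turtle-dove worked example", {
  ex <- example_turtle_dove()
  shares <- population_shares(ex$populations, "turtle_dove", "european")
  expect_equal(sum(shares$share_pct), 100, tolerance = 1e-9)
  expect_equal(round(shares$share_pct[shares$country == "ESP"], 1), 73.8)
  expect_equal(round(shares$share_pct[shares$country == "FRA"], 1), 24.9)
  tracked <- sum(shares$share_pct[shares$country %in% ex$tracked_countries])
  expect_equal(round(tracked, 1), 25.1)

  single <- tibble::tibble(species_id = "solo", country = "EUA",
                           pop_size = 42, trend = "other",
                           species_group = "raptor")
  expect_equal(population_shares(single, "solo", "european")$share_pct, 100)
})

test_that("random share tables always sum to 100 per scope", {
  set.seed(3)
  for (rep in 1:10) {
    pop <- tibble::tibble(
      species_id = "SP", country = sprintf("E%02d", 1:8),
      pop_size = stats::rlnorm(8, 8, 2), trend = "other",
      species_group = "landbird")
    expect_equal(sum(population_shares(pop, "SP", "european")$share_pct),
                 100, tolerance = 1e-9)
  }
})

test_that("range shares split by area and match a rasterised oracle", {
  w <- strip_world(n_afr = 2)          # two unit squares
  shares <- range_shares(w$ranges, w$countries, "SP001",
                         scope = "sub_saharan", crs = "planar")
  expect_equal(shares$share_pct, c(50, 50))

  # random polygon vs grid-count oracle
  set.seed(5)
  rw <- random_small_world(4)
  afr <- rw$world$countries[rw$world$countries$continent == "Africa", ]
  sp <- rw$species$species$species_id[1]
  shares <- range_shares(rw$species$ranges, rw$world$countries, sp,
                         "sub_saharan", crs = "planar")
  rg <- range_geometry(rw$species$ranges, sp, "nonbreeding")
  areas_oracle <- vapply(shares$country, function(code) {
    cg <- flywaylinks:::country_geometry(rw$world$countries, code)
    b <- geom_bbox(cg)
    oracle_area_grid(geom_intersection(rg, cg),
                     c(b["xmin"], b["xmax"], b["ymin"], b["ymax"]), n = 250)
  }, numeric(1))
  oracle_pct <- 100 * areas_oracle / sum(areas_oracle)
  expect_true(all(abs(oracle_pct - shares$share_pct) < 0.5))
})

test_that("country connectivity counts equal brute-force recounts", {
  links <- dplyr::bind_rows(
    observed_links_of(c(A01 = 3, A02 = 1), species = "SPA",
                      breeding = "EUR"),
    observed_links_of(c(A01 = 2), species = "SPB", breeding = "EUR"))
  links$strength_pct <- c(75, 25, 100)
  layer <- strip_world(n_afr = 2)$countries
  cc <- country_connectivity(links, "EUR", layer)
  expect_equal(cc$summary$n_links, 3L)
  expect_equal(cc$summary$n_species_tracked, 2L)
  expect_equal(cc$summary$n_partner_countries, 2L)
  # ordering: strength desc
  expect_equal(cc$links$strength_pct, c(100, 75, 25))

  cc_a <- country_connectivity(links, "A01", layer)
  expect_equal(cc_a$summary$n_links, 2L)
  # empty summary, not an error
  empty <- country_connectivity(links[0, ], "EUR", layer)
  expect_identical(nrow(empty$summary), 0L)

  # random tables vs recount oracle
  set.seed(9)
  for (rep in 1:5) {
    rl <- tibble::tibble(
      species_id = sample(c("S1", "S2", "S3"), 30, TRUE),
      species_group = "landbird",
      breeding_country = "EUR",
      nonbreeding_country = sample(c("A01", "A02"), 30, TRUE),
      status = "observed", record_count = 1, strength_pct = 1) |>
      dplyr::distinct(.data$species_id, .data$nonbreeding_country,
                      .keep_all = TRUE)
    cc <- country_connectivity(rl, "EUR", layer)
    expect_equal(cc$summary$n_links, nrow(rl))
    expect_equal(cc$summary$n_species_tracked,
                 length(unique(rl$species_id)))
    expect_equal(cc$summary$n_partner_countries,
                 length(unique(rl$nonbreeding_country)))
  }
})

test_that("species importance weights strengths by population shares", {
  pop <- tibble::tibble(species_id = "SPA", country = c("EUA", "EUB"),
                        pop_size = c(50, 50), trend = "other",
                        species_group = "landbird")
  # one population holding 100%: importance = strength
  solo_pop <- pop[1, ]; solo_pop$pop_size <- 77
  links1 <- observed_links_of(c(AFX = 2, AFY = 3), species = "SPA",
                              breeding = "EUA")
  links1 <- compute_strengths(links1)
  imp1 <- species_importance(links1, solo_pop, "SPA")
  expect_equal(imp1$importance_pct[imp1$african_country == "AFX"], 40)

  # two populations 50/50, strengths to X of 100% and 0%
  links2 <- dplyr::bind_rows(
    compute_strengths(observed_links_of(c(AFX = 5), "SPA", "EUA")),
    compute_strengths(observed_links_of(c(AFZ = 5), "SPA", "EUB")))
  imp2 <- species_importance(links2, pop, "SPA")
  expect_equal(imp2$importance_pct[imp2$african_country == "AFX"], 50)

  # conservation: sum importance == summed share of tracked populations
  set.seed(21)
  for (rep in 1:10) {
    npop <- sample(2:5, 1)
    pops <- tibble::tibble(species_id = "SPA",
                           country = sprintf("E%02d", 1:npop),
                           pop_size = stats::runif(npop, 10, 100),
                           trend = "other", species_group = "landbird")
    tracked <- sample(pops$country, sample(npop, 1))
    links <- dplyr::bind_rows(lapply(tracked, function(bc) {
      k <- sample(1:4, 1)
      compute_strengths(observed_links_of(
        stats::setNames(sample(1:5, k, TRUE), sprintf("A%02d", 1:k)),
        "SPA", bc))
    }))
    imp <- species_importance(links, pops, "SPA")
    shares <- population_shares(pops, "SPA", "european")
    expect_equal(sum(imp$importance_pct),
                 sum(shares$share_pct[shares$country %in% tracked]),
                 tolerance = 1e-6)
    # double-loop oracle
    oracle <- stats::setNames(rep(0, 20), sprintf("A%02d", 1:20))
    for (i in seq_len(nrow(links))) {
      w <- shares$share_pct[shares$country == links$breeding_country[i]]
      oracle[links$nonbreeding_country[i]] <-
        oracle[links$nonbreeding_country[i]] +
        links$strength_pct[i] / 100 * w
    }
    for (i in seq_len(nrow(imp))) {
      expect_equal(imp$importance_pct[i],
                   unname(oracle[imp$african_country[i]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("flyway counts recount the link table with zeros for untouched countries", {
  layer <- strip_world(n_afr = 3)$countries
  links <- compute_strengths(
    observed_links_of(c(A01 = 2, A02 = 3), species = "SPA",
                      breeding = "EUR"))
  fc <- flyway_counts(links, layer)
  expect_equal(fc$n_links[fc$country == "EUR"], 2L)
  expect_equal(fc$n_species_tracked[fc$country == "EUR"], 1L)
  expect_equal(fc$n_links[fc$country == "A03"], 0L)
  empty <- flyway_counts(links[0, ], layer)
  expect_true(all(empty$n_links == 0))
})

test_that("cumulative trends are non-decreasing and date links by earliest study", {
  recs <- dplyr::bind_rows(
    make_records("SPA", "EUR", c("A01", "A01", "A02"), study = "S1",
                 year = 1996L),
    make_records("SPA", "EUR", c("A01", "A02", "A03"), study = "S2",
                 year = 2000L),
    make_records("SPB", "EUR", c("A01", "A01", "A01"), study = "S3",
                 year = 2000L))
  recs$record_id <- sprintf("R%04d", seq_len(nrow(recs)))
  links <- derive_observed_links(recs)
  tr <- cumulative_trends(recs, links)
  expect_equal(tr$year, c(1996L, 2000L))
  expect_equal(tr$cumulative_studies, c(1L, 3L))
  # 1996: SPA-A01 and SPA-A02 exist; 2000 adds SPA-A03 and SPB-A01
  expect_equal(tr$cumulative_links, c(2L, 4L))
  expect_true(all(diff(tr$cumulative_studies) >= 0))
  expect_true(all(diff(tr$cumulative_links) >= 0))

  # a study without a year is excluded with a warning
  recs2 <- recs
  recs2$year_published[recs2$study_id == "S3"] <- NA_integer_
  expect_warning(tr2 <- cumulative_trends(recs2, links), "without")
  expect_equal(max(tr2$cumulative_links), 3L)

  # sort-and-scan oracle on random study sets
  set.seed(13)
  for (rep in 1:5) {
    yrs <- sample(1996:2020, 12, replace = TRUE)
    rr <- make_records("SPX", "EUR",
                       sample(sprintf("A%02d", 1:4), 12, TRUE))
    rr$study_id <- sprintf("S%02d", seq_len(12))
    rr$year_published <- yrs
    rr$record_id <- sprintf("R%04d", seq_len(12))
    ll <- derive_observed_links(rr)
    tr3 <- cumulative_trends(rr, ll)
    for (i in seq_len(nrow(tr3))) {
      expect_equal(tr3$cumulative_studies[i],
                   sum(unique(yrs) <= tr3$year[i]) * 0 +
                     length(unique(rr$study_id[yrs <= tr3$year[i]])))
    }
  }
})

test_that("effort curve recovers noiseless parameters and flags saturation", {
  n <- c(1, 2, 4, 8, 16, 32, 64, 128)
  exact <- tibble::tibble(n_records = n, n_links = 10 * n / (5 + n))
  fit <- fit_effort_curve(exact)
  expect_equal(fit$a, 10, tolerance = 1e-6)
  expect_equal(fit$b, 5, tolerance = 1e-6)
  expect_true(fit$reaches_95pct_asymptote)    # 128 > 19 * 5

  short <- exact[1:4, ]                        # max n = 8 < 95
  fit2 <- fit_effort_curve(short)
  expect_false(fit2$reaches_95pct_asymptote)

  flat <- tibble::tibble(n_records = n, n_links = 4)
  fit3 <- fit_effort_curve(flat)
  expect_true(fit3$degenerate)
  expect_equal(fit3$a, 4)
  expect_equal(fit3$b, 0)

  # noisy recovery at 200 populations within 10%
  set.seed(99)
  nn <- sample(3:150, 200, replace = TRUE)
  noisy <- tibble::tibble(
    n_records = nn,
    n_links = pmax(1, 12 * nn / (8 + nn) *
                     exp(stats::rnorm(200, 0, 0.08))))
  fit4 <- fit_effort_curve(noisy)
  expect_lt(abs(fit4$a - 12) / 12, 0.1)
  expect_lt(abs(fit4$b - 8) / 8, 0.25)
})

test_that("population effort pairs records with links", {
  rw <- random_small_world(2)
  res <- suppressMessages(derive_links(
    rw$records, rw$world$countries, rw$species$ranges, planar_config()))
  eff <- population_effort(rw$records, res$links)
  expect_true(all(eff$n_links >= 1))
  # every retained population appears exactly once
  flt <- suppressMessages(filter_populations(rw$records, 3))
  expect_identical(
    nrow(eff),
    nrow(unique(flt$retained[c("species_id", "breeding_country")])))
  # links per population never exceed total nonbreeding countries linked
  expect_true(all(eff$n_records >= 3))
})
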