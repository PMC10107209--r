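# Shared fixtures and independent oracles. All toy worlds use planar
# coordinates (config equal_area_crs = "planar") so expected values are
# closed-form.

rect_ring <- function(x0, y0, w, h) {
  list(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
}

rect_geom <- function(x0, y0, w, h) list(rect_ring(x0, y0, w, h))

planar_config <- function(...) {
  analysis_config(equal_area_crs = "planar", ...)
}

# A 1-row-per-country layer from a named list of geometries.
make_layer <- function(geoms, continents, subregions) {
  tibble::tibble(
    code = names(geoms),
    name = names(geoms),
    continent = continents,
    subregion = subregions,
    geometry = unname(geoms))
}

# Toy flyway: one European strip country, a row of unit-square African
# countries A..; nonbreeding range covers `range_cols` of them.
strip_world <- function(n_afr = 3, range_cols = seq_len(n_afr)) {
  geoms <- c(list(EUR = rect_geom(0, 10, n_afr, 1)),
             stats::setNames(
               lapply(seq_len(n_afr) - 1, function(i) rect_geom(i, 0, 1, 1)),
               sprintf("A%02d", seq_len(n_afr))))
  layer <- make_layer(
    geoms,
    continents = c("Europe", rep("Africa", n_afr)),
    subregions = c("western Europe", rep("western Africa", n_afr)))
  range_geom <- geom_union_all(
    lapply(range_cols - 1, function(i) rect_geom(i, 0, 1, 1)))
  ranges <- tibble::tibble(species_id = "SP001", season = "nonbreeding",
                           geometry = list(range_geom))
  list(countries = layer, ranges = ranges)
}

make_records <- function(species, breeding, nonbreeding, group = "landbird",
                         study = "ST1", year = 2015L) {
  n <- length(nonbreeding)
  tibble::tibble(
    record_id = sprintf("R%04d", seq_len(n)),
    species_id = species, species_group = group,
    breeding_country = breeding, nonbreeding_country = nonbreeding,
    device = "GLS", study_id = study, year_published = year)
}

observed_links_of <- function(counts, species = "SP001", breeding = "EUR",
                              group = "landbird") {
  tibble::tibble(
    species_id = species, species_group = group,
    breeding_country = breeding,
    nonbreeding_country = names(counts),
    status = "observed", record_count = as.numeric(counts),
    strength_pct = NA_real_)
}

# ---- independent oracles ----------------------------------------------------

# Naive O(n^3) convex hull: a directed pair (i, j) is a hull edge when every
# other point lies on or to the left of it. Returns indices of hull vertices.
oracle_hull_indices <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cross <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      if (all(cross <= 1e-12 * max(abs(c(x, y, 1)))^2)) {
        on_hull[i] <- TRUE; on_hull[j] <- TRUE
      }
    }
  }
  which(on_hull)
}

point_seg_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
  sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
}

# Minimum distance between the boundaries of two ring sets, by densely
# sampling one boundary and measuring distance to every edge of the other.
oracle_boundary_distance <- function(g1, g2, n_samples = 60) {
  best <- Inf
  for (r in g1) {
    n <- length(r$x)
    xs <- r$x; ys <- r$y
    xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
    for (e in seq_len(n)) {
      tt <- seq(0, 1, length.out = n_samples)
      px <- xs[e] + tt * (xn[e] - xs[e]); py <- ys[e] + tt * (yn[e] - ys[e])
      for (r2 in g2) {
        m <- length(r2$x)
        x2 <- r2$x; y2 <- r2$y
        x2n <- c(x2[-1], x2[1]); y2n <- c(y2[-1], y2[1])
        for (e2 in seq_len(m)) {
          best <- min(best, min(point_seg_dist(px, py, x2[e2], y2[e2],
                                               x2n[e2], y2n[e2])))
        }
      }
    }
  }
  best
}

# Does `geom` intersect the hull of points (px, py)? Independent of the
# production path: naive hull + clipper overlap area + sampled boundary
# distance for pure touching.
oracle_hull_intersects <- function(px, py, geom, touch_tol = 1e-9) {
  idx <- oracle_hull_indices(px, py)
  hx <- px[idx]; hy <- py[idx]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hull_ring <- list(x = hx[o], y = hy[o])
  if (abs(ring_signed_area(hull_ring)) > 0) {
    if (geom_area(geom_intersection(list(hull_ring), geom)) > 0) return(TRUE)
    return(oracle_boundary_distance(list(hull_ring), geom) < touch_tol)
  }
  # degenerate hull: segment between the two most distant points; a
  # crossing is detected by dense point sampling along the segment, a pure
  # touch by the sampled boundary distance
  d <- as.matrix(stats::dist(cbind(px, py)))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  tt <- seq(0, 1, length.out = 801)
  sx <- px[ij[1]] + tt * (px[ij[2]] - px[ij[1]])
  sy <- py[ij[1]] + tt * (py[ij[2]] - py[ij[1]])
  for (i in seq_along(tt)) {
    if (point_in_geom(c(sx[i], sy[i]), geom)) return(TRUE)
  }
  seg <- list(x = c(px[ij[1]], px[ij[2]], px[ij[1]]),
              y = c(py[ij[1]], py[ij[2]], py[ij[1]]))
  oracle_boundary_distance(list(seg), geom, n_samples = 400) < touch_tol
}

# Monte-Carlo area of a geometry within a bbox (rasterised-area oracle).
oracle_area_grid <- function(g, bbox, n = 300) {
  gx <- seq(bbox[1], bbox[2], length.out = n)
  gy <- seq(bbox[3], bbox[4], length.out = n)
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  hits <- 0L
  pts <- expand.grid(x = gx, y = gy)
  inside <- vapply(seq_len(nrow(pts)), function(i)
    point_in_geom(c(pts$x[i], pts$y[i]), g), logical(1))
  sum(inside) * cell
}

# Small random synthetic world used by property tests; returns the pieces
# needed to exercise the link engine.
random_small_world <- function(seed, n_eur = 5, n_afr = 8) {
  params <- simulation_params(
    n_countries_europe = n_eur, n_countries_africa = n_afr,
    n_landbirds = 2, n_raptors = 1, nonbreeding_lambda = 3,
    hole_prob = 0.3, track_prob = 1)
  world <- generate_world(params, seed)
  spx <- generate_species(world, params, seed)
  truth <- generate_truth(spx, params, seed)
  records <- sample_records(truth, world, params, seed)
  list(params = params, world = world, species = spx, truth = truth,
       records = records)
}
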