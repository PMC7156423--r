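# Shared fixtures: memoized synthetic worlds and independent geometry
# oracles. Everything is built in code; no stored fixtures.

.world_cache <- new.env(parent = emptyenv())

get_world <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- build_world(world_config(seed = seed))
  }
  .world_cache[[key]]
}

# run the full pipeline on generated records; returns list of stages
run_pipeline <- function(world, gen) {
  std <- standardize_records(gen$records, world$registry)
  ded <- dedup_records(std)
  flg <- apply_flags(ded, world$land, world$light, world$provinces,
                     world$ranges)
  list(std = std, ded = ded, flg = flg, prn = prune_records(flg))
}

# tiny hand-built registry: one accepted species, a synonym, a 2-hop
# synonym chain, an uncertain taxon and an infraspecific variety
tiny_registry_df <- function() {
  data.frame(
    aphiaID = c(1L, 2L, 3L, 4L, 5L, 6L),
    scientificName = c("Zostera marina", "Zostera oretavensis",
                       "Zostera antiqua", "Dubia incerta",
                       "Zostera marina var. stenophylla", "Fucus vesiculosus"),
    status = c("accepted", "unaccepted", "unaccepted", "uncertain",
               "accepted", "accepted"),
    acceptedAphiaID = c(1L, 1L, 2L, 4L, 5L, 6L),
    rank = c("species", "species", "species", "species", "variety", "species"),
    kingdom = "Plantae", phylum = "Tracheophyta", class = "Magnoliopsida",
    order = c("Alismatales", "", "", "", "Alismatales", "Fucales"),
    family = c("Zosteraceae", "", "", "", "Zosteraceae", "Fucaceae"),
    genus = c("Zostera", "Zostera", "Zostera", "Dubia", "Zostera", "Fucus"),
    stringsAsFactors = FALSE)
}

# winding-number point-in-polygon oracle (angle summation), independent of
# the ray-casting implementation under test
winding_inside <- function(px, py, ring) {
  vapply(seq_along(px), function(i) {
    dx <- ring[, 1] - px[i]
    dy <- ring[, 2] - py[i]
    ang <- atan2(dy, dx)
    d <- diff(ang)
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# star-shaped simple polygon: radii at sorted angles around a center
random_simple_polygon <- function(n_vertices = 8, cx = 0, cy = 0) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.5, 3)
  ring <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  rbind(ring, ring[1, , drop = FALSE])
}

# dense-sampling shoreline-distance oracle: boundary sampled at 0.001
# degrees, distances via geosphere's haversine on the same sphere radius
oracle_shoreline_km <- function(lon, lat, ps, step = 0.001) {
  best <- Inf
  for (poly in ps$polygons) for (ring in poly$rings) {
    for (i in seq_len(nrow(ring) - 1L)) {
      a <- ring[i, ]; b <- ring[i + 1, ]
      k <- max(1L, ceiling(max(abs(b - a)) / step))
      t <- seq(0, 1, length.out = k + 1L)
      pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
      d <- geosphere::distHaversine(c(lon, lat), pts, r = 6371000) / 1000
      best <- min(best, min(d))
    }
  }
  best
}

# 1x1-degree single-island world on a small grid, handy for flag tests
small_island_world <- function(seed = 5L) {
  build_world(world_config(
    seed = seed, n_islands = 1L, island_size_deg = 1,
    grid = list(xll = 0, yll = 0, cellsize = 0.1, ncols = 60L, nrows = 60L),
    province_grid = c(2L, 2L), n_species = 4L, synonyms_per_species = 1L))
}

# uniform single-value light stack covering [0,10]x[0,10]
uniform_stack <- function(value, nodata = -9999) {
  m <- matrix(value, nrow = 20, ncol = 20)
  light_stack(list(m, m, m), xll = 0, yll = 0, cellsize = 0.5,
              nodata = nodata)
}
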