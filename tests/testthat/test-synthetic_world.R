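test_that("the same seed reproduces the world and record set bit-for-bit", {
  w1 <- build_world(world_config(seed = 21))
  w2 <- build_world(world_config(seed = 21))
  expect_identical(w1$cells, w2$cells)
  expect_identical(w1$registry$table, w2$registry$table)
  expect_identical(w1$ranges$table, w2$ranges$table)
  expect_identical(w1$light$layers, w2$light$layers)
  g1 <- generate_records(w1, 150, seed = 21)
  g2 <- generate_records(w2, 150, seed = 21)
  expect_identical(g1$records$records, g2$records$records)
  expect_identical(g1$truth, g2$truth)
})

test_that("world construction honours the configured counts", {
  w <- build_world(world_config(seed = 22, n_islands = 2,
                                province_grid = c(3L, 3L)))
  expect_length(w$land$polygons, 2)
  expect_length(w$provinces$polygons, 9)
  n_acc <- sum(w$registry$table$status == "accepted")
  # n_species ranged species + the no-range species + one uncertain taxon
  expect_equal(n_acc, 12 + 1)
  expect_equal(sum(w$registry$table$status == "unaccepted"), 12 * 2)
  expect_setequal(names(w$ranges$by_species),
                  w$registry$table$scientificName[
                    w$registry$table$status == "accepted" &
                      w$registry$table$aphiaID < 9000])
})

test_that("provinces tile the domain exactly and ranges are contiguous blocks", {
  w <- get_world(1)
  g <- w$config$grid
  area <- function(r) (r[, 1] |> range() |> diff()) * (r[, 2] |> range() |> diff())
  total <- sum(vapply(w$provinces$polygons,
                      function(p) area(p$rings[[1]]), numeric(1)))
  expect_equal(total, g$ncols * g$cellsize * g$nrows * g$cellsize)
  for (ids in w$ranges$by_species) {
    expect_equal(sort(ids), seq(min(ids), max(ids)))
  }
})

test_that("light layers share geometry, deeper layers are dimmer, land is nodata", {
  w <- get_world(1)
  st <- w$light
  ok <- st$layers[[1]] != st$nodata
  expect_true(all(st$layers[[1]][ok] >= st$layers[[2]][ok]))
  expect_true(all(st$layers[[2]][ok] >= st$layers[[3]][ok]))
  # every cell whose center lies on land carries nodata in all layers
  land_cells <- w$cells[w$cells$land, ]
  expect_gt(nrow(land_cells), 0)
  v <- sample_light_max(land_cells$x, land_cells$y, st)
  expect_true(all(is.na(v)))
  # ocean cells hold the shallowest layer's decay value
  oc <- w$cells[!w$cells$land, ][1:50, ]
  expect_equal(sample_light_max(oc$x, oc$y, st), oc$light_max)
})

test_that("island placement fails loudly when islands cannot fit", {
  expect_error(build_world(world_config(n_islands = 2, island_size_deg = 7)),
               "cannot be placed without overlap")
})

test_that("ground-truth label counts follow the rounding arithmetic", {
  w <- get_world(1)
  gen <- generate_records(w, 1000,
                          error_mix = c(on_land = 0.10, low_light = 0.05,
                                        out_of_range = 0.05, duplicate = 0.10),
                          seed = 31)
  tab <- table(gen$truth$label)
  expect_equal(unname(tab[c("on_land", "low_light", "out_of_range",
                            "duplicate")]), c(100, 50, 50, 100),
               ignore_attr = TRUE)
  expect_equal(unname(tab["clean"]), 700, ignore_attr = TRUE)
  expect_equal(n_records(gen$records), 1000)
  # every duplicate's target exists and precedes it
  dup <- gen$truth[gen$truth$label == "duplicate", ]
  expect_true(all(dup$duplicate_of %in% gen$truth$id))
  expect_true(all(match(dup$duplicate_of, gen$truth$id) <
                    match(dup$id, gen$truth$id)))
})

test_that("n = 0 yields empty records and truth", {
  gen <- generate_records(get_world(1), 0, seed = 1)
  expect_equal(n_records(gen$records), 0)
  expect_equal(nrow(gen$truth), 0)
})

test_that("infeasible placements fail with a diagnostic", {
  w0 <- build_world(world_config(seed = 23, n_islands = 0L))
  expect_error(generate_records(w0, 10, error_mix = c(on_land = 1), seed = 1),
               "on_land")
  expect_error(generate_records(get_world(1), 10,
                                error_mix = c(on_land = 0.6, low_light = 0.6)),
               "sum to <= 1")
})

test_that("a world round-trips through its interchange files", {
  w <- small_island_world()
  d <- withr::local_tempdir()
  write_world(w, d)
  expect_equal(read_polygons_geojson(file.path(d, "land.geojson"))$polygons[[1]]$rings,
               w$land$polygons[[1]]$rings)
  prov <- read_polygons_geojson(file.path(d, "provinces.geojson"))
  expect_equal(vapply(prov$polygons, `[[`, integer(1), "id"), 1:4)
  st <- read_light_stack(file.path(d, sprintf("light_depth%d.asc", 1:3)))
  expect_equal(st$layers, w$light$layers, tolerance = 1e-8)
  reg <- load_registry(file.path(d, "registry.csv"))
  expect_identical(reg$table$aphiaID, w$registry$table$aphiaID)
  rng <- read_known_ranges(file.path(d, "ranges.csv"))
  expect_equal(rng$by_species, w$ranges$by_species)
  gz <- read_gazetteer(file.path(d, "gazetteer.csv"))
  expect_equal(gz$entries, w$gazetteer$entries)
})

test_that("synonym aggregation recovers the species actually drawn", {
  w <- get_world(1)
  gen <- generate_records(w, 400, error_mix = c(synonym_used = 0.5), seed = 33)
  std <- standardize_records(gen$records, w$registry)
  expect_equal(n_records(std), 400)
  drawn <- length(unique(std$records$acceptedAphiaID))
  # names used include synonyms, yet accepted species count what was drawn
  expect_gt(length(unique(gen$records$records$name)), drawn)
  expect_lte(drawn, w$config$n_species)
})
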