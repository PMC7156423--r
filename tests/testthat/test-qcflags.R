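# fixtures: a 2x2-degree island at the origin, uniform light stacks and a
# 3-tile province strip
island <- function() polygon_set(list(rect_ring(0, 0, 2, 2)))
strip <- function() polygon_set(lapply(1:3, function(i) {
  list(rings = list(rect_ring(i - 1, 0, i, 1)), id = i)
}))
mkrs <- function(lon, lat, species = "Laminaria digitata") {
  n <- length(lon)
  record_set(data.frame(id = paste0("r", seq_len(n)), name = species,
                        acceptedName = species,
                        decimalLongitude = lon, decimalLatitude = lat,
                        stringsAsFactors = FALSE))
}

test_that("on-land flag requires being inside land and beyond the shoreline tolerance", {
  land <- island()
  # open ocean; deep inland (~111 km); inland but ~0.56 km from shore
  rs <- mkrs(c(5, 1, 0.005, NA), c(5, 1, 1, NA))
  f <- flag_on_land(rs, land)
  expect_equal(f, c("clear", "flagged", "clear", "unevaluated"))
})

test_that("tightening the shoreline tolerance only grows the on-land flagged set", {
  land <- island()
  set.seed(13)
  rs <- mkrs(stats::runif(60, -0.5, 2.5), stats::runif(60, -0.5, 2.5))
  thresholds <- c(5, 1, 0.2, 0.05)
  sets <- lapply(thresholds, function(th) {
    which(flag_on_land(rs, land, qc_config(shoreline_threshold_km = th)) == "flagged")
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("light flag is strict at the 50 threshold", {
  rs <- mkrs(c(5, 5), c(5, 5))
  expect_equal(flag_unsuitable_light(rs, uniform_stack(49.9)),
               c("flagged", "flagged"))
  expect_equal(flag_unsuitable_light(rs, uniform_stack(50.0)),
               c("clear", "clear"))
})

test_that("holopelagic Sargassum species are never light-flagged", {
  rs <- mkrs(5, 5, species = "Sargassum natans")
  expect_equal(flag_unsuitable_light(rs, uniform_stack(0)), "clear")
  # the exemption is configurable: without it the same record is flagged
  cfg <- qc_config(exempt_species = character())
  expect_equal(flag_unsuitable_light(rs, uniform_stack(0), cfg), "flagged")
})

test_that("light flag is unevaluated where the stack has no data", {
  rs <- mkrs(c(5, 50), c(5, 5))  # second point outside the grid
  st <- uniform_stack(-9999)
  expect_equal(flag_unsuitable_light(rs, st), c("unevaluated", "unevaluated"))
})

test_that("with an empty exemption set a uniform sub-threshold raster flags every evaluable record", {
  set.seed(14)
  rs <- mkrs(stats::runif(30, 0, 10), stats::runif(30, 0, 10))
  cfg <- qc_config(exempt_species = character())
  expect_true(all(flag_unsuitable_light(rs, uniform_stack(49.999), cfg) == "flagged"))
  expect_true(all(flag_unsuitable_light(rs, uniform_stack(50), cfg) == "clear"))
})

test_that("distribution flag compares the containing province with the known range", {
  ranges <- known_ranges(c("Laminaria digitata", "Laminaria digitata",
                           "Zostera marina"),
                         c(1L, 3L, 2L))
  rs <- mkrs(c(1.5, 0.5, 0.5, 9, NA), c(0.5, 0.5, 0.5, 9, NA))
  rs$records$acceptedName[3] <- rs$records$name[3] <- "Fucus ignotus"
  f <- flag_outside_distribution(rs, strip(), ranges)
  expect_equal(f, c("flagged",      # province 2, range {1,3}
                    "clear",        # province 1
                    "remove",       # species absent from the table
                    "unevaluated",  # outside all provinces
                    "unevaluated")) # no coordinates
})

test_that("a species documented with an empty range set is flagged, not removed", {
  ranges <- known_ranges("Laminaria digitata", NA_integer_)
  rs <- mkrs(0.5, 0.5)
  expect_equal(flag_outside_distribution(rs, strip(), ranges), "flagged")
})

test_that("apply_flags evaluates the three flags independently and removes unverifiable species", {
  land <- island()
  provinces <- strip()
  ranges <- known_ranges("Laminaria digitata", 1:3)
  rs <- mkrs(c(1, 2.5, 0.5), c(0.5, 0.5, 0.5))
  rs$records$acceptedName[3] <- rs$records$name[3] <- "Fucus ignotus"
  out <- apply_flags(rs, land, uniform_stack(10), provinces, ranges)
  expect_equal(n_records(out), 2)  # unverifiable species removed
  r1 <- out$records[1, ]
  expect_equal(r1$flagMachineOnLand, "flagged")            # deep inside land
  expect_equal(r1$flagMachineSuitableLightBottom, "flagged")
  expect_equal(r1$flagHumanCuratedDistribution, "clear")
  # union semantics: both survivors carry >= 1 flag, prune removes each once
  expect_equal(n_records(prune_records(out)), 0)
})

test_that("each flag depends only on its own inputs", {
  land <- island()
  rs <- mkrs(c(1, 5), c(1, 5))
  light_before <- flag_unsuitable_light(rs, uniform_stack(60))
  # moving the landmass cannot change the light flag
  other_land <- polygon_set(list(rect_ring(40, 40, 42, 42)))
  expect_equal(flag_on_land(rs, other_land), c("clear", "clear"))
  expect_equal(flag_unsuitable_light(rs, uniform_stack(60)), light_before)
})

test_that("flag evaluation is deterministic", {
  w <- get_world(15)
  gen <- generate_records(w, 200, seed = 15)
  std <- standardize_records(gen$records, w$registry)
  a <- apply_flags(std, w$land, w$light, w$provinces, w$ranges)
  b <- apply_flags(std, w$land, w$light, w$provinces, w$ranges)
  expect_identical(a$records, b$records)
})

test_that("qc_config validates thresholds and reads key-value files", {
  expect_error(qc_config(shoreline_threshold_km = 0), "> 0")
  expect_error(qc_config(light_threshold = -3), "> 0")
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("# thresholds", "shoreline_threshold_km: 2.5",
               "light_threshold: 40",
               "exempt_species: Sargassum natans, Sargassum fluitans"), f)
  cfg <- read_qc_config(f)
  expect_equal(cfg$shoreline_threshold_km, 2.5)
  expect_equal(cfg$light_threshold, 40)
  expect_equal(cfg$exempt_species, c("Sargassum natans", "Sargassum fluitans"))
  writeLines("nonsense_key: 1", f)
  expect_error(read_qc_config(f), "unknown qc_config key")
})
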