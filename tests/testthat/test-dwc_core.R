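test_that("reading keeps well-formed rows and drops invariant violations with counts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,name,decimalLongitude,decimalLatitude,year,month,day",
    "r1,Zostera marina,-8.8,37.0,2001,5,12",
    "r2,Fucus vesiculosus,0.5,91.0,2002,6,1",    # latitude out of range
    "r3,Zostera marina,181.0,10.0,2003,1,1",     # longitude out of range
    "r4,Zostera marina,1.0,1.0,,5,12",           # month without year
    "r5,Zostera marina,1.0,1.0,2004,13,1",       # month out of range
    "r6,Fucus vesiculosus,2.0,2.0,2005,2,28"), f)
  rs <- read_records(f)
  expect_equal(n_records(rs), 2)
  expect_setequal(rs$records$id, c("r1", "r6"))
  expect_match(rs$provenance[1], "read: 2 kept, 4 dropped", fixed = TRUE)
})

test_that("flag columns decode -1/empty/absent as flagged/clear/unevaluated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,name,decimalLongitude,decimalLatitude,flagMachineOnLand,flagMachineSuitableLightBottom",
    "r1,Zostera marina,1,1,-1,",
    paste0("r2,Zostera marina,1,2,,", "−1")), f)  # unicode minus accepted
  rs <- read_records(f)
  expect_equal(rs$records$flagMachineOnLand, c("flagged", "clear"))
  expect_equal(rs$records$flagMachineSuitableLightBottom, c("clear", "flagged"))
  expect_equal(rs$records$flagHumanCuratedDistribution,
               c("unevaluated", "unevaluated"))
})

test_that("schema and file errors are fatal", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,decimalLongitude", "r1,1.0"), f)
  expect_error(read_records(f), "schema error")
  expect_error(read_records(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("write/read round-trip is the identity on evaluated record sets", {
  w <- get_world(11)
  gen <- generate_records(w, 300, seed = 11)
  flg <- run_pipeline(w, gen)$flg
  # the -1/empty file encoding carries two states; restrict to records
  # whose flags are all evaluated so equality is exact field-by-field
  evaluated <- !apply(flg$records[FLAG_COLUMNS] == "unevaluated", 1, any)
  rs <- record_set(flg$records[evaluated, , drop = FALSE])
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(rs, f)
  back <- read_records(f)
  expect_equal(back$records, rs$records)
})

test_that("flagged records serialize as -1 and pruned output drops them", {
  df <- data.frame(id = paste0("r", 1:5), name = "Zostera marina",
                   decimalLongitude = 1:5, decimalLatitude = 1:5,
                   flagMachineOnLand = c("clear", "flagged", "clear", "clear", "clear"),
                   flagMachineSuitableLightBottom = "clear",
                   flagHumanCuratedDistribution = c("clear", "flagged", "clear", "flagged", "clear"),
                   stringsAsFactors = FALSE)
  rs <- record_set(df)
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(rs, f)
  raw <- utils::read.csv(f, colClasses = "character")
  expect_equal(raw$flagMachineOnLand, c("", "-1", "", "", ""))
  fp <- withr::local_tempfile(fileext = ".csv")
  write_records(rs, fp, pruned = TRUE)
  expect_equal(n_records(read_records(fp)), 3)
})

test_that("geocoding fills coordinates from the gazetteer and removes unmatched", {
  gaz <- gazetteer(c("Faro, Portugal", "Olhao"), c(-7.93, -7.84),
                   c(37.01, 37.02), c(500, 800))
  df <- data.frame(id = c("a", "b", "c", "d"),
                   name = "Zostera marina",
                   decimalLongitude = c(5, NA, NA, NA),
                   decimalLatitude = c(5, NA, NA, NA),
                   locality = c("ignored", "  faro,   portugal ", "nowhere", NA),
                   stringsAsFactors = FALSE)
  rs <- geocode_records(record_set(df), gaz)
  expect_equal(rs$records$id, c("a", "b"))
  expect_equal(rs$records$decimalLongitude, c(5, -7.93))
  expect_equal(rs$records$coordinateUncertaintyInMeters[2], 500)
  expect_match(rs$records$recordNotes[2], "geocoded")
  expect_match(rs$provenance[1], "1 filled from gazetteer, 2 removed")
})

test_that("duplicates share taxon, exact position, depth and date; first survives", {
  base <- data.frame(id = "x", name = "n", acceptedAphiaID = 7L,
                     decimalLongitude = 1.25, decimalLatitude = 2.5,
                     verbatimDepth = 3.0, year = 2000L, month = 6L, day = 15L,
                     stringsAsFactors = FALSE)
  mk <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(seq_along(rows), function(i) {
      r <- base; r$id <- paste0("r", i)
      for (nm in names(rows[[i]])) r[[nm]] <- rows[[i]][[nm]]
      r
    }))
  }
  # exact copy collapses; differing day survives; missing == missing
  rs <- record_set(mk(list(), list(), list(day = 16L),
                      list(day = NA_integer_), list(day = NA_integer_)))
  out <- dedup_records(rs)
  expect_equal(out$records$id, c("r1", "r3", "r4"))
  expect_match(out$provenance[1], "2 duplicates removed")
})

test_that("depth key prefers verbatimDepth and falls back to the min/max pair", {
  df <- data.frame(id = c("a", "b", "c", "d"), name = "n",
                   acceptedAphiaID = 1L,
                   decimalLongitude = 1, decimalLatitude = 1,
                   verbatimDepth = c(NA, NA, 5, 5),
                   minimumDepthInMeters = c(2, 2, 9, 9),
                   maximumDepthInMeters = c(4, 4, 9, 1),
                   year = 2000L, month = 1L, day = 1L,
                   stringsAsFactors = FALSE)
  out <- dedup_records(record_set(df))
  # a/b duplicate on the min/max pair; c/d duplicate on verbatimDepth
  expect_equal(out$records$id, c("a", "c"))
})

test_that("dedup is idempotent, order-stable and never grows the set", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    df <- data.frame(id = paste0("r", 1:n), name = "n",
                     acceptedAphiaID = sample(1:3, n, TRUE),
                     decimalLongitude = sample(c(1, 2), n, TRUE),
                     decimalLatitude = sample(c(1, 2), n, TRUE),
                     verbatimDepth = sample(c(NA, 5), n, TRUE),
                     year = 2000L, month = 1L,
                     day = sample(c(NA, 1L, 2L), n, TRUE),
                     stringsAsFactors = FALSE)
    once <- dedup_records(record_set(df))
    twice <- dedup_records(once)
    expect_identical(twice$records, once$records)
    expect_lte(n_records(once), n)
    expect_true(all(once$records$id %in% df$id))
  }
})

test_that("prune retains exactly the unflagged records (union semantics)", {
  df <- data.frame(id = paste0("r", 1:5), name = "n",
                   flagMachineOnLand = c("clear", "flagged", "clear", "clear", "clear"),
                   flagMachineSuitableLightBottom = c("clear", "flagged", "clear", "flagged", "clear"),
                   flagHumanCuratedDistribution = "clear",
                   stringsAsFactors = FALSE)
  out <- prune_records(record_set(df))
  expect_equal(out$records$id, c("r1", "r3", "r5"))  # r2 doubly flagged, once
  clean <- record_set(transform(df, flagMachineOnLand = "clear",
                                flagMachineSuitableLightBottom = "clear"))
  expect_equal(prune_records(clean)$records$id, df$id)
})

test_that("pruning a never-flagged set is a pipeline error", {
  df <- data.frame(id = "r1", name = "n", stringsAsFactors = FALSE)
  expect_error(prune_records(record_set(df)), "apply_flags")
})

test_that("provenance counts across a pipeline run sum to input minus output", {
  w <- get_world(12)
  gen <- generate_records(w, 400, seed = 12)
  st <- run_pipeline(w, gen)
  hits <- unlist(regmatches(
    st$prn$provenance,
    gregexpr("[0-9]+(?= (duplicates |flagged records |duplicate )?removed)",
             st$prn$provenance, perl = TRUE)))
  removed <- sum(as.numeric(hits))
  expect_equal(n_records(gen$records) - removed, n_records(st$prn))
})
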