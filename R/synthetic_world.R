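# Deterministic synthetic world: rectangular islands in a rectangular ocean
# domain, a 3-layer benthic light stack decaying with distance from shore,
# a rectangular province tiling, a taxon registry with synonyms, a known-
# range table, and a gazetteer — plus a record generator that plants
# records with labelled error types at a guard margin from every decision
# boundary, so pipeline recovery of the labels is exact by construction.

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Synthetic world configuration
#'
#' Parameters of the synthetic ocean domain. Defaults give a 12 x 12 degree
#' equatorial domain on a 0.1-degree grid with two 2-degree islands, a
#' surface light maximum of 170 E·m^-2·yr^-1 decaying 8% per cell of
#' distance from shore (so the 50-unit photosynthesis limit falls ~1.5
#' degrees offshore), a 3 x 3 province tiling, and 12 species with 2
#' registered synonyms each.
#'
#' @param seed integer seed governing every random choice.
#' @param n_islands number of rectangular islands.
#' @param island_size_deg island side length, degrees.
#' @param grid list: `xll`, `yll`, `cellsize` (degrees), `ncols`, `nrows`.
#' @param light_surface_max light at the shoreline, shallowest layer.
#' @param light_decay_per_cell fractional light loss per cell of shore
#'   distance in the shallowest layer; deeper layers decay 1.5x and 2x
#'   faster.
#' @param province_grid integer c(rows, cols) tiling of the domain.
#' @param n_species number of accepted species with documented ranges.
#' @param synonyms_per_species registered synonyms per accepted species.
#' @return A `world_config` object.
#' @export
world_config <- function(seed = 1L, n_islands = 2L, island_size_deg = 2,
                         grid = list(xll = 0, yll = 0, cellsize = 0.1,
                                     ncols = 120L, nrows = 120L),
                         light_surface_max = 170,
                         light_decay_per_cell = 0.08,
                         province_grid = c(3L, 3L),
                         n_species = 12L, synonyms_per_species = 2L) {
  stopifnot(n_islands >= 0, island_size_deg > 0, n_species >= 1,
            synonyms_per_species >= 0, light_surface_max > 0,
            light_decay_per_cell > 0, light_decay_per_cell < 0.5)
  structure(list(seed = as.integer(seed), n_islands = as.integer(n_islands),
                 island_size_deg = island_size_deg, grid = grid,
                 light_surface_max = light_surface_max,
                 light_decay_per_cell = light_decay_per_cell,
                 province_grid = as.integer(province_grid),
                 n_species = as.integer(n_species),
                 synonyms_per_species = as.integer(synonyms_per_species)),
            class = "world_config")
}

rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
}

# distance (degrees, planar) from points to a rectangle's boundary-or-interior
rect_dist_deg <- function(x, y, r) {
  dx <- pmax(r[1] - x, x - r[3], 0)
  dy <- pmax(r[2] - y, y - r[4], 0)
  sqrt(dx^2 + dy^2)
}

# synthetic species pools; names are fabricated epithets on real genera
KELP_GENERA <- data.frame(
  genus = c("Laminaria", "Saccharina", "Fucus", "Himanthalia"),
  family = c("Laminariaceae", "Laminariaceae", "Fucaceae", "Himanthaliaceae"),
  order = c("Laminariales", "Laminariales", "Fucales", "Fucales"),
  stringsAsFactors = FALSE)
SEAGRASS_GENERA <- data.frame(
  genus = c("Zostera", "Posidonia", "Cymodocea", "Halophila"),
  family = c("Zosteraceae", "Posidoniaceae", "Cymodoceaceae", "Hydrocharitaceae"),
  order = c("Alismatales", "Alismatales", "Alismatales", "Alismatales"),
  stringsAsFactors = FALSE)

synthetic_registry <- function(cfg) {
  n <- cfg$n_species
  rows <- list()
  for (i in seq_len(n)) {
    kelp <- i <= ceiling(n / 2)
    pool <- if (kelp) KELP_GENERA else SEAGRASS_GENERA
    g <- pool[((i - 1) %% nrow(pool)) + 1, ]
    sp_name <- sprintf("%s simulata%02d", g$genus, i)
    rows[[length(rows) + 1]] <- data.frame(
      aphiaID = 1000L + i, scientificName = sp_name, status = "accepted",
      acceptedAphiaID = 1000L + i, rank = "species",
      kingdom = if (kelp) "Chromista" else "Plantae",
      phylum = if (kelp) "Ochrophyta" else "Tracheophyta",
      class = if (kelp) "Phaeophyceae" else "Magnoliopsida",
      order = g$order, family = g$family, genus = g$genus,
      stringsAsFactors = FALSE)
    for (j in seq_len(cfg$synonyms_per_species)) {
      rows[[length(rows) + 1]] <- data.frame(
        aphiaID = 5000L + (i - 1L) * cfg$synonyms_per_species + j,
        scientificName = sprintf("%s prior%02d%s", g$genus, i, letters[j]),
        status = "unaccepted", acceptedAphiaID = 1000L + i, rank = "species",
        kingdom = "", phylum = "", class = "", order = "", family = "",
        genus = g$genus, stringsAsFactors = FALSE)
    }
  }
  # a documented-nowhere species (absent from the range table) and an
  # uncertain taxon, for the removal paths
  rows[[length(rows) + 1]] <- data.frame(
    aphiaID = 9000L, scientificName = "Fucus ignotus", status = "accepted",
    acceptedAphiaID = 9000L, rank = "species", kingdom = "Chromista",
    phylum = "Ochrophyta", class = "Phaeophyceae", order = "Fucales",
    family = "Fucaceae", genus = "Fucus", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    aphiaID = 9001L, scientificName = "Dubia incerta", status = "uncertain",
    acceptedAphiaID = 9001L, rank = "species", kingdom = "", phylum = "",
    class = "", order = "", family = "", genus = "Dubia",
    stringsAsFactors = FALSE)
  taxon_registry(do.call(rbind, rows))
}

#' Build a synthetic world
#'
#' Constructs, deterministically from the seed, every geospatial and
#' taxonomic input the QC pipeline needs: non-overlapping rectangular
#' islands (land polygons), a 3-layer light stack whose deeper layers decay
#' faster with distance from shore (cells whose center is on land carry
#' nodata — benthic light is undefined on land), provinces tiling the
#' domain exactly, a registry of `n_species` accepted species plus
#' synonyms, a range table assigning each species a contiguous block of
#' provinces, and a small gazetteer of ocean localities.
#'
#' @param cfg a [world_config()].
#' @return An object of class `mf_world`: list with `land`, `light`,
#'   `provinces`, `registry`, `ranges`, `gazetteer`, `config`, and `cells`
#'   (per-cell ground-truth table used by [generate_records()]).
#' @export
build_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  g <- cfg$grid
  W <- g$ncols * g$cellsize; H <- g$nrows * g$cellsize
  xmax <- g$xll + W; ymax <- g$yll + H

  # island slots on a k x k lattice, diagonal-first so light reaches
  # provinces across the domain
  islands <- list()
  if (cfg$n_islands > 0) {
    k <- ceiling(sqrt(cfg$n_islands))
    sx <- W / k; sy <- H / k
    if (cfg$island_size_deg >= min(sx, sy)) {
      stop("islands cannot be placed without overlap: island_size_deg ",
           cfg$island_size_deg, " exceeds slot spacing ", min(sx, sy))
    }
    slots <- expand.grid(i = seq_len(k), j = seq_len(k))
    slots <- slots[order(abs(slots$i - slots$j), slots$i + slots$j), ]
    half <- cfg$island_size_deg / 2
    for (m in seq_len(cfg$n_islands)) {
      cx <- g$xll + (slots$i[m] - 0.5) * sx
      cy <- g$yll + (slots$j[m] - 0.5) * sy
      islands[[m]] <- c(cx - half, cy - half, cx + half, cy + half)
    }
  }
  land <- polygon_set(lapply(seq_along(islands), function(m) {
    r <- islands[[m]]
    list(rings = list(rect_ring(r[1], r[2], r[3], r[4])),
         id = m, name = sprintf("island %d", m))
  }))

  # province tiling, ids row-major from the south-west corner
  prows <- cfg$province_grid[1]; pcols <- cfg$province_grid[2]
  pw <- W / pcols; ph <- H / prows
  prov_polys <- list()
  for (pr in seq_len(prows)) for (pc in seq_len(pcols)) {
    id <- (pr - 1L) * pcols + pc
    prov_polys[[id]] <- list(
      rings = list(rect_ring(g$xll + (pc - 1) * pw, g$yll + (pr - 1) * ph,
                             g$xll + pc * pw, g$yll + pr * ph)),
      id = id, name = sprintf("province %d", id))
  }
  provinces <- polygon_set(prov_polys)

  # per-cell ground truth (centers), computed by rectangle arithmetic only
  cx <- g$xll + (seq_len(g$ncols) - 0.5) * g$cellsize
  cy <- g$yll + (seq_len(g$nrows) - 0.5) * g$cellsize
  cells <- expand.grid(x = cx, y = cy)
  if (length(islands)) {
    dmat <- sapply(islands, function(r) rect_dist_deg(cells$x, cells$y, r))
    dmat <- matrix(dmat, nrow = nrow(cells))
    cells$shore_deg <- apply(dmat, 1, min)
    inside <- rep(FALSE, nrow(cells))
    for (r in islands) {
      inside <- inside | (cells$x >= r[1] & cells$x <= r[3] &
                            cells$y >= r[2] & cells$y <= r[4])
    }
    cells$land <- inside
    cells$land_dist_deg <- cells$shore_deg
  } else {
    # no islands: a uniformly shallow, fully lit sea (no decay reference)
    cells$shore_deg <- 0
    cells$land <- FALSE
    cells$land_dist_deg <- Inf
  }
  cells$province <- (pmin(floor((cells$y - g$yll) / ph), prows - 1)) * pcols +
    pmin(floor((cells$x - g$xll) / pw), pcols - 1) + 1L

  # light: layer k decays (1, 1.5, 2) x the base rate per cell of shore
  # distance; land cells are nodata in all layers
  d_cells <- cells$shore_deg / g$cellsize
  nodata <- -9999
  layers <- lapply(c(1, 1.5, 2), function(f) {
    v <- cfg$light_surface_max * (1 - f * cfg$light_decay_per_cell)^d_cells
    v[cells$land] <- nodata
    # expand.grid varies x fastest: v[(row_from_south-1)*ncols + col];
    # matrix row 1 must be the northernmost row
    m <- matrix(v, nrow = g$nrows, ncol = g$ncols, byrow = TRUE)
    m[rev(seq_len(g$nrows)), , drop = FALSE]
  })
  light <- light_stack(layers, g$xll, g$yll, g$cellsize, nodata)
  cells$light_max <- ifelse(cells$land, NA_real_,
                            cfg$light_surface_max *
                              (1 - cfg$light_decay_per_cell)^d_cells)

  registry <- synthetic_registry(cfg)

  # guard margins (degrees): placements stay this far from the light and
  # province decision boundaries so pipeline recovery is exact
  margin <- list(shore = max(0.15, 1.5 * g$cellsize),
                 province = g$cellsize / 2 + 0.31 * g$cellsize,
                 light_hi = 55, light_lo = 45)
  pb_x <- pmin((cells$x - g$xll) %% pw, pw - (cells$x - g$xll) %% pw)
  pb_y <- pmin((cells$y - g$yll) %% ph, ph - (cells$y - g$yll) %% ph)
  edge <- pmin(cells$x - g$xll, xmax - cells$x, cells$y - g$yll, ymax - cells$y)
  cells$placeable <- !cells$land & cells$land_dist_deg >= margin$shore &
    pmin(pb_x, pb_y) >= margin$province & edge >= g$cellsize

  good_prov <- sort(unique(cells$province[cells$placeable &
                                            cells$light_max >= margin$light_hi]))
  if (!length(good_prov)) {
    stop("no province contains well-lit placeable ocean cells; ",
         "enlarge the domain or soften light_decay_per_cell")
  }

  ranges <- with_seed(cfg$seed, {
    P <- prows * pcols
    L <- min(3L, P)
    starts_ok <- Filter(function(s) {
      block <- s:(s + L - 1L)
      length(intersect(block, good_prov)) > 0 &&
        length(setdiff(good_prov, block)) > 0
    }, seq_len(P - L + 1L))
    if (!length(starts_ok)) stop("cannot assign species ranges: no contiguous ",
                                 "province block is compatible with the light field")
    sp <- registry$table
    sp <- sp$scientificName[sp$status == "accepted" & sp$aphiaID < 9000L]
    blocks <- lapply(sp, function(s) {
      st <- starts_ok[[sample.int(length(starts_ok), 1)]]
      st:(st + L - 1L)
    })
    # coastal guarantee: every province holding an island interior is
    # inside at least one species' range, so on-land error placements are
    # always feasible (species do occur near their coasts)
    island_provs <- vapply(islands, function(r) {
      cx <- (r[1] + r[3]) / 2; cy <- (r[2] + r[4]) / 2
      as.integer(floor((cy - g$yll) / ph) * pcols +
                   floor((cx - g$xll) / pw) + 1)
    }, integer(1))
    for (m in seq_along(island_provs)) {
      p <- island_provs[m]
      if (any(vapply(blocks, function(b) p %in% b, logical(1)))) next
      covering <- seq(max(1L, p - L + 1L), min(p, P - L + 1L))
      pref <- intersect(covering, starts_ok)
      st <- if (length(pref)) pref[sample.int(length(pref), 1)]
            else covering[sample.int(length(covering), 1)]
      blocks[[((m - 1L) %% length(blocks)) + 1L]] <- st:(st + L - 1L)
    }
    known_ranges(rep(sp, lengths(blocks)), unlist(blocks),
                 citation = "synthetic range assignment")
  })

  gaz <- with_seed(cfg$seed + 1L, {
    pool <- which(cells$placeable & !is.na(cells$light_max) &
                    cells$light_max >= margin$light_hi)
    pick <- pool[sample.int(length(pool), min(5L, length(pool)))]
    gazetteer(sprintf("port %02d", seq_along(pick)),
              cells$x[pick], cells$y[pick],
              rep(500, length(pick)))
  })

  structure(list(land = land, light = light, provinces = provinces,
                 registry = registry, ranges = ranges, gazetteer = gaz,
                 config = cfg, islands = islands, cells = cells,
                 margin = margin),
            class = "mf_world")
}

#' @export
print.mf_world <- function(x, ...) {
  g <- x$config$grid
  cat(sprintf("<mf_world: %d islands, %dx%d grid, %d provinces, %d taxa>\n",
              length(x$islands), g$nrows, g$ncols,
              length(x$provinces$polygons), nrow(x$registry$table)))
  invisible(x)
}

#' Generate occurrence records with labelled error types
#'
#' Plants `n` records in a synthetic world with ground-truth labels:
#' `clean` (ocean, suitable light, inside the species' range), `on_land`
#' (well inside an island), `low_light` (ocean cells whose 3-layer light
#' maximum is below the threshold), `out_of_range` (well-lit ocean in a
#' province outside the species' range), `duplicate` (exact copy of an
#' earlier record, new id), `synonym_used` (clean placement recorded under
#' a registered synonym) and `no_range_info` (species absent from the range
#' table). Label counts are `round(n * proportion)` with the remainder
#' going to `clean`. Every placement keeps a guard margin from the light,
#' shoreline and province decision boundaries, so running
#' standardize/dedup/flag on the output recovers the labels exactly.
#'
#' @param world an `mf_world` from [build_world()].
#' @param n number of records.
#' @param error_mix named numeric proportions for labels `on_land`,
#'   `low_light`, `out_of_range`, `duplicate`, `synonym_used`,
#'   `no_range_info` (subset allowed; must sum to <= 1).
#' @param seed integer seed.
#' @return List with `records` (a [record_set()]) and `truth` (data frame
#'   `id`, `label`, `duplicate_of`).
#' @export
generate_records <- function(world, n,
                             error_mix = c(on_land = 0.10, low_light = 0.05,
                                           out_of_range = 0.05,
                                           duplicate = 0.10,
                                           synonym_used = 0.05,
                                           no_range_info = 0.02),
                             seed = world$config$seed) {
  stopifnot(inherits(world, "mf_world"), n >= 0)
  labels_all <- c("on_land", "low_light", "out_of_range", "duplicate",
                  "synonym_used", "no_range_info")
  if (!all(names(error_mix) %in% labels_all)) {
    stop("unknown error_mix labels: ",
         paste(setdiff(names(error_mix), labels_all), collapse = ", "))
  }
  if (sum(error_mix) > 1 + 1e-12) stop("error_mix proportions must sum to <= 1")
  counts <- stats::setNames(integer(length(labels_all)), labels_all)
  counts[names(error_mix)] <- as.integer(round(n * error_mix))
  if (sum(counts) > n) stop("rounded label counts exceed n")
  n_clean <- n - sum(counts)
  if (counts["duplicate"] > 0 && n_clean + sum(counts) - counts["duplicate"] == 0) {
    stop("duplicates need at least one earlier record to copy")
  }
  if (n == 0) {
    return(list(records = record_set(), truth = data.frame(
      id = character(), label = character(), duplicate_of = character(),
      stringsAsFactors = FALSE)))
  }

  cfg <- world$config
  cells <- world$cells
  mg <- world$margin
  reg_t <- world$registry$table
  sp_reg <- reg_t[reg_t$status == "accepted" & reg_t$aphiaID < 9000L, ]
  ranged <- sp_reg$scientificName
  range_of <- world$ranges$by_species

  pool_good <- which(cells$placeable & cells$light_max >= mg$light_hi)
  pool_low <- which(cells$placeable & cells$light_max < mg$light_lo)
  prov_good <- split(pool_good, cells$province[pool_good])
  prov_low <- split(pool_low, cells$province[pool_low])

  with_seed(seed, {
    jitter <- function(k) stats::runif(k, -0.3, 0.3) * cfg$grid$cellsize
    synonyms_of <- function(sp_name) {
      aid <- reg_t$aphiaID[match(sp_name, reg_t$scientificName)]
      reg_t$scientificName[reg_t$status == "unaccepted" &
                             reg_t$acceptedAphiaID == aid]
    }
    pick_cell <- function(pmap, provs, label) {
      provs <- provs[as.character(provs) %in% names(pmap)]
      if (!length(provs)) {
        stop("infeasible placement for label '", label,
             "': no candidate cell in provinces of interest")
      }
      p <- provs[sample.int(length(provs), 1)]
      ids <- pmap[[as.character(p)]]
      ids[sample.int(length(ids), 1)]
    }
    new_row <- function(label) {
      if (label == "no_range_info") {
        sp <- "Fucus ignotus"
        cell <- pick_cell(prov_good, as.integer(names(prov_good)), label)
      } else if (label == "low_light") {
        ok <- ranged[vapply(ranged, function(s)
          any(as.character(range_of[[s]]) %in% names(prov_low)), logical(1))]
        if (!length(ok)) stop("infeasible placement for label 'low_light': ",
                              "no species range overlaps a low-light province")
        sp <- ok[sample.int(length(ok), 1)]
        cell <- pick_cell(prov_low, range_of[[sp]], label)
      } else if (label == "out_of_range") {
        ok <- ranged[vapply(ranged, function(s)
          any(!names(prov_good) %in% as.character(range_of[[s]])), logical(1))]
        if (!length(ok)) stop("infeasible placement for label 'out_of_range': ",
                              "every well-lit province is inside every range")
        sp <- ok[sample.int(length(ok), 1)]
        outside <- setdiff(as.integer(names(prov_good)), range_of[[sp]])
        cell <- pick_cell(prov_good, outside, label)
      } else if (label == "on_land") {
        if (!length(world$islands)) {
          stop("infeasible placement for label 'on_land': world has no islands")
        }
        g <- cfg$grid
        pw <- g$ncols * g$cellsize / cfg$province_grid[2]
        ph <- g$nrows * g$cellsize / cfg$province_grid[1]
        prov_at <- function(x, y) {
          floor((y - g$yll) / ph) * cfg$province_grid[2] +
            floor((x - g$xll) / pw) + 1L
        }
        # islands whose interior provinces overlap at least one range
        feasible <- Filter(function(m) {
          r <- world$islands[[m]]
          provs <- unique(c(outer(
            seq(r[1] + mg$shore, r[3] - mg$shore, length.out = 5),
            seq(r[2] + mg$shore, r[4] - mg$shore, length.out = 5),
            Vectorize(prov_at))))
          any(vapply(ranged, function(s) any(provs %in% range_of[[s]]),
                     logical(1)))
        }, seq_along(world$islands))
        if (!length(feasible)) {
          stop("infeasible placement for label 'on_land': no species range ",
               "covers a province containing an island interior")
        }
        for (attempt in 1:2000) {
          r <- world$islands[[feasible[[sample.int(length(feasible), 1)]]]]
          x <- stats::runif(1, r[1] + mg$shore, r[3] - mg$shore)
          y <- stats::runif(1, r[2] + mg$shore, r[4] - mg$shore)
          prov <- prov_at(x, y)
          pb <- min((x - g$xll) %% pw, pw - (x - g$xll) %% pw,
                    (y - g$yll) %% ph, ph - (y - g$yll) %% ph)
          ok <- ranged[vapply(ranged, function(s) prov %in% range_of[[s]],
                              logical(1))]
          if (pb >= mg$province && length(ok)) {
            sp <- ok[sample.int(length(ok), 1)]
            return(list(sp = sp, name = sp, x = x, y = y))
          }
        }
        stop("infeasible placement for label 'on_land': rejection sampling ",
             "found no in-range island point")
      } else {  # clean or synonym_used
        ok <- ranged[vapply(ranged, function(s)
          any(as.character(range_of[[s]]) %in% names(prov_good)), logical(1))]
        sp <- ok[sample.int(length(ok), 1)]
        cell <- pick_cell(prov_good, range_of[[sp]], label)
      }
      nm <- sp
      if (label == "synonym_used") {
        syn <- synonyms_of(sp)
        if (!length(syn)) stop("infeasible 'synonym_used': species ", sp,
                               " has no registered synonyms")
        nm <- syn[sample.int(length(syn), 1)]
      }
      list(sp = sp, name = nm,
           x = cells$x[cell] + jitter(1), y = cells$y[cell] + jitter(1))
    }

    originals <- c(rep("clean", n_clean),
                   rep("on_land", counts["on_land"]),
                   rep("low_light", counts["low_light"]),
                   rep("out_of_range", counts["out_of_range"]),
                   rep("synonym_used", counts["synonym_used"]),
                   rep("no_range_info", counts["no_range_info"]))
    originals <- sample(originals)
    rows <- vector("list", length(originals))
    for (i in seq_along(originals)) rows[[i]] <- new_row(originals[i])

    n_orig <- length(originals)
    df <- data.frame(
      id = sprintf("rec%06d", seq_len(n_orig)),
      name = vapply(rows, `[[`, character(1), "name"),
      decimalLongitude = vapply(rows, `[[`, numeric(1), "x"),
      decimalLatitude = vapply(rows, `[[`, numeric(1), "y"),
      verbatimDepth = round(stats::runif(n_orig, 0, 30), 1),
      year = sample(1950:2018, n_orig, replace = TRUE),
      month = sample(1:12, n_orig, replace = TRUE),
      day = sample(1:28, n_orig, replace = TRUE),
      sourceType = sample(c("literature", "herbaria", "repositories"),
                          n_orig, replace = TRUE),
      bibliographicCitation = "synthetic record generator",
      stringsAsFactors = FALSE)
    truth <- data.frame(id = df$id, label = originals,
                        duplicate_of = NA_character_,
                        stringsAsFactors = FALSE)

    n_dup <- counts["duplicate"]
    if (n_dup > 0) {
      src <- sample.int(n_orig, n_dup, replace = TRUE)
      dup <- df[src, , drop = FALSE]
      dup$id <- sprintf("rec%06d", n_orig + seq_len(n_dup))
      df <- rbind(df, dup)
      truth <- rbind(truth, data.frame(id = dup$id, label = "duplicate",
                                       duplicate_of = df$id[src],
                                       stringsAsFactors = FALSE))
    }
    rownames(df) <- rownames(truth) <- NULL
    list(records = record_set(df, provenance = sprintf(
           "generate: %d records (%d clean, %d on_land, %d low_light, %d out_of_range, %d duplicate, %d synonym_used, %d no_range_info)",
           nrow(df), n_clean, counts["on_land"], counts["low_light"],
           counts["out_of_range"], counts["duplicate"],
           counts["synonym_used"], counts["no_range_info"])),
         truth = truth)
  })
}

#' Write a synthetic world to a directory
#'
#' Serializes every component in its interchange format: `land.geojson`,
#' `provinces.geojson`, `light_depth1..3.asc`, `registry.csv`,
#' `ranges.csv`, `gazetteer.csv`.
#'
#' @param world an `mf_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "mf_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_polygons_geojson(world$land, file.path(dir, "land.geojson"))
  write_polygons_geojson(world$provinces, file.path(dir, "provinces.geojson"))
  write_light_stack(world$light, dir)
  utils::write.csv(world$registry$table, file.path(dir, "registry.csv"),
                   row.names = FALSE)
  utils::write.csv(world$ranges$table, file.path(dir, "ranges.csv"),
                   row.names = FALSE)
  gz <- world$gazetteer$entries
  names(gz)[names(gz) == "uncertainty_m"] <- "uncertainty_m"
  utils::write.csv(gz, file.path(dir, "gazetteer.csv"), row.names = FALSE)
  invisible(dir)
}
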