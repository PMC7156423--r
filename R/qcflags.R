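# The three-part quality flagging system: records on land, records in
# regions with unsuitable benthic light for photosynthesis, and records
# outside the known distribution of their species.

#' Quality-control configuration
#'
#' Thresholds and exemptions of the flagging system. The shoreline
#' tolerance absorbs the spatial resolution of the land polygons: a record
#' inside land but within `shoreline_threshold_km` of the coast is not
#' flagged. The light threshold is the minimum annual light dose at the
#' sea bottom compatible with marine-forest photosynthesis. Holopelagic
#' *Sargassum* species, which complete their life cycle floating at the
#' surface, are exempt from the light flag.
#'
#' @param shoreline_threshold_km on-land tolerance, kilometers (> 0).
#' @param light_threshold limiting light, E·m^-2·yr^-1 (> 0).
#' @param exempt_species accepted species names exempt from the light flag.
#' @return A `qc_config` object.
#' @export
qc_config <- function(shoreline_threshold_km = 1.0,
                      light_threshold = 50.0,
                      exempt_species = c("Sargassum fluitans",
                                         "Sargassum natans",
                                         "Sargassum pusillum")) {
  stopifnot(shoreline_threshold_km > 0, light_threshold > 0)
  structure(list(shoreline_threshold_km = shoreline_threshold_km,
                 light_threshold = light_threshold,
                 exempt_species = exempt_species),
            class = "qc_config")
}

#' Read a qc_config from a plain-text key-value file
#'
#' Lines of the form `key: value` (YAML-style scalars);
#' `exempt_species` may be a comma-separated list. Unknown keys error.
#'
#' @param path file path.
#' @return A [qc_config()].
#' @export
read_qc_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- grep("^[[:space:]]*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  cfg <- qc_config()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    switch(key,
      shoreline_threshold_km = { cfg$shoreline_threshold_km <- as.numeric(val) },
      light_threshold = { cfg$light_threshold <- as.numeric(val) },
      exempt_species = { cfg$exempt_species <- trimws(strsplit(val, ",")[[1]]) },
      stop("unknown qc_config key: ", key))
  }
  stopifnot(cfg$shoreline_threshold_km > 0, cfg$light_threshold > 0)
  cfg
}

#' Known distribution ranges per species
#'
#' Maps an accepted species name to the set of marine province ids where
#' literature or expert knowledge documents the species. A species present
#' with an empty set is distinct from a species absent from the table:
#' absent species have no distribution information at all and their records
#' are removed by [apply_flags()].
#'
#' @param species character vector (one entry per species-province pair).
#' @param province_id integer vector parallel to `species`.
#' @param citation optional citation per pair.
#' @return A `known_ranges` object.
#' @export
known_ranges <- function(species = character(), province_id = integer(),
                         citation = NULL) {
  df <- data.frame(species = as.character(species),
                   province_id = as.integer(province_id),
                   citation = if (is.null(citation)) NA_character_ else as.character(citation),
                   stringsAsFactors = FALSE)
  # a pair with NA province_id registers the species with an empty range
  # set (documented, but nowhere) — distinct from a species absent entirely
  by_species <- lapply(split(df$province_id, df$species),
                       function(v) v[!is.na(v)])
  structure(list(table = df, by_species = by_species),
            class = "known_ranges")
}

#' @rdname known_ranges
#' @param path CSV with columns `species`, `province_id` and optionally
#'   `citation`.
#' @export
read_known_ranges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "province_id") %in% names(df))) {
    stop("range table must have columns species, province_id")
  }
  known_ranges(df$species, df$province_id, df$citation)
}

#' On-land flag
#'
#' A record is flagged when its point lies inside a land polygon AND more
#' than the shoreline tolerance from the nearest shoreline; points inside
#' land but within the tolerance are treated as coastal polygon-resolution
#' error and left clear. Records without coordinates are `"unevaluated"`.
#'
#' @param rs a [record_set()].
#' @param land land [polygon_set()].
#' @param cfg a [qc_config()].
#' @return Character vector of flag states, one per record.
#' @export
flag_on_land <- function(rs, land, cfg = qc_config()) {
  stopifnot(inherits(rs, "record_set"), inherits(land, "polygon_set"))
  lon <- rs$records$decimalLongitude
  lat <- rs$records$decimalLatitude
  out <- rep("clear", nrow(rs$records))
  out[is.na(lon) | is.na(lat)] <- "unevaluated"
  eval_i <- which(out == "clear")
  if (!length(eval_i)) return(out)
  inside <- rep(FALSE, length(eval_i))
  for (p in land$polygons) {
    bb <- p$bbox
    cand <- which(!inside & lon[eval_i] >= bb[1] & lon[eval_i] <= bb[3] &
                    lat[eval_i] >= bb[2] & lat[eval_i] <= bb[4])
    if (!length(cand)) next
    inside[cand] <- point_in_polygon(lon[eval_i[cand]], lat[eval_i[cand]], p$rings)
  }
  if (any(inside)) {
    ii <- eval_i[inside]
    d <- distance_to_shoreline_km(lon[ii], lat[ii], land)
    out[ii[d > cfg$shoreline_threshold_km]] <- "flagged"
  }
  out
}

#' Unsuitable-light flag
#'
#' A record is flagged when the maximum benthic light over the three depth
#' layers at its location is strictly below the limiting threshold.
#' Exempt (holopelagic) species are never flagged. `"unevaluated"` where
#' coordinates are missing or no layer has data at the point.
#'
#' @param rs a [record_set()] with standardized taxonomy.
#' @param stack a [light_stack()].
#' @param cfg a [qc_config()].
#' @return Character vector of flag states.
#' @export
flag_unsuitable_light <- function(rs, stack, cfg = qc_config()) {
  stopifnot(inherits(rs, "record_set"), inherits(stack, "light_stack"))
  lon <- rs$records$decimalLongitude
  lat <- rs$records$decimalLatitude
  out <- rep("clear", nrow(rs$records))
  no_xy <- is.na(lon) | is.na(lat)
  out[no_xy] <- "unevaluated"
  light <- rep(NA_real_, length(lon))
  light[!no_xy] <- sample_light_max(lon[!no_xy], lat[!no_xy], stack)
  out[!no_xy & is.na(light)] <- "unevaluated"
  out[!no_xy & !is.na(light) & light < cfg$light_threshold] <- "flagged"
  exempt <- !is.na(rs$records$acceptedName) &
    rs$records$acceptedName %in% cfg$exempt_species
  out[exempt & !no_xy] <- "clear"
  out
}

#' Outside-known-distribution flag
#'
#' Compares the marine province containing each record with the species'
#' documented province set. Returns per record one of `"flagged"` (in a
#' province outside the documented set), `"clear"` (inside), `"remove"`
#' (species absent from the range table — no distribution information
#' exists, the record cannot be verified and is removed downstream), or
#' `"unevaluated"` (missing coordinates, or no province contains the
#' point, e.g. far offshore beyond province coverage).
#'
#' @param rs a [record_set()] with standardized taxonomy.
#' @param provinces province [polygon_set()].
#' @param ranges a [known_ranges()] table.
#' @return Character vector over
#'   `{"flagged", "clear", "remove", "unevaluated"}`.
#' @export
flag_outside_distribution <- function(rs, provinces, ranges) {
  stopifnot(inherits(rs, "record_set"), inherits(provinces, "polygon_set"),
            inherits(ranges, "known_ranges"))
  df <- rs$records
  out <- rep("clear", nrow(df))
  known <- df$acceptedName %in% names(ranges$by_species)
  out[!known] <- "remove"
  no_xy <- is.na(df$decimalLongitude) | is.na(df$decimalLatitude)
  out[known & no_xy] <- "unevaluated"
  todo <- which(known & !no_xy)
  if (length(todo)) {
    prov <- locate_province(df$decimalLongitude[todo], df$decimalLatitude[todo],
                            provinces)
    in_range <- mapply(function(p, sp) {
      if (is.na(p)) NA
      else p %in% ranges$by_species[[sp]]
    }, prov, df$acceptedName[todo])
    out[todo[is.na(in_range)]] <- "unevaluated"
    out[todo[!is.na(in_range) & !in_range]] <- "flagged"
  }
  out
}

#' Evaluate all three quality flags
#'
#' Runs the on-land, unsuitable-light and outside-distribution checks on a
#' standardized, deduplicated record set. The three flags are independent:
#' a record may carry one, two or all three. Records whose species has no
#' entry in the range table are removed (with a provenance count), since
#' no information exists to verify their distribution.
#'
#' @param rs a [record_set()].
#' @param land land [polygon_set()].
#' @param stack a [light_stack()].
#' @param provinces province [polygon_set()].
#' @param ranges a [known_ranges()] table.
#' @param cfg a [qc_config()].
#' @return The flagged `record_set`.
#' @export
apply_flags <- function(rs, land, stack, provinces, ranges,
                        cfg = qc_config()) {
  stopifnot(inherits(rs, "record_set"))
  rs$records$flagMachineOnLand <- flag_on_land(rs, land, cfg)
  rs$records$flagMachineSuitableLightBottom <-
    flag_unsuitable_light(rs, stack, cfg)
  dist <- flag_outside_distribution(rs, provinces, ranges)
  drop <- dist == "remove"
  rs$records$flagHumanCuratedDistribution <-
    ifelse(drop, "unevaluated", dist)
  rs <- subset_records(rs, !drop)
  f <- rs$records
  add_provenance(rs, sprintf(
    "flags: %d removed (no distribution information); flagged on-land %d, light %d, distribution %d",
    sum(drop), sum(f$flagMachineOnLand == "flagged"),
    sum(f$flagMachineSuitableLightBottom == "flagged"),
    sum(f$flagHumanCuratedDistribution == "flagged")))
}
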