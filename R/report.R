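# Summary tables (records and species per ecological group x source type
# x flag) and GeoJSON export.

# half-up decimal rounding; R's round() is half-even, summary percentages
# follow the usual half-up reporting convention
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

GROUPS <- c("kelp_fucoid", "seagrass")
SOURCES <- c("literature", "herbaria", "repositories")
METRICS <- c("overall", "flagged_on_land", "flagged_light",
             "flagged_distribution")

#' Summarize flag counts per ecological group and source type
#'
#' Produces the record-level summary (counts of records, and of records
#' flagged on land / for unsuitable light / outside the known
#' distribution, per ecological group x source type, with `total` margins)
#' and a species-level variant counting species with at least one record,
#' or at least one flagged record, in each cell. Percentages are
#' `100 * count / overall` of the same group x source cell, half-up
#' rounded to 2 decimals; the species-level denominator is the number of
#' species observed in that group x source cell. Empty cells report 0
#' counts and 0 percentages.
#'
#' @param rs a flagged [record_set()] with standardized taxonomy.
#' @param gs a [group_scheme()].
#' @return A `qc_summary`: list of data frames `records` and `species`
#'   with columns `group`, `sourceType`, `metric`, `count`, `percentage`.
#' @export
summarize_records <- function(rs, gs = group_scheme()) {
  stopifnot(inherits(rs, "record_set"))
  df <- rs$records
  grp <- assign_group(df$order, df$family, gs)
  groups <- c(intersect(c(GROUPS, "none"), unique(grp)), "total")
  src <- ifelse(is.na(df$sourceType), "unknown", df$sourceType)
  sources <- c(intersect(c(SOURCES, "unknown"), unique(src)), "total")
  is_flagged <- cbind(
    overall = rep(TRUE, nrow(df)),
    flagged_on_land = df$flagMachineOnLand == "flagged",
    flagged_light = df$flagMachineSuitableLightBottom == "flagged",
    flagged_distribution = df$flagHumanCuratedDistribution == "flagged")

  one_table <- function(counter) {
    rows <- expand.grid(group = groups, sourceType = sources,
                        metric = METRICS, stringsAsFactors = FALSE)
    rows$count <- mapply(function(g, s, m) {
      sel <- (g == "total" | grp == g) & (s == "total" | src == s)
      counter(sel, is_flagged[, m])
    }, rows$group, rows$sourceType, rows$metric)
    overall <- rows$count[rows$metric == "overall"]
    names(overall) <- paste(rows$group[rows$metric == "overall"],
                            rows$sourceType[rows$metric == "overall"])
    denom <- overall[paste(rows$group, rows$sourceType)]
    rows$percentage <- ifelse(denom > 0,
                              round_half_up(100 * rows$count / denom, 2), 0)
    rows$percentage[rows$metric == "overall"] <- NA_real_
    rows[order(match(rows$group, groups), match(rows$sourceType, sources),
               match(rows$metric, METRICS)), , drop = FALSE]
  }

  rec_tab <- one_table(function(sel, flag) sum(sel & flag))
  spp_tab <- one_table(function(sel, flag) {
    length(unique(df$acceptedAphiaID[sel & flag &
                                       !is.na(df$acceptedAphiaID)]))
  })
  rownames(rec_tab) <- rownames(spp_tab) <- NULL
  structure(list(records = rec_tab, species = spp_tab), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("Record counts (percentage of group x source overall):\n")
  print(x$records, row.names = FALSE)
  cat("\nSpecies with >= 1 (flagged) record:\n")
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Export records as a GeoJSON FeatureCollection of points
#'
#' One Point feature per georeferenced record, coordinates in
#' `[longitude, latitude]` order, with every occurrence field as a feature
#' property (flags in the dataset's `-1`/empty convention). Records
#' without coordinates are skipped and counted.
#'
#' @param rs a [record_set()].
#' @param path output path.
#' @return `path`, invisibly; the number of skipped records is reported
#'   via a message.
#' @export
export_geojson <- function(rs, path) {
  stopifnot(inherits(rs, "record_set"))
  df <- rs$records
  has_xy <- !is.na(df$decimalLongitude) & !is.na(df$decimalLatitude)
  skipped <- sum(!has_xy)
  df <- df[has_xy, , drop = FALSE]
  for (col in FLAG_COLUMNS) {
    df[[col]] <- ifelse(df[[col]] == "flagged", "-1", "")
  }
  prop_cols <- setdiff(names(df), c("decimalLongitude", "decimalLatitude"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, prop_cols, drop = FALSE])
    props <- props[!vapply(props, function(v) is.na(v), logical(1))]
    list(type = "Feature", properties = props,
         geometry = list(type = "Point",
                         coordinates = c(df$decimalLongitude[i],
                                         df$decimalLatitude[i])))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (skipped > 0) message(skipped, " record(s) without coordinates skipped")
  invisible(path)
}
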