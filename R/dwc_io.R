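# Tabular I/O for occurrence records, gazetteer geocoding, duplicate
# removal and pruning.

# exact text form of a double: %.17g round-trips the binary value, trailing
# zeros are irrelevant after parsing, so equal doubles <=> equal strings
num_key <- function(x) {
  out <- rep("NA", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  out
}

chr_key <- function(x) ifelse(is.na(x), "NA", as.character(x))

normalize_locality <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

parse_num <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read occurrence records from a delimited text file
#'
#' Reads a CSV/TSV table whose header uses the Darwin-Core-style column
#' names of the marine-forest occurrence schema (`id`, `name`,
#' `acceptedName`, `decimalLongitude`, `decimalLatitude`, `year`, ...,
#' `flagMachineOnLand`, `flagMachineSuitableLightBottom`,
#' `flagHumanCuratedDistribution`). Unknown columns are kept as passthrough.
#' Rows violating basic type invariants (coordinates out of range, month or
#' day out of range, day without month, month without year, negative
#' coordinate uncertainty) are dropped and counted in the provenance log.
#'
#' Flag columns holding `-1` map to the `"flagged"` state, empty fields to
#' `"clear"`; a flag column absent from the file maps to `"unevaluated"`.
#'
#' @param path path to the delimited file.
#' @param delim field delimiter, default comma.
#' @return A [record_set()].
#' @seealso [write_records()]
#' @export
read_records <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = delim, colClasses = "character",
                         check.names = FALSE, na.strings = character(),
                         fileEncoding = "UTF-8")
  if (!any(c("name", "acceptedName") %in% names(raw))) {
    stop("schema error: file has neither a 'name' nor an 'acceptedName' column")
  }
  n_in <- nrow(raw)
  df <- raw
  blank_to_na <- function(x) { x <- as.character(x); x[trimws(x) == ""] <- NA; x }
  for (col in names(df)) df[[col]] <- blank_to_na(df[[col]])

  dropped_parse <- rep(FALSE, n_in)
  for (col in intersect(c(DWC_NUMERIC, DWC_INTEGER), names(df))) {
    num <- parse_num(df[[col]])
    dropped_parse <- dropped_parse | (!is.na(df[[col]]) & is.na(num))
    df[[col]] <- if (col %in% DWC_INTEGER) as.integer(round(num)) else num
  }
  present_flags <- intersect(FLAG_COLUMNS, names(df))
  for (col in present_flags) {
    v <- df[[col]]
    flagged <- !is.na(v) & trimws(v) %in% c("-1", "−1")
    df[[col]] <- ifelse(flagged, "flagged", "clear")
  }
  if (is.null(df$id)) df$id <- sprintf("row%06d", seq_len(n_in))

  valid <- !dropped_parse
  inrng <- function(x, lo, hi) is.na(x) | (x >= lo & x <= hi)
  if (!is.null(df$decimalLatitude))  valid <- valid & inrng(df$decimalLatitude, -90, 90)
  if (!is.null(df$decimalLongitude)) valid <- valid & inrng(df$decimalLongitude, -180, 180)
  if (!is.null(df$month)) valid <- valid & inrng(df$month, 1, 12)
  if (!is.null(df$day))   valid <- valid & inrng(df$day, 1, 31)
  if (!is.null(df$coordinateUncertaintyInMeters)) {
    valid <- valid & inrng(df$coordinateUncertaintyInMeters, 0, Inf)
  }
  # day present => month present => year present
  if (all(c("year", "month", "day") %in% names(df))) {
    valid <- valid & !(!is.na(df$day) & is.na(df$month)) &
      !(!is.na(df$month) & is.na(df$year))
  }
  df <- df[valid, , drop = FALSE]
  rs <- record_set(df)
  for (col in setdiff(FLAG_COLUMNS, present_flags)) {
    rs$records[[col]] <- "unevaluated"
  }
  add_provenance(rs, sprintf("read: %d kept, %d dropped", nrow(df),
                             n_in - nrow(df)))
}

#' Write occurrence records to CSV
#'
#' Writes the record set with the dataset's column names. Flag states
#' serialize per the deposited-table convention: `"flagged"` as `-1`,
#' `"clear"` as an empty field; `"unevaluated"` also writes as empty but the
#' affected flags are listed in a `recordNotes` annotation (the binary file
#' encoding cannot carry the third state). With `pruned = TRUE` only
#' records retained by [prune_records()] are written.
#'
#' @param rs a [record_set()].
#' @param path output file path.
#' @param pruned write only unflagged records.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path, pruned = FALSE, delim = ",") {
  stopifnot(inherits(rs, "record_set"))
  if (pruned) rs <- prune_records(rs)
  df <- rs$records
  uneval <- rep("", nrow(df))
  for (col in FLAG_COLUMNS) {
    u <- df[[col]] == "unevaluated"
    uneval[u] <- paste0(uneval[u], ifelse(nzchar(uneval[u]), ",", ""), col)
    df[[col]] <- ifelse(df[[col]] == "flagged", "-1", "")
  }
  has_note <- nzchar(uneval)
  if (any(has_note)) {
    note <- paste0("unevaluated flags: ", uneval[has_note])
    old <- df$recordNotes[has_note]
    df$recordNotes[has_note] <- ifelse(is.na(old), note, paste(old, note, sep = "; "))
  }
  for (col in intersect(DWC_NUMERIC, names(df))) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  utils::write.table(df, con, sep = delim, na = "", row.names = FALSE,
                     qmethod = "double", quote = TRUE)
  invisible(path)
}

#' Load a locality gazetteer
#'
#' Reads a 4-column CSV (`locality`, `longitude`, `latitude`,
#' `uncertainty_m`) mapping place names to coordinates. Locality keys are
#' normalized (lowercased, whitespace-collapsed); coordinates must be in
#' valid ranges and uncertainties non-negative.
#'
#' @param path path to the gazetteer CSV.
#' @return A `gazetteer` object.
#' @export
read_gazetteer <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locality", "longitude", "latitude", "uncertainty_m")
  if (!all(need %in% names(df))) {
    stop("gazetteer must have columns: ", paste(need, collapse = ", "))
  }
  gazetteer(df$locality, df$longitude, df$latitude, df$uncertainty_m)
}

#' @rdname read_gazetteer
#' @param locality,longitude,latitude,uncertainty_m vectors defining entries.
#' @export
gazetteer <- function(locality = character(), longitude = numeric(),
                      latitude = numeric(), uncertainty_m = numeric()) {
  df <- data.frame(locality = normalize_locality(locality),
                   longitude = as.numeric(longitude),
                   latitude = as.numeric(latitude),
                   uncertainty_m = as.numeric(uncertainty_m),
                   stringsAsFactors = FALSE)
  if (any(abs(df$longitude) > 180 | abs(df$latitude) > 90, na.rm = TRUE)) {
    stop("gazetteer coordinates out of range")
  }
  if (any(df$uncertainty_m < 0, na.rm = TRUE)) stop("gazetteer uncertainty must be >= 0")
  df <- df[!duplicated(df$locality), , drop = FALSE]
  structure(list(entries = df), class = "gazetteer")
}

#' Geocode records lacking coordinates from a gazetteer
#'
#' Records that already carry coordinates pass through unchanged. Records
#' without coordinates but with a locality matching a gazetteer entry get
#' that entry's coordinates and uncertainty, plus a `recordNotes`
#' annotation. Records without coordinates and with no gazetteer match are
#' removed (the pipeline keeps only georeferenceable records) and counted
#' in the provenance log.
#'
#' @param rs a [record_set()].
#' @param gaz a [gazetteer()].
#' @return The geocoded `record_set`.
#' @export
geocode_records <- function(rs, gaz) {
  stopifnot(inherits(rs, "record_set"), inherits(gaz, "gazetteer"))
  df <- rs$records
  missing_xy <- is.na(df$decimalLongitude) | is.na(df$decimalLatitude)
  key <- normalize_locality(df$locality)
  idx <- match(key, gaz$entries$locality)
  fill <- missing_xy & !is.na(df$locality) & !is.na(idx)
  if (any(fill)) {
    df$decimalLongitude[fill] <- gaz$entries$longitude[idx[fill]]
    df$decimalLatitude[fill] <- gaz$entries$latitude[idx[fill]]
    df$coordinateUncertaintyInMeters[fill] <- gaz$entries$uncertainty_m[idx[fill]]
    note <- paste0("geocoded from gazetteer entry '", key[fill], "'")
    old <- df$recordNotes[fill]
    df$recordNotes[fill] <- ifelse(is.na(old), note, paste(old, note, sep = "; "))
  }
  drop <- missing_xy & !fill
  rs$records <- df[!drop, , drop = FALSE]
  rownames(rs$records) <- NULL
  add_provenance(rs, sprintf("geocode: %d filled from gazetteer, %d removed (no coordinates)",
                             sum(fill), sum(drop)))
}

#' Remove exact duplicate records
#'
#' Two records are duplicates when they agree exactly on accepted taxon,
#' longitude, latitude, depth and collection date (year, month, day), with
#' absent values comparing equal to absent. The depth component uses
#' `verbatimDepth` when present, otherwise the
#' (`minimumDepthInMeters`, `maximumDepthInMeters`) pair. Among duplicates
#' the first record in input order is retained.
#'
#' @param rs a [record_set()] (taxonomically standardized, so that
#'   `acceptedAphiaID` identifies the taxon where resolvable).
#' @return The deduplicated `record_set`.
#' @export
dedup_records <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  df <- rs$records
  depth_key <- ifelse(!is.na(df$verbatimDepth), num_key(df$verbatimDepth),
                      paste(num_key(df$minimumDepthInMeters),
                            num_key(df$maximumDepthInMeters), sep = ".."))
  key <- paste(chr_key(df$acceptedAphiaID),
               num_key(df$decimalLongitude), num_key(df$decimalLatitude),
               depth_key, chr_key(df$year), chr_key(df$month),
               chr_key(df$day), sep = "|")
  keep <- !duplicated(key)
  rs$records <- df[keep, , drop = FALSE]
  rownames(rs$records) <- NULL
  add_provenance(rs, sprintf("dedup: %d duplicates removed", sum(!keep)))
}

#' Prune flagged records
#'
#' Returns the records carrying no quality flag: the "pruned" dataset
#' discarding all potentially biased records. A record is removed when any
#' of its three flags is in the `"flagged"` state; flags left
#' `"unevaluated"` by [apply_flags()] (e.g. the light flag where the raster
#' has no data) are not treated as evidence of bias. Calling this on a set
#' in which some record has all three flags unevaluated is an error:
#' pruning before flagging is a pipeline mistake.
#'
#' @param rs a flagged [record_set()].
#' @return The pruned `record_set`.
#' @export
prune_records <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  df <- rs$records
  uneval <- df$flagMachineOnLand == "unevaluated" &
    df$flagMachineSuitableLightBottom == "unevaluated" &
    df$flagHumanCuratedDistribution == "unevaluated"
  if (any(uneval)) {
    stop(sum(uneval), " record(s) have no evaluated flags; run apply_flags() before pruning")
  }
  flagged <- df$flagMachineOnLand == "flagged" |
    df$flagMachineSuitableLightBottom == "flagged" |
    df$flagHumanCuratedDistribution == "flagged"
  rs$records <- df[!flagged, , drop = FALSE]
  rownames(rs$records) <- NULL
  add_provenance(rs, sprintf("prune: %d flagged records removed", sum(flagged)))
}
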