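# Core record container: a data frame of Darwin-Core-termed occurrence rows
# plus a provenance log of every operation applied to it.

# Canonical column set, in dataset order. Flag columns use the deposited
# dataset's names; internally they hold the tri-state strings "flagged",
# "clear", "unevaluated" and serialize to -1 / empty on write.
DWC_COLUMNS <- c(
  "id", "name", "acceptedAphiaID", "acceptedName", "taxonomicStatus",
  "kingdom", "phylum", "class", "order", "family", "genus",
  "decimalLongitude", "decimalLatitude", "coordinateUncertaintyInMeters",
  "verbatimDepth", "minimumDepthInMeters", "maximumDepthInMeters",
  "year", "month", "day", "country", "locality", "sourceType",
  "bibliographicCitation", "bibliographicCitationDOI",
  "flagMachineOnLand", "flagMachineSuitableLightBottom",
  "flagHumanCuratedDistribution", "recordNotes"
)

FLAG_COLUMNS <- c(
  "flagMachineOnLand", "flagMachineSuitableLightBottom",
  "flagHumanCuratedDistribution"
)

FLAG_STATES <- c("flagged", "clear", "unevaluated")

DWC_NUMERIC <- c(
  "decimalLongitude", "decimalLatitude", "coordinateUncertaintyInMeters",
  "verbatimDepth", "minimumDepthInMeters", "maximumDepthInMeters"
)
DWC_INTEGER <- c("acceptedAphiaID", "year", "month", "day")

#' Occurrence record set
#'
#' A `record_set` bundles an ordered data frame of occurrence records (one
#' row per record, Darwin-Core-termed columns, see [read_records()]) with a
#' provenance log: a character vector where every operation that removed or
#' altered records appends a line with its counts. Record ids must be unique.
#'
#' @param records data frame of occurrence records. Missing canonical
#'   columns are added as `NA`; extra columns are preserved as passthrough.
#' @param provenance character vector of lineage entries.
#' @return An object of class `record_set` with elements `records` (data
#'   frame) and `provenance` (character).
#' @examples
#' rs <- record_set(data.frame(id = "r1", name = "Zostera marina",
#'                             decimalLongitude = -8.8, decimalLatitude = 37))
#' n_records(rs)
#' @export
record_set <- function(records = data.frame(), provenance = character()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0 && is.null(records$id)) {
    stop("records must have an 'id' column")
  }
  for (col in setdiff(DWC_COLUMNS, names(records))) {
    fill <- if (col %in% DWC_NUMERIC) NA_real_
      else if (col %in% DWC_INTEGER) NA_integer_
      else if (col %in% FLAG_COLUMNS) "unevaluated"
      else NA_character_
    records[[col]] <- rep(fill, nrow(records))
  }
  extra <- setdiff(names(records), DWC_COLUMNS)
  records <- records[, c(DWC_COLUMNS, extra), drop = FALSE]
  if (anyDuplicated(records$id)) {
    stop("record ids must be unique within a record_set")
  }
  bad <- !records$flagMachineOnLand %in% FLAG_STATES |
    !records$flagMachineSuitableLightBottom %in% FLAG_STATES |
    !records$flagHumanCuratedDistribution %in% FLAG_STATES
  if (any(bad)) stop("flag columns must be one of: ",
                     paste(FLAG_STATES, collapse = ", "))
  rownames(records) <- NULL
  structure(list(records = records, provenance = as.character(provenance)),
            class = "record_set")
}

#' @rdname record_set
#' @param rs a `record_set`.
#' @export
n_records <- function(rs) {
  stopifnot(inherits(rs, "record_set"))
  nrow(rs$records)
}

#' @rdname record_set
#' @param entry single provenance line to append.
#' @export
add_provenance <- function(rs, entry) {
  stopifnot(inherits(rs, "record_set"), is.character(entry))
  rs$provenance <- c(rs$provenance, entry)
  rs
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set: %d records>\n", nrow(x$records)))
  flags <- vapply(FLAG_COLUMNS, function(f) sum(x$records[[f]] == "flagged"),
                  integer(1))
  cat(sprintf("  flagged: on-land %d, light %d, distribution %d\n",
              flags[1], flags[2], flags[3]))
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in x$provenance) cat("    -", p, "\n")
  }
  invisible(x)
}

# keep rows by logical/integer index, preserving passthrough columns
subset_records <- function(rs, keep) {
  rs$records <- rs$records[keep, , drop = FALSE]
  rownames(rs$records) <- NULL
  rs
}
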