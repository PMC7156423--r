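# Local WoRMS-style taxonomic standardization: registry loading, synonym
# resolution, record standardization and ecological group assignment.

HIERARCHY_COLS <- c("kingdom", "phylum", "class", "order", "family", "genus")

normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Build or load a taxon registry
#'
#' A taxon registry is a local stand-in for the World Register of Marine
#' Species: each row holds an `aphiaID`, a `scientificName`, a `status`
#' (`accepted`, `unaccepted` or `uncertain`), the `acceptedAphiaID` it
#' resolves to, a `rank` and the taxonomic hierarchy (kingdom..genus).
#' Accepted rows must reference themselves; unaccepted rows must resolve,
#' possibly through a finite chain of synonyms, to an accepted row.
#'
#' @param df data frame with the registry columns.
#' @return A `taxon_registry` object.
#' @export
taxon_registry <- function(df) {
  need <- c("aphiaID", "scientificName", "status", "acceptedAphiaID",
            "rank", HIERARCHY_COLS)
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("registry missing columns: ",
                            paste(missing, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$aphiaID <- as.integer(df$aphiaID)
  df$acceptedAphiaID <- as.integer(df$acceptedAphiaID)
  if (any(is.na(df$aphiaID)) || any(df$aphiaID <= 0)) {
    stop("aphiaID must be a positive integer")
  }
  if (anyDuplicated(df$aphiaID)) {
    stop("duplicate aphiaID in registry: ",
         paste(unique(df$aphiaID[duplicated(df$aphiaID)]), collapse = ", "))
  }
  if (!all(df$status %in% c("accepted", "unaccepted", "uncertain"))) {
    stop("status must be accepted, unaccepted or uncertain")
  }
  acc <- df$status == "accepted"
  if (any(df$acceptedAphiaID[acc] != df$aphiaID[acc])) {
    stop("accepted records must have acceptedAphiaID equal to their own aphiaID")
  }
  reg <- structure(list(
    table = df,
    id_index = stats::setNames(seq_len(nrow(df)), df$aphiaID),
    name_index = stats::setNames(seq_len(nrow(df)),
                                 normalize_name(df$scientificName))
  ), class = "taxon_registry")
  # validate synonym chains of every unaccepted row: finite, ending accepted
  for (i in which(df$status == "unaccepted")) {
    j <- chain_resolve(reg, i)
    if (is.na(j)) {
      stop("dangling or cyclic acceptedAphiaID chain from aphiaID ", df$aphiaID[i])
    }
  }
  reg
}

# follow acceptedAphiaID from row i to an accepted row; NA when the chain
# dangles, cycles, or exceeds the depth cap
chain_resolve <- function(reg, i, max_depth = 20L) {
  df <- reg$table
  for (step in seq_len(max_depth)) {
    if (df$status[i] == "accepted") return(i)
    if (df$status[i] == "uncertain") return(NA_integer_)
    nxt <- reg$id_index[as.character(df$acceptedAphiaID[i])]
    if (is.na(nxt) || nxt == i) return(NA_integer_)
    i <- nxt
  }
  NA_integer_
}

#' @rdname taxon_registry
#' @param path path to a registry CSV with columns `aphiaID`,
#'   `scientificName`, `status`, `acceptedAphiaID`, `rank`, `kingdom`,
#'   `phylum`, `class`, `order`, `family`, `genus`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  taxon_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.taxon_registry <- function(x, ...) {
  cat(sprintf("<taxon_registry: %d taxa (%d accepted)>\n",
              nrow(x$table), sum(x$table$status == "accepted")))
  invisible(x)
}

#' Resolve a verbatim taxon name to its accepted record
#'
#' Lookup is exact after case and whitespace normalization — no fuzzy
#' matching; misspelled names are treated as absent, mirroring the removal
#' (rather than repair) of unmatchable entries. Unaccepted names follow
#' their synonym chain to the accepted record. Names resolving to a record
#' with infraspecific rank are rolled up to the species-rank parent when
#' the binomial itself is registered.
#'
#' @param name verbatim taxon name.
#' @param reg a [taxon_registry()].
#' @return A list with `status` (`"accepted"`, `"nomatch"` or
#'   `"uncertain"`) and, when accepted, `taxon`: the accepted registry row.
#' @export
resolve_name <- function(name, reg) {
  stopifnot(inherits(reg, "taxon_registry"))
  i <- reg$name_index[normalize_name(name)]
  if (is.na(i)) return(list(status = "nomatch", taxon = NULL))
  df <- reg$table
  if (df$status[i] == "uncertain") return(list(status = "uncertain", taxon = NULL))
  j <- chain_resolve(reg, i)
  if (is.na(j)) return(list(status = "nomatch", taxon = NULL))
  # infraspecific rollup: prefer the species-rank accepted parent if present
  if (!is.na(df$rank[j]) && !df$rank[j] %in% c("species", "Species")) {
    tokens <- strsplit(trimws(df$scientificName[j]), "[[:space:]]+")[[1]]
    if (length(tokens) > 2) {
      k <- reg$name_index[normalize_name(paste(tokens[1:2], collapse = " "))]
      if (!is.na(k)) {
        k2 <- chain_resolve(reg, k)
        if (!is.na(k2)) j <- k2
      }
    }
  }
  list(status = "accepted", taxon = as.list(df[j, , drop = FALSE]))
}

#' Standardize record taxonomy against a registry
#'
#' Resolves every record's verbatim `name`, fills `acceptedAphiaID`,
#' `acceptedName`, `taxonomicStatus` and the taxonomic hierarchy from the
#' accepted registry record, and removes records whose names have no match
#' or an uncertain status (counts go to provenance). After this step every
#' surviving record points to an accepted species, and synonyms of the same
#' species share one `acceptedAphiaID`.
#'
#' @param rs a [record_set()].
#' @param reg a [taxon_registry()].
#' @return The standardized `record_set`.
#' @export
standardize_records <- function(rs, reg) {
  stopifnot(inherits(rs, "record_set"), inherits(reg, "taxon_registry"))
  df <- rs$records
  keys <- unique(df$name)
  res <- lapply(keys, resolve_name, reg = reg)
  names(res) <- keys
  status <- vapply(res, `[[`, character(1), "status")[df$name]
  keep <- !is.na(status) & status == "accepted"
  n_nomatch <- sum(is.na(status) | status == "nomatch")
  n_uncertain <- sum(!is.na(status) & status == "uncertain")
  for (i in which(keep)) {
    t <- res[[df$name[i]]]$taxon
    df$acceptedAphiaID[i] <- t$aphiaID
    df$acceptedName[i] <- t$scientificName
    df$taxonomicStatus[i] <- "accepted"
    for (h in HIERARCHY_COLS) df[[h]][i] <- t[[h]]
  }
  rs$records <- df[keep, , drop = FALSE]
  rownames(rs$records) <- NULL
  rs <- add_provenance(rs, sprintf(
    "standardize: %d removed (no match), %d removed (uncertain status); %d accepted species",
    n_nomatch, n_uncertain, length(unique(rs$records$acceptedAphiaID))))
  rs
}

#' Ecological group scheme
#'
#' Marine forests comprise two ecological groups: kelp and fucoid brown
#' algae, identified by the orders Fucales, Laminariales and
#' Tilopteridales, and seagrasses, identified by the families
#' Cymodoceaceae, Hydrocharitaceae, Posidoniaceae and Zosteraceae.
#'
#' @param kelp_fucoid_orders order names defining the kelp/fucoid group.
#' @param seagrass_families family names defining the seagrass group.
#' @return A `group_scheme` object.
#' @export
group_scheme <- function(
    kelp_fucoid_orders = c("Fucales", "Laminariales", "Tilopteridales"),
    seagrass_families = c("Cymodoceaceae", "Hydrocharitaceae",
                          "Posidoniaceae", "Zosteraceae")) {
  structure(list(kelp_fucoid_orders = kelp_fucoid_orders,
                 seagrass_families = seagrass_families),
            class = "group_scheme")
}

#' Assign a taxon (or records) to an ecological group
#'
#' @param order,family taxonomic hierarchy values (vectorized).
#' @param gs a [group_scheme()].
#' @return `"kelp_fucoid"`, `"seagrass"` or `"none"` per element.
#' @export
assign_group <- function(order, family, gs = group_scheme()) {
  out <- rep("none", length(order))
  out[!is.na(family) & family %in% gs$seagrass_families] <- "seagrass"
  out[!is.na(order) & order %in% gs$kelp_fucoid_orders] <- "kelp_fucoid"
  out
}
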