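# Geospatial containers and their plain-text interchange formats:
# polygon sets as GeoJSON FeatureCollections, benthic light stacks as
# ESRI-ASCII-style grids (one file per depth layer).

# proper-intersection test of two planar segments (shared endpoints allowed)
segs_cross <- function(a1, a2, b1, b2) {
  orient <- function(p, q, r) {
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  }
  d1 <- orient(b1, b2, a1); d2 <- orient(b1, b2, a2)
  d3 <- orient(a1, a2, b1); d4 <- orient(a1, a2, b2)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

validate_ring <- function(ring, what = "ring") {
  if (!is.matrix(ring) || ncol(ring) != 2) stop(what, ": need a 2-column matrix")
  n <- nrow(ring)
  if (n < 4) stop(what, ": a closed ring needs at least 4 vertices")
  if (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2]) {
    stop(what, ": ring not closed (first vertex must equal last)")
  }
  if (any(abs(ring[, 1]) > 180) || any(abs(ring[, 2]) > 90)) {
    stop(what, ": vertex outside lon [-180,180] / lat [-90,90]")
  }
  if (any(abs(diff(ring[, 1])) > 180)) {
    stop(what, ": edge spans more than 180 degrees of longitude; ",
         "antimeridian-crossing polygons must be split at +/-180")
  }
  m <- n - 1L  # edges
  if (m > 3) {
    for (i in seq_len(m - 2L)) {
      jmax <- if (i == 1) m - 1L else m
      for (j in seq(i + 2L, jmax)) {
        if (segs_cross(ring[i, ], ring[i + 1, ], ring[j, ], ring[j + 1, ])) {
          stop(what, ": self-intersecting ring (edges ", i, " and ", j, ")")
        }
      }
    }
  }
  invisible(ring)
}

#' Polygon set
#'
#' A collection of polygons (outer ring plus optional hole rings), each
#' optionally carrying an integer `id` and a `name` — used for landmasses
#' and for marine province tilings. Rings are validated on construction:
#' closed, at least 4 vertices, non-self-intersecting, and not crossing the
#' antimeridian (split such inputs at +/-180 first).
#'
#' @param polygons list of `list(rings = <list of 2-col lon/lat matrices>,
#'   id = <int or NA>, name = <chr or NA>)`.
#' @return A `polygon_set` object.
#' @export
polygon_set <- function(polygons = list()) {
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(rings = list(p))
    if (is.null(p$rings)) stop("each polygon needs a 'rings' element")
    p$rings <- lapply(p$rings, function(r) {
      r <- as.matrix(r); storage.mode(r) <- "double"; validate_ring(r)
    })
    if (is.null(p$id)) p$id <- NA_integer_
    if (is.null(p$name)) p$name <- NA_character_
    p$bbox <- c(min(vapply(p$rings, function(r) min(r[, 1]), 0)),
                min(vapply(p$rings, function(r) min(r[, 2]), 0)),
                max(vapply(p$rings, function(r) max(r[, 1]), 0)),
                max(vapply(p$rings, function(r) max(r[, 2]), 0)))
    p
  })
  structure(list(polygons = polygons), class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set: %d polygons>\n", length(x$polygons)))
  invisible(x)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon features in WGS84 lon/lat axis order;
#' a MultiPolygon becomes one polygon per part sharing the feature's
#' attributes. Features may carry `province_id` and `province_name`
#' properties, used for province lookups.
#'
#' @param path path to a GeoJSON file.
#' @return A [polygon_set()].
#' @export
read_polygons_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  ring_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(v) c(v[[1]], v[[2]])))
  }
  polys <- list()
  for (f in gj$features) {
    geom <- f$geometry
    props <- f$properties
    id <- if (!is.null(props$province_id)) as.integer(props$province_id) else NA_integer_
    name <- if (!is.null(props$province_name)) as.character(props$province_name) else NA_character_
    parts <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    for (part in parts) {
      polys[[length(polys) + 1L]] <-
        list(rings = lapply(part, ring_mat), id = id, name = name)
    }
  }
  polygon_set(polys)
}

#' Write a polygon set as GeoJSON
#'
#' @param ps a [polygon_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(ps, path) {
  stopifnot(inherits(ps, "polygon_set"))
  features <- lapply(ps$polygons, function(p) {
    coords <- lapply(p$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    props <- list()
    if (!is.na(p$id)) props$province_id <- p$id
    if (!is.na(p$name)) props$province_name <- p$name
    list(type = "Feature",
         properties = if (length(props)) props else stats::setNames(list(), character()),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Benthic light raster stack
#'
#' Three co-registered regular lon/lat grids of annual benthic light
#' (E·m^-2·yr^-1), one per depth range, sharing origin, cell size and
#' dimensions. Values are non-negative or the nodata sentinel. Matrices are
#' stored with row 1 as the northernmost row (ASCII-grid order).
#'
#' @param layers list of 3 numeric matrices (identical dimensions).
#' @param xll,yll lower-left corner of the grid, decimal degrees.
#' @param cellsize cell size in degrees.
#' @param nodata nodata sentinel value.
#' @return A `light_stack` object.
#' @export
light_stack <- function(layers, xll, yll, cellsize, nodata = -9999) {
  stopifnot(length(layers) == 3)
  dims <- vapply(layers, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all 3 layers must share the same grid")
  for (m in layers) {
    bad <- !is.na(m) & m != nodata & m < 0
    if (any(bad)) stop("light values must be >= 0 or nodata")
  }
  structure(list(layers = layers, xll = xll, yll = yll,
                 cellsize = cellsize, nrows = dims[1, 1], ncols = dims[2, 1],
                 nodata = nodata),
            class = "light_stack")
}

#' Read / write one depth layer as an ESRI-ASCII-style grid
#'
#' Plain-text grid with a 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of values,
#' north to south.
#'
#' @param path file path.
#' @return `read_ascii_grid`: a list with `values` (matrix, row 1 north),
#'   `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  list(values = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll,cellsize,nodata grid geometry and sentinel.
#' @export
write_ascii_grid <- function(values, path, xll, yll, cellsize, nodata = -9999) {
  hdr <- c(sprintf("ncols %d", ncol(values)),
           sprintf("nrows %d", nrow(values)),
           sprintf("xllcorner %.10g", xll),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(values, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 3-layer light stack from ASCII grid files
#'
#' @param paths character vector of 3 grid file paths, shallowest depth
#'   range first.
#' @return A [light_stack()].
#' @export
read_light_stack <- function(paths) {
  stopifnot(length(paths) == 3)
  grids <- lapply(paths, read_ascii_grid)
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (g$xll != g1$xll || g$yll != g1$yll || g$cellsize != g1$cellsize ||
        !all(dim(g$values) == dim(g1$values))) {
      stop("light layers do not share the same grid geometry")
    }
  }
  light_stack(lapply(grids, `[[`, "values"), g1$xll, g1$yll, g1$cellsize,
              g1$nodata)
}

#' @rdname read_light_stack
#' @param stack a [light_stack()].
#' @param dir output directory; files `light_depth1.asc` .. `light_depth3.asc`.
#' @export
write_light_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "light_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("light_depth%d.asc", 1:3))
  for (k in 1:3) {
    write_ascii_grid(stack$layers[[k]], paths[k], stack$xll, stack$yll,
                     stack$cellsize, stack$nodata)
  }
  invisible(paths)
}

# grid cell index of points; NA outside the grid
cell_index <- function(lon, lat, stack) {
  col <- floor((lon - stack$xll) / stack$cellsize) + 1
  row_from_bottom <- floor((lat - stack$yll) / stack$cellsize) + 1
  row <- stack$nrows - row_from_bottom + 1
  ok <- col >= 1 & col <= stack$ncols & row >= 1 & row <= stack$nrows
  col[!ok] <- NA; row[!ok] <- NA
  cbind(row = row, col = col)
}

#' Maximum benthic light across the three depth layers
#'
#' Nearest-cell lookup in each depth layer; returns the maximum over
#' layers with data — a conservative estimate of light available at the
#' record's (unknown) depth. `NA` when the point falls outside the grid or
#' all three layers are nodata there.
#'
#' @param lon,lat point coordinates (vectorized).
#' @param stack a [light_stack()].
#' @return Numeric vector (E·m^-2·yr^-1), `NA` where unavailable.
#' @export
sample_light_max <- function(lon, lat, stack) {
  stopifnot(inherits(stack, "light_stack"))
  idx <- cell_index(lon, lat, stack)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx[, 1])
  if (!any(ok)) return(out)
  flat <- (idx[ok, 2] - 1L) * stack$nrows + idx[ok, 1]  # column-major
  vals <- sapply(stack$layers, function(m) m[flat])
  vals <- matrix(vals, nrow = sum(ok))
  vals[vals == stack$nodata] <- NA
  mx <- apply(vals, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  out[ok] <- mx
  out
}

#' Locate the marine province containing each point
#'
#' Returns the `province_id` of the polygon containing each point; when a
#' point lies on a shared boundary of several provinces the lowest id wins;
#' `NA` where no province contains the point.
#'
#' @param lon,lat point coordinates (vectorized).
#' @param provinces a [polygon_set()] whose polygons carry integer ids.
#' @return Integer vector of province ids (`NA` = outside all provinces).
#' @export
locate_province <- function(lon, lat, provinces) {
  stopifnot(inherits(provinces, "polygon_set"))
  polys <- provinces$polygons
  ord <- order(vapply(polys, function(p) as.integer(p$id), integer(1)),
               na.last = TRUE)
  out <- rep(NA_integer_, length(lon))
  for (p in polys[ord]) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    bb <- p$bbox
    cand <- todo[lon[todo] >= bb[1] & lon[todo] <= bb[3] &
                 lat[todo] >= bb[2] & lat[todo] <= bb[4]]
    if (!length(cand)) next
    hit <- point_in_polygon(lon[cand], lat[cand], p$rings)
    out[cand[hit]] <- p$id
  }
  out
}
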