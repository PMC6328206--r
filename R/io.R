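#' Read an Argos fix table from CSV
#'
#' Expects columns `ptt`, `timestamp` (ISO-8601 UTC), `lc`, `lon`, `lat`.
#' Malformed rows (unknown location class, unparseable timestamp,
#' out-of-range coordinates) are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return validated data frame of fixes.
#' @export
read_argos_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ptt = "character", lc = "character"))
  req <- c("ptt", "timestamp", "lc", "lon", "lat")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- which(is.na(ts) & !is.na(df$timestamp))
  if (length(bad))
    stop("unparseable timestamp in ", path, ", row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df$timestamp <- ts
  validate_fixes(df)
  df[, req]
}

#' Write an Argos fix table to CSV
#'
#' Timestamps are written as ISO-8601 UTC with microseconds and coordinates
#' at full double precision, so `read_argos_csv(write_argos_csv(x))`
#' round-trips.
#'
#' @param fixes data frame of fixes.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_argos_csv <- function(fixes, path) {
  df <- data.frame(
    ptt = as.character(fixes$ptt),
    timestamp = strftime(fixes$timestamp, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC"),
    lc = as.character(fixes$lc),
    lon = sprintf("%.17g", fixes$lon),
    lat = sprintf("%.17g", fixes$lat),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landmask from GeoJSON
#'
#' Accepts a FeatureCollection (or bare geometry) of Polygons and
#' MultiPolygons in WGS84 lon/lat axis order. The first ring of each polygon
#' is the outer boundary; subsequent rings are holes.
#'
#' @param path GeoJSON file path.
#' @return a `landmask` object.
#' @export
read_landmask <- function(path) {
  g <- jsonlite::read_json(path)
  geoms <- list()
  push_geom <- function(geom) {
    if (geom$type == "Polygon") {
      geoms[[length(geoms) + 1]] <<- geom$coordinates
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) geoms[[length(geoms) + 1]] <<- poly
    } else stop("unsupported geometry type: ", geom$type)
  }
  if (!is.null(g$type) && g$type == "FeatureCollection") {
    for (f in g$features) push_geom(f$geometry)
  } else if (!is.null(g$type) && g$type == "Feature") {
    push_geom(g$geometry)
  } else if (!is.null(g$type)) {
    push_geom(g)
  } else stop("not a GeoJSON object: ", path)
  polys <- lapply(geoms, function(rings) {
    mats <- lapply(rings, function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
    list(outer = mats[[1]], holes = mats[-1])
  })
  structure(polys, class = "landmask")
}

#' Write a landmask to GeoJSON
#'
#' @param landmask a `landmask` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmask <- function(landmask, path) {
  stopifnot(inherits(landmask, "landmask"))
  feat <- lapply(landmask, function(p) {
    rings <- c(list(p$outer), p$holes)
    coords <- lapply(rings, function(r) {
      if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write classified daily locations to GeoJSON
#'
#' Point features with per-point `date`, `label` and `season` properties,
#' ready for any GIS.
#'
#' @param steps a [daily_steps()] data frame (end positions are written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locations_geojson <- function(steps, path) {
  feat <- lapply(seq_len(nrow(steps)), function(i) {
    list(type = "Feature",
         properties = list(date = format(as.Date(steps$date[i], tz = "UTC")),
                           label = steps$label[i], season = steps$season[i]),
         geometry = list(type = "Point",
                         coordinates = c(steps$lon1[i], steps$lat1[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Published tracking-log summary of the 2001 Gulf of California deployment
#'
#' Per-tag tracking summary for the eleven Argos tags deployed on fin whales
#' in the Gulf of California in 2001: transmission dates, tracking days,
#' filtered location counts, locations per day, and the fitted model's
#' deviance and DIC (NA for the two tags excluded for lack of data). Used as
#' a worked-example input for the quality-control arithmetic.
#'
#' @return data frame with one row per tag.
#' @export
goc_track_log <- function() {
  path <- system.file("extdata", "goc_track_log.csv", package = "dcrws",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ptt = "character"))
}

#' Published per-track movement statistics of the 2001 deployment
#'
#' Daily distance and speed statistics for the eight fin whale tracks
#' retained in the 2001 Gulf of California analysis, in the schema of
#' [per_track_summary()]. Used as a worked-example input for the cohort
#' aggregation arithmetic.
#'
#' @return data frame with one row per track.
#' @export
goc_step_stats <- function() {
  path <- system.file("extdata", "goc_step_stats.csv", package = "dcrws",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ptt = "character"))
}
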