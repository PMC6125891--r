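# Minimal planar GeoJSON serialization for road networks and polygon sets.
# Coordinates are written as-is (planar km); the CRS string is recorded in a
# foreign member and not transformed.

#' Write and read roads / polygons as GeoJSON
#'
#' @param net A `road_network` (list of vertex matrices).
#' @param polys A `polygon_set`.
#' @param path File path.
#' @return Readers return the corresponding object.
#' @export
write_geojson_roads <- function(net, path) {
  feats <- lapply(seq_along(net$lines), function(i) {
    v <- net$lines[[i]]
    list(type = "Feature",
         properties = list(id = i),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(v)),
                                              function(r) unname(v[r, ]))))
  })
  obj <- list(type = "FeatureCollection", crs_name = net$crs, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_roads
#' @export
read_geojson_roads <- function(path) {
  obj <- jsonlite::read_json(path)
  lines <- lapply(obj$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates, function(p)
      c(x = p[[1]], y = p[[2]])))
    m
  })
  structure(list(lines = lines,
                 crs = if (!is.null(obj$crs_name)) obj$crs_name else "unknown"),
            class = "road_network")
}

#' @rdname write_geojson_roads
#' @export
write_geojson_polygons <- function(polys, path) {
  feats <- lapply(polys$polygons, function(p) {
    list(type = "Feature",
         properties = list(id = p$id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p$coords)),
                                                   function(r) unname(p$coords[r, ])))))
  })
  obj <- list(type = "FeatureCollection", crs_name = polys$crs, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_roads
#' @export
read_geojson_polygons <- function(path) {
  obj <- jsonlite::read_json(path)
  polys <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(x = p[[1]], y = p[[2]])))
    list(id = f$properties$id, coords = m)
  })
  structure(list(polygons = polys,
                 crs = if (!is.null(obj$crs_name)) obj$crs_name else "unknown"),
            class = "polygon_set")
}

#' Write and read occurrence points as CSV (`period,x,y`)
#'
#' @param occ Data frame with columns `period, x, y`.
#' @param path File path.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(occ[, c("period", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  utils::read.csv(path, colClasses = c(period = "character"))
}
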