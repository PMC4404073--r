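#' Minimal GeoJSON interchange for planar features
#'
#' Point, polygon and polyline layers round-trip through GeoJSON
#' FeatureCollections. Coordinates are taken verbatim: they must already
#' be in a projected planar system in metres (the package refuses
#' coordinate sets that all look like lon/lat degrees unless
#' `allow_degrees = TRUE`).
#'
#' @param path GeoJSON file path.
#' @param allow_degrees Accept coordinates within lon/lat bounds.
#' @return `read_geojson_points()`: a tibble with `x_m`, `y_m` and one
#'   column per feature property. `read_geojson_polygons()`: a list of
#'   polygons, each a list with `rings` (list of two-column matrices,
#'   first ring the shell, the rest holes) and `properties` (named list).
#'   `read_geojson_lines()`: a list of two-column coordinate matrices
#'   with a `properties` attribute each.
#' @name geojson
NULL

geojson_read_raw <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(g$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  }
  g$features
}

coord_guard <- function(x, y, allow_degrees) {
  if (!allow_degrees && length(x) > 0 && looks_like_degrees(x, y)) {
    stop("coordinates look like lon/lat degrees; project to planar metres ",
         "first (or pass allow_degrees = TRUE)", call. = FALSE)
  }
}

#' @rdname geojson
#' @export
read_geojson_points <- function(path, allow_degrees = FALSE) {
  feats <- geojson_read_raw(path)
  feats <- purrr::keep(feats, ~ identical(.x$geometry$type, "Point"))
  if (length(feats) == 0) {
    return(tibble::tibble(x_m = numeric(), y_m = numeric()))
  }
  xy <- purrr::map(feats, ~ as.numeric(unlist(.x$geometry$coordinates)))
  props <- purrr::map(feats, ~ .x$properties %||% list())
  keys <- unique(unlist(purrr::map(props, names)))
  out <- tibble::tibble(
    x_m = purrr::map_dbl(xy, 1),
    y_m = purrr::map_dbl(xy, 2)
  )
  for (k in keys) {
    out[[k]] <- purrr::map_vec(props, ~ .x[[k]] %||% NA)
  }
  coord_guard(out$x_m, out$y_m, allow_degrees)
  out
}

#' @rdname geojson
#' @param points Tibble with `x_m`, `y_m` and optional property columns.
#' @export
write_geojson_points <- function(points, path) {
  props <- setdiff(names(points), c("x_m", "y_m"))
  feats <- purrr::map(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x_m[i], points$y_m[i])),
      properties = as.list(points[i, props, drop = FALSE])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

ring_to_matrix <- function(ring) {
  m <- do.call(rbind, purrr::map(ring, ~ as.numeric(unlist(.x))[1:2]))
  colnames(m) <- c("x_m", "y_m")
  m
}

#' @rdname geojson
#' @export
read_geojson_polygons <- function(path, allow_degrees = FALSE) {
  feats <- geojson_read_raw(path)
  feats <- purrr::keep(
    feats, ~ .x$geometry$type %in% c("Polygon", "MultiPolygon"))
  out <- purrr::map(feats, function(f) {
    gt <- f$geometry$type
    rings <- switch(
      gt,
      Polygon = purrr::map(f$geometry$coordinates, ring_to_matrix),
      MultiPolygon = purrr::flatten(
        purrr::map(f$geometry$coordinates,
                   function(poly) purrr::map(poly, ring_to_matrix)))
    )
    list(rings = rings, properties = f$properties %||% list())
  })
  allx <- unlist(purrr::map(out, ~ purrr::map(.x$rings, ~ .x[, 1])))
  ally <- unlist(purrr::map(out, ~ purrr::map(.x$rings, ~ .x[, 2])))
  coord_guard(allx, ally, allow_degrees)
  out
}

#' @rdname geojson
#' @export
read_geojson_lines <- function(path, allow_degrees = FALSE) {
  feats <- geojson_read_raw(path)
  feats <- purrr::keep(
    feats, ~ .x$geometry$type %in% c("LineString", "MultiLineString"))
  out <- purrr::map(feats, function(f) {
    gt <- f$geometry$type
    coords <- switch(
      gt,
      LineString = list(ring_to_matrix(f$geometry$coordinates)),
      MultiLineString = purrr::map(f$geometry$coordinates, ring_to_matrix)
    )
    purrr::map(coords, ~ structure(.x, properties = f$properties %||% list()))
  })
  out <- purrr::flatten(out)
  allx <- unlist(purrr::map(out, ~ .x[, 1]))
  ally <- unlist(purrr::map(out, ~ .x[, 2]))
  coord_guard(allx, ally, allow_degrees)
  out
}

# Point-in-polygon with holes: inside the shell and in no hole.
# `polygon` is a list of rings as returned by read_geojson_polygons.
points_in_polygon <- function(x, y, rings) {
  pts <- cbind(x, y)
  inside <- mgcv::in.out(rings[[1]], pts)
  if (length(rings) > 1) {
    for (h in rings[-1]) {
      inside <- inside & !mgcv::in.out(h, pts)
    }
  }
  inside
}
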