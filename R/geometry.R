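# Distance from points to each segment (p1 -> p2): project onto the segment,
# clamp the projection parameter to [0, 1], take the Euclidean residual.
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

as_polylines <- function(lines) {
  if (is.matrix(lines) || is.data.frame(lines)) lines <- list(as.matrix(lines))
  if (!is.list(lines) || length(lines) == 0) {
    abort("`lines` must be a non-empty polyline set (list of coordinate matrices).")
  }
  lapply(lines, function(l) {
    l <- as.matrix(l)
    if (ncol(l) < 2 || nrow(l) < 2) abort("Each polyline needs >= 2 xy vertices.")
    l[, 1:2, drop = FALSE]
  })
}

#' Minimum distance from sites to a polyline network
#'
#' Planar point-to-segment distance, minimised over every segment of every
#' polyline. Coordinates must be projected (metres); geographic
#' degree coordinates are rejected because planar distances on them are
#' meaningless -- project the data first.
#'
#' @param sites A data frame with `x`, `y` columns (projected metres), or a
#'   length-2 numeric vector for a single point.
#' @param lines A polyline set: a list of two-column coordinate matrices (or
#'   a single matrix), e.g. from [read_geojson_lines()].
#' @param crs_units `"m"` or `"deg"`; overridden by a `crs_units` attribute
#'   on `lines` if present.
#' @return Numeric vector of distances (m), one per site.
#' @export
#' @examples
#' distance_to_line(c(3, 4), rbind(c(0, 0), c(10, 0)))  # 4
distance_to_line <- function(sites, lines, crs_units = NULL) {
  crs_units <- attr(lines, "crs_units") %||% crs_units %||% "m"
  if (identical(crs_units, "deg")) {
    abort("Coordinates are geographic (degrees); project to a metre CRS first.")
  }
  if (is.numeric(sites) && is.null(dim(sites))) {
    sites <- tibble(x = sites[1], y = sites[2])
  }
  stopifnot(all(c("x", "y") %in% names(sites)))
  polys <- as_polylines(lines)
  vapply(seq_len(nrow(sites)), function(i) {
    best <- Inf
    for (l in polys) {
      for (s in seq_len(nrow(l) - 1)) {
        d <- point_segment_distance(sites$x[i], sites$y[i],
                                    l[s, 1], l[s, 2], l[s + 1, 1], l[s + 1, 2])
        if (d < best) best <- d
      }
    }
    best
  }, numeric(1))
}

#' Read and write polyline networks as GeoJSON
#'
#' Serialises a list of polylines as a GeoJSON FeatureCollection of
#' LineStrings. A non-standard `crs_units` member records whether the
#' coordinates are projected metres (`"m"`) or geographic degrees (`"deg"`);
#' distance computations require metres.
#'
#' @param lines List of two-column coordinate matrices.
#' @param path File path.
#' @param crs_units `"m"` or `"deg"`.
#' @return `read_geojson_lines()` returns the polyline list with a
#'   `crs_units` attribute; `write_geojson_lines()` returns `path` invisibly.
#' @export
write_geojson_lines <- function(lines, path, crs_units = "m") {
  polys <- as_polylines(lines)
  features <- lapply(polys, function(l) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(l)),
                                              function(i) unname(l[i, ]))))
  })
  obj <- list(type = "FeatureCollection", crs_units = crs_units,
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_lines
#' @export
read_geojson_lines <- function(path) {
  obj <- jsonlite::read_json(path)
  lines <- lapply(obj$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates, function(xy) {
      c(as.numeric(xy[[1]]), as.numeric(xy[[2]]))
    }))
  })
  attr(lines, "crs_units") <- obj$crs_units %||% "deg"
  lines
}
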