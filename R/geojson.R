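# Minimal GeoJSON interchange for the vector artifacts the pipeline
# produces: road / least-cost-path polylines and fragment cell-union
# polygons. Coordinates are planar km (the CRS is a local planar frame).

#' Write polylines to GeoJSON
#'
#' @param lines list of two-column matrices (x, y vertices in km).
#' @param path output file.
#' @param properties optional data.frame of per-feature properties.
#' @export
write_lines_geojson <- function(lines, path, properties = NULL) {
  feats <- lapply(seq_along(lines), function(i) {
    props <- if (is.null(properties)) {
      list(id = i)
    } else as.list(properties[i, , drop = FALSE])
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "LineString",
                      coordinates = unname(apply(lines[[i]], 1L, c,
                                                 simplify = FALSE)))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read LineString features from GeoJSON
#'
#' @param path GeoJSON file with `LineString` features.
#' @return list of two-column coordinate matrices.
#' @export
read_lines_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "LineString")) {
      stop("expected LineString geometries", call. = FALSE)
    }
    do.call(rbind, lapply(f$geometry$coordinates, function(p) {
      c(x = as.numeric(p[[1L]]), y = as.numeric(p[[2L]]))
    }))
  })
}

# Fragments as MultiPolygons of their constituent cell squares. Adequate for
# the toy scales the package works at; no polygon dissolving is attempted.
fragment_feature <- function(frag, r, extra = list()) {
  nr <- nrow(r$values); cs <- r$cell_km
  polys <- apply(frag$cells, 1L, function(rc) {
    x0 <- r$xmin + (rc[2L] - 1L) * cs
    y0 <- r$ymin + (nr - rc[1L]) * cs
    list(list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
              c(x0, y0 + cs), c(x0, y0)))
  }, simplify = FALSE)
  list(type = "Feature",
       properties = c(list(id = frag$id, area_km2 = frag$area_km2,
                           good_area_km2 = frag$good_area_km2), extra),
       geometry = list(type = "MultiPolygon", coordinates = unname(polys)))
}

#' Write habitat fragments (with optional labels) to GeoJSON
#'
#' @param fragments list of fragments from [extract_fragments()].
#' @param r the raster the fragments were derived from.
#' @param path output file.
#' @param labels optional data.frame from [classify_occupancy()].
#' @export
write_fragments_geojson <- function(fragments, r, path, labels = NULL) {
  feats <- lapply(fragments, function(fr) {
    extra <- list()
    if (!is.null(labels)) {
      extra$label <- labels$label[match(fr$id, labels$fragment_id)]
    }
    fragment_feature(fr, r, extra)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
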