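#' Georeferenced suitability grid
#'
#' Lightweight in-memory raster used throughout the pipeline. Values are a
#' numeric matrix whose first row is the northernmost row (ESRI ASCII grid
#' convention); coordinates are planar kilometres. `NA` encodes NoData.
#'
#' @param values numeric matrix, non-`NA` entries in `[0, 1]` unless
#'   `check_range = FALSE` (used internally for resistance/cost grids).
#' @param cell_km cell size in km (> 0).
#' @param xmin,ymin coordinates of the lower-left corner of the grid (km).
#' @param check_range enforce the `[0, 1]` suitability contract.
#' @return an object of class `suit_raster`.
#' @export
suit_raster <- function(values, cell_km, xmin = 0, ymin = 0,
                        check_range = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0) {
    stop("`cell_km` must be a single positive number", call. = FALSE)
  }
  v <- values[!is.na(values)]
  if (check_range && length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(values = values, cell_km = as.numeric(cell_km),
         xmin = as.numeric(xmin), ymin = as.numeric(ymin)),
    class = "suit_raster"
  )
}

#' @export
print.suit_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<suit_raster> %d x %d cells of %.3g km (%.5g .. %.5g)\n",
              nrow(x$values), ncol(x$values), x$cell_km,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
dim.suit_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + ncol(r$values) * r$cell_km,
    ymin = r$ymin, ymax = r$ymin + nrow(r$values) * r$cell_km)
}

cell_area_km2 <- function(r) r$cell_km^2

#' Total non-NoData area of a raster (km^2)
#' @param r a [suit_raster()].
#' @export
raster_area_km2 <- function(r) sum(!is.na(r$values)) * cell_area_km2(r)

# Matrix (row, col) of the cell containing planar point(s); points on the
# top/right boundary are clamped into the last cell.
cell_at_xy <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xmin) / r$cell_km) + 1L
  row <- nr - floor((y - r$ymin) / r$cell_km)
  col[x == r$xmin + nc * r$cell_km] <- nc
  row[y == r$ymin + nr * r$cell_km] <- 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Cell-centre coordinates of (row, col) index pairs.
cell_centers <- function(r, rc) {
  nr <- nrow(r$values)
  cbind(x = r$xmin + (rc[, 2L] - 0.5) * r$cell_km,
        y = r$ymin + (nr - rc[, 1L] + 0.5) * r$cell_km)
}

#' Raster values at planar points
#'
#' @param r a [suit_raster()].
#' @param x,y point coordinates (km). Points outside the raster extent
#'   return `NA` unless `strict = TRUE`, in which case they are an error.
#' @param strict error (listing offenders) on points off the raster.
#' @export
extract_values <- function(r, x, y, strict = FALSE) {
  rc <- cell_at_xy(r, x, y)
  if (strict && anyNA(rc[, 1L])) {
    off <- which(is.na(rc[, 1L]))
    stop(sprintf("records outside raster extent at rows: %s",
                 paste(off, collapse = ", ")), call. = FALSE)
  }
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1L])
  out[ok] <- r$values[cbind(rc[ok, 1L], rc[ok, 2L])]
  out
}

#' Read / write ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format (`.asc`). Written with
#' full double precision so that a write/read round trip is lossless.
#'
#' @param path file path.
#' @param check_range enforce the `[0, 1]` contract on read.
#' @return `read_ascii_grid()` returns a [suit_raster()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, check_range = TRUE) {
  lines <- readLines(path, n = 6L)
  hdr <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(body) != nr * nc) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  suit_raster(m, cell_km = vals[["cellsize"]],
              xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
              check_range = check_range)
}

#' @rdname read_ascii_grid
#' @param r a [suit_raster()] to write.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "suit_raster"))
  m <- r$values
  m[is.na(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(m)), sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", r$xmin), sprintf("YLLCORNER %.10g", r$ymin),
    sprintf("CELLSIZE %.10g", r$cell_km), "NODATA_VALUE -9999"
  ), con)
  writeLines(apply(m, 1L, function(row) {
    paste(formatC(row, format = "g", digits = 17), collapse = " ")
  }), con)
  invisible(path)
}
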