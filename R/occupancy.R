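# Habitat fragments and occupancy labelling. Suitable cells of the class
# map are split by rasterized roads, grouped into 4-connected components,
# and each fragment is labelled occupied (AJO), potentially occupied (APJO)
# or empty using the median-outside-distance rule.

# Cells of the grid intersected by a polyline. Each segment is traversed by
# dense sampling at quarter-cell steps; robust on sliver geometries, which
# is why vector-difference splitting was rejected.
rasterize_polyline <- function(line, nr, nc, cell_km, xmin, ymin) {
  hits <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(nrow(line) - 1L)) {
    a <- line[i, ]; b <- line[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len / (cell_km / 4)) + 1L)
    t <- seq(0, 1, length.out = n)
    x <- a[1L] + t * (b[1L] - a[1L]); y <- a[2L] + t * (b[2L] - a[2L])
    col <- pmin(pmax(floor((x - xmin) / cell_km) + 1L, 1L), nc)
    row <- pmin(pmax(nr - floor((y - ymin) / cell_km), 1L), nr)
    inside <- x >= xmin & x <= xmin + nc * cell_km &
      y >= ymin & y <= ymin + nr * cell_km
    hits <- rbind(hits, cbind(row, col)[inside, , drop = FALSE])
  }
  unique(hits)
}

# 4-connected component labelling by iterative flood fill.
label_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
              if (c > 1L) cur - nr, if (c < nc) cur + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      stack <- c(stack, nb)
    }
  }
  lab
}

fragment_size_class <- function(area) {
  cut(area, c(-Inf, 100, 1000, Inf),
      labels = c("<100", "100-1000", ">1000"), right = FALSE)
}

#' Extract habitat fragments from a class map
#'
#' Suitable cells (class `marginal` and up) intersected by a road polyline
#' become barriers; the remaining suitable cells are grouped into
#' 4-connected components. 4-connectivity is deliberate: 8-connectivity
#' would leak across diagonal road crossings.
#'
#' @param class_map a [reclassify()] map.
#' @param roads list of polyline vertex matrices (km), possibly empty.
#' @return list of fragments, each a list `id`, `cells` (row/col matrix),
#'   `area_km2`, `good_area_km2` (medium + high cells), `size_class`,
#'   plus the shared `cell_km`/origin for geometry work. Empty suitable
#'   mask yields an empty list.
#' @export
extract_fragments <- function(class_map, roads = list()) {
  stopifnot(inherits(class_map, "suit_class_map"))
  cls <- class_map$classes
  mask <- !is.na(cls) & cls >= 1L
  nr <- nrow(cls); nc <- ncol(cls)
  for (line in roads) {
    rc <- rasterize_polyline(line, nr, nc, class_map$cell_km,
                             class_map$xmin, class_map$ymin)
    if (nrow(rc)) mask[rc] <- FALSE
  }
  lab <- label_components4(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  a <- class_map$cell_km^2
  lapply(seq_len(n), function(i) {
    cells <- which(lab == i, arr.ind = TRUE)
    colnames(cells) <- c("row", "col")
    area <- nrow(cells) * a
    good <- sum(cls[cells] >= 2L) * a
    list(id = i, cells = cells, area_km2 = area, good_area_km2 = good,
         size_class = as.character(fragment_size_class(area)),
         cell_km = class_map$cell_km,
         xmin = class_map$xmin, ymin = class_map$ymin,
         nrow = nr)
  })
}

# Distance from point(s) to the closest cell square of a fragment (0 if
# inside). Cell (r, c) spans [xmin+(c-1)s, xmin+cs] x [ymin+(nr-r)s, ...].
point_fragment_distance <- function(frag, x, y) {
  s <- frag$cell_km
  x0 <- frag$xmin + (frag$cells[, "col"] - 1L) * s
  y0 <- frag$ymin + (frag$nrow - frag$cells[, "row"]) * s
  vapply(seq_along(x), function(i) {
    dx <- pmax(x0 - x[i], x[i] - (x0 + s), 0)
    dy <- pmax(y0 - y[i], y[i] - (y0 + s), 0)
    sqrt(min(dx^2 + dy^2))
  }, 0)
}

# Minimum boundary-to-boundary distance between two fragments (0 if the
# cell unions touch or overlap).
fragment_distance <- function(fa, fb) {
  s <- fa$cell_km
  ax0 <- fa$xmin + (fa$cells[, "col"] - 1L) * s
  ay0 <- fa$ymin + (fa$nrow - fa$cells[, "row"]) * s
  bx0 <- fb$xmin + (fb$cells[, "col"] - 1L) * s
  by0 <- fb$ymin + (fb$nrow - fb$cells[, "row"]) * s
  best <- Inf
  for (i in seq_along(ax0)) {
    dx <- pmax(bx0 - (ax0[i] + s), ax0[i] - (bx0 + s), 0)
    dy <- pmax(by0 - (ay0[i] + s), ay0[i] - (by0 + s), 0)
    best <- min(best, min(dx^2 + dy^2))
    if (best == 0) return(0)
  }
  sqrt(best)
}

#' Median distance of outside records to the nearest fragment
#'
#' Records lying inside any fragment are excluded; the median Euclidean
#' distance from the remaining records to their closest fragment boundary
#' is returned. This is the radius used to call near-fragment records
#' "occupancy" evidence.
#'
#' @param records data.frame with `x_km`, `y_km`.
#' @param fragments list from [extract_fragments()].
#' @return median distance (km).
#' @export
median_outside_distance <- function(records, fragments) {
  if (!length(fragments)) stop("no fragments supplied", call. = FALSE)
  dmat <- matrix(vapply(fragments, point_fragment_distance,
                        numeric(nrow(records)),
                        x = records$x_km, y = records$y_km),
                 nrow = nrow(records))
  d <- apply(dmat, 1L, min)
  outside <- d[d > 0]
  if (!length(outside)) {
    stop(paste("no records fall outside the fragments;",
               "supply the occupancy radius explicitly"), call. = FALSE)
  }
  median(outside)
}

#' Classify fragments as AJO / APJO / empty
#'
#' A fragment is AJO when a record lies inside it or strictly closer than
#' `radius_km` to its boundary; a record-free fragment is APJO when it lies
#' strictly closer than `radius_km` to an AJO fragment. APJO status is
#' determined after all AJO labels are fixed and does not chain.
#'
#' @param fragments list from [extract_fragments()].
#' @param records data.frame with `x_km`, `y_km`.
#' @param radius_km occupancy radius (km), >= 0. At radius 0 the rule
#'   reduces to containment and the APJO set is empty.
#' @return data.frame `fragment_id`, `label`, `supporting_records`
#'   (comma-separated record row indices for AJO fragments).
#' @export
classify_occupancy <- function(fragments, records, radius_km = 1.7) {
  if (radius_km < 0) stop("radius_km must be >= 0", call. = FALSE)
  n <- length(fragments)
  if (n == 0L) {
    return(data.frame(fragment_id = integer(0), label = character(0),
                      supporting_records = character(0)))
  }
  dmat <- vapply(fragments, point_fragment_distance,
                 numeric(nrow(records)),
                 x = records$x_km, y = records$y_km)
  dmat <- matrix(dmat, nrow = nrow(records))
  ajo <- logical(n); support <- character(n)
  for (i in seq_len(n)) {
    hit <- which(dmat[, i] == 0 | dmat[, i] < radius_km)
    ajo[i] <- length(hit) > 0
    support[i] <- paste(hit, collapse = ",")
  }
  label <- ifelse(ajo, "AJO", "empty")
  if (any(ajo) && any(!ajo) && radius_km > 0) {
    for (i in which(!ajo)) {
      dd <- vapply(which(ajo), function(j) {
        fragment_distance(fragments[[i]], fragments[[j]])
      }, 0)
      if (any(dd < radius_km)) label[i] <- "APJO"
    }
  }
  data.frame(fragment_id = vapply(fragments, `[[`, 0L, "id"),
             label = label, supporting_records = support,
             stringsAsFactors = FALSE)
}

#' Occupancy summary by fragment size class
#'
#' @param fragments list from [extract_fragments()].
#' @param labels data.frame from [classify_occupancy()].
#' @return data.frame of counts and areas per size class and label;
#'   totals conserve fragment count and area.
#' @export
occupancy_summary <- function(fragments, labels) {
  if (length(fragments) != nrow(labels)) {
    stop("labels must cover all fragments", call. = FALSE)
  }
  df <- data.frame(
    size_class = vapply(fragments, `[[`, "", "size_class"),
    area = vapply(fragments, `[[`, 0, "area_km2"),
    label = labels$label[match(vapply(fragments, `[[`, 0L, "id"),
                               labels$fragment_id)]
  )
  out <- expand.grid(size_class = c("<100", "100-1000", ">1000"),
                     label = c("AJO", "APJO", "empty"),
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(sc, lb) sum(df$size_class == sc & df$label == lb),
                  out$size_class, out$label)
  out$area_km2 <- mapply(function(sc, lb) {
    sum(df$area[df$size_class == sc & df$label == lb])
  }, out$size_class, out$label)
  out
}

#' Occupancy ratios relative to total suitable habitat
#'
#' Given per-class suitable areas and the AJO/APJO totals, computes the
#' shares of suitable habitat that are occupied, potentially occupied, and
#' without records (each rounded to 1 decimal, in percent).
#'
#' @param class_areas_km2 named vector with at least `marginal`, `medium`,
#'   `high` areas (km^2), or a single total suitable area.
#' @param ajo_km2,apjo_km2 occupied / potentially occupied areas (km^2).
#' @return list `suitable_km2`, `empty_km2`, `pct_ajo`, `pct_apjo`,
#'   `pct_empty`.
#' @export
occupancy_ratios <- function(class_areas_km2, ajo_km2, apjo_km2) {
  suitable <- if (length(class_areas_km2) == 1L) {
    as.numeric(class_areas_km2)
  } else {
    sum(class_areas_km2[c("marginal", "medium", "high")])
  }
  if (!is.finite(suitable) || suitable <= 0) {
    stop("total suitable area must be positive", call. = FALSE)
  }
  empty <- suitable - ajo_km2 - apjo_km2
  list(suitable_km2 = suitable, empty_km2 = empty,
       pct_ajo = round(100 * ajo_km2 / suitable, 1),
       pct_apjo = round(100 * apjo_km2 / suitable, 1),
       pct_empty = round(100 * empty / suitable, 1))
}
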