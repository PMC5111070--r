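# Least-cost connectivity: resistance as the inverse of suitability,
# accumulated-cost grids from source polygons, and pairwise least-cost
# linkages between conservation units on the 8-neighbour cell graph.

#' Resistance surface from suitability
#'
#' Linear inverse mapping \code{r = 1 + (1 - s) (r_max - 1)} (best habitat
#' has unit cost, unsuitable habitat `r_max`); NoData becomes `r_max`. Set
#' `form = "reciprocal"` for \code{r = min(1 / s, r_max)}.
#'
#' @param raster a [suit_raster()].
#' @param r_max cost at suitability 0 (>= 1), default 100.
#' @param form `"linear"` (default) or `"reciprocal"`.
#' @return a `resistance_surface` (same grid frame, values in
#'   `[1, r_max]`).
#' @export
resistance_from_suitability <- function(raster, r_max = 100,
                                        form = c("linear", "reciprocal")) {
  stopifnot(inherits(raster, "suit_raster"))
  form <- match.arg(form)
  if (r_max < 1) stop("r_max must be >= 1", call. = FALSE)
  s <- raster$values
  r <- switch(form,
              linear = 1 + (1 - s) * (r_max - 1),
              reciprocal = pmin(1 / pmax(s, 1 / r_max), r_max))
  r[is.na(r)] <- r_max
  structure(list(values = r, cell_km = raster$cell_km,
                 xmin = raster$xmin, ymin = raster$ymin, r_max = r_max),
            class = "resistance_surface")
}

# 8-neighbour grid graph; edge weight = mean of endpoint resistances x
# cell size (x sqrt(2) on diagonals). Vertex id = cell index in R's
# column-major order.
resistance_graph <- function(surface) {
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  cs <- surface$cell_km
  e_from <- e_to <- integer(0); e_w <- numeric(0)
  add <- function(a, b, mult) {
    e_from <<- c(e_from, a); e_to <<- c(e_to, b)
    e_w <<- c(e_w, (v[a] + v[b]) / 2 * cs * mult)
  }
  add(as.vector(idx[-nr, ]), as.vector(idx[-1L, ]), 1)        # vertical
  add(as.vector(idx[, -nc]), as.vector(idx[, -1L]), 1)        # horizontal
  add(as.vector(idx[-nr, -nc]), as.vector(idx[-1L, -1L]), sqrt(2))
  add(as.vector(idx[-1L, -nc]), as.vector(idx[-nr, -1L]), sqrt(2))
  g <- igraph::make_graph(rbind(e_from, e_to), n = nr * nc,
                          directed = FALSE)
  igraph::E(g)$weight <- e_w
  g
}

#' Accumulated cost-distance grid from source cells
#'
#' Dijkstra's algorithm over the 8-neighbour cell graph; source cells have
#' cost 0. Doubling all resistances doubles all accumulated costs.
#'
#' @param surface a [resistance_from_suitability()] surface.
#' @param source logical matrix (same dimensions) or a two-column
#'   row/col matrix of source cells.
#' @return matrix of accumulated least costs (cost-km units).
#' @export
cost_distance <- function(surface, source) {
  stopifnot(inherits(surface, "resistance_surface"))
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  src <- if (is.logical(source)) which(source) else {
    if (any(source[, 1L] < 1L | source[, 1L] > nr |
            source[, 2L] < 1L | source[, 2L] > nc)) {
      stop("source cells outside the grid", call. = FALSE)
    }
    (source[, 2L] - 1L) * nr + source[, 1L]
  }
  src <- unique(as.integer(src))
  if (!length(src) || any(src < 1L | src > nr * nc)) {
    stop("source cells outside the grid", call. = FALSE)
  }
  g <- resistance_graph(surface)
  d <- igraph::distances(g, v = src, algorithm = "dijkstra")
  matrix(apply(d, 2L, min), nr, nc)
}

# Do two cell sets share a cell or border each other (8-adjacency)?
units_touch <- function(a, b) {
  for (i in seq_len(nrow(a))) {
    if (any(abs(b[, 1L] - a[i, 1L]) <= 1L &
            abs(b[, 2L] - a[i, 2L]) <= 1L)) return(TRUE)
  }
  FALSE
}

#' Pairwise least-cost linkages between units
#'
#' For every pair of units (given as cell sets on the surface grid), the
#' least accumulated cost between any pair of member cells, plus one
#' representative least-cost path polyline. Touching or overlapping units
#' have cost 0. Unreachable pairs get cost `Inf` and no path.
#'
#' @param surface a resistance surface.
#' @param units named list; each element a two-column row/col matrix of
#'   the unit's cells.
#' @return list with `cost` (symmetric matrix, zero diagonal) and `paths`
#'   (list of two-column x/y polylines keyed `"i-j"`).
#' @export
least_cost_linkages <- function(surface, units) {
  if (length(units) < 2L) stop("need at least 2 units", call. = FALSE)
  nr <- nrow(surface$values)
  cell_of <- function(rc) as.integer((rc[, 2L] - 1L) * nr + rc[, 1L])
  ids <- lapply(units, cell_of)
  g <- resistance_graph(surface)
  n <- length(units)
  nm <- names(units) %||% as.character(seq_len(n))
  cost <- matrix(0, n, n, dimnames = list(nm, nm))
  paths <- list()
  for (i in seq_len(n - 1L)) {
    d <- igraph::distances(g, v = ids[[i]], algorithm = "dijkstra")
    for (j in seq.int(i + 1L, n)) {
      # units sharing or bordering cells touch: zero-length linkage
      if (units_touch(units[[i]], units[[j]])) {
        cost[i, j] <- cost[j, i] <- 0
        next
      }
      sub <- d[, ids[[j]], drop = FALSE]
      best <- which(sub == min(sub), arr.ind = TRUE)[1L, , drop = TRUE]
      cij <- min(sub)
      cost[i, j] <- cost[j, i] <- cij
      if (is.finite(cij)) {
        vp <- igraph::shortest_paths(
          g, from = ids[[i]][best[1L]], to = ids[[j]][best[2L]],
          algorithm = "dijkstra")$vpath[[1L]]
        cells <- as.integer(vp)
        rc <- cbind(row = (cells - 1L) %% nr + 1L,
                    col = (cells - 1L) %/% nr + 1L)
        xy <- cbind(
          x = surface$xmin + (rc[, "col"] - 0.5) * surface$cell_km,
          y = surface$ymin +
            (nr - rc[, "row"] + 0.5) * surface$cell_km)
        paths[[paste(nm[i], nm[j], sep = "-")]] <- xy
      }
    }
  }
  list(cost = cost, paths = paths)
}
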