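# Synthetic landscapes with known ground truth: a spatially autocorrelated
# suitability surface, roads that bisect habitat, and presence records
# concentrated in suitable cells. Every generator is a pure function of
# (spec, seed).

#' Specification of a synthetic landscape
#'
#' @param extent_km width/height of the square study rectangle (km).
#' @param cell_km raster resolution (km); must divide the extent evenly.
#' @param autocorrelation_range_km correlation length of the suitability
#'   field (standard deviation of the Gaussian smoothing kernel, km). Zero
#'   yields spatially independent white noise.
#' @param road_count number of edge-to-edge road polylines.
#' @param seed integer random seed.
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(extent_km = 100, cell_km = 1,
                           autocorrelation_range_km = 10,
                           road_count = 2, seed = 1) {
  if (extent_km <= 0 || cell_km <= 0) {
    stop("extent_km and cell_km must be positive", call. = FALSE)
  }
  n <- extent_km / cell_km
  if (abs(n - round(n)) > 1e-9) {
    stop("cell_km must divide extent_km evenly", call. = FALSE)
  }
  if (autocorrelation_range_km < 0) {
    stop("autocorrelation_range_km must be >= 0", call. = FALSE)
  }
  structure(list(extent_km = extent_km, cell_km = cell_km,
                 autocorrelation_range_km = autocorrelation_range_km,
                 road_count = road_count, seed = seed),
            class = "landscape_spec")
}

# Gaussian random field by FFT convolution of white noise with a Gaussian
# kernel, on a padded grid to avoid wrap-around, then min-max rescaled to
# [0, 1]. The declared range is the kernel standard deviation in km.
gaussian_field <- function(n, range_cells) {
  z <- matrix(rnorm(n * n), n, n)
  if (range_cells <= 0) return(z)
  pad <- min(3L * ceiling(range_cells), 3L * n)
  m <- n + 2L * pad
  zp <- matrix(0, m, m)
  zp[seq_len(n) + pad, seq_len(n) + pad] <- z
  d <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1))
  k <- exp(-outer(d^2, d^2, "+") / (2 * range_cells^2))
  k <- k / sum(k)
  sm <- Re(fft(fft(zp) * fft(k), inverse = TRUE)) / length(zp)
  sm[seq_len(n) + pad, seq_len(n) + pad]
}

#' Generate a synthetic landscape
#'
#' Produces a suitability raster (values in `[0, 1]`, autocorrelated at the
#' declared range) plus `road_count` low-curvature polylines crossing the
#' extent edge-to-edge. Deterministic per seed.
#'
#' @param spec a [landscape_spec()].
#' @return list with elements `raster` ([suit_raster()]) and `roads`
#'   (list of two-column vertex matrices, km).
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(spec$seed, {
    n <- as.integer(round(spec$extent_km / spec$cell_km))
    f <- gaussian_field(n, spec$autocorrelation_range_km / spec$cell_km)
    rng <- range(f)
    v <- if (diff(rng) < 1e-12) {
      matrix(0.5, n, n)
    } else (f - rng[1L]) / diff(rng)
    r <- suit_raster(v, cell_km = spec$cell_km)
    roads <- lapply(seq_len(spec$road_count), function(i) {
      generate_road(spec$extent_km)
    })
    list(raster = r, roads = roads)
  })
}

# One edge-to-edge polyline: entry and exit on opposite sides, one jittered
# midpoint for low curvature.
generate_road <- function(ext) {
  vertical <- runif(1) < 0.5
  a <- runif(1, 0, ext); b <- runif(1, 0, ext)
  mid <- c((a + b) / 2 + runif(1, -ext / 10, ext / 10), ext / 2)
  mid[1L] <- min(max(mid[1L], 0), ext)
  pts <- rbind(c(a, 0), mid, c(b, ext))
  if (!vertical) pts <- pts[, 2:1]
  colnames(pts) <- c("x", "y")
  pts
}

#' Sample presence records proportional to suitability
#'
#' Cells are drawn with probability proportional to their suitability value;
#' each point is then jittered uniformly within its cell. Emulates a
#' presence-only record set concentrated in suitable habitat.
#'
#' @param raster a [suit_raster()].
#' @param n number of records (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `x_km`, `y_km`, `date`, `source`.
#' @export
sample_presences <- function(raster, n, seed = 1) {
  stopifnot(inherits(raster, "suit_raster"))
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  empty <- data.frame(x_km = numeric(0), y_km = numeric(0),
                      date = character(0), source = character(0))
  if (n == 0) return(empty)
  w <- raster$values
  w[is.na(w)] <- 0
  if (sum(w) <= 0) {
    stop("raster has no positive suitability to sample from", call. = FALSE)
  }
  with_seed(seed, {
    idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
    rc <- cbind(row = (idx - 1L) %% nrow(w) + 1L,
                col = (idx - 1L) %/% nrow(w) + 1L)
    ctr <- cell_centers(raster, rc)
    jit <- matrix(runif(2L * n, -0.5, 0.5) * raster$cell_km, ncol = 2L)
    data.frame(x_km = ctr[, 1L] + jit[, 1L], y_km = ctr[, 2L] + jit[, 2L],
               date = rep("2020-01-01", n), source = rep("synthetic", n))
  })
}
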