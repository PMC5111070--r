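# Capture-history simulation under the half-normal SECR detection model
# with known density, the generative counterpart of the fitted model.

#' Ground-truth parameters for SECR simulation
#'
#' @param density_true individuals per 100 km^2.
#' @param p0_true baseline per-occasion detection probability at distance 0.
#' @param sigma_true half-normal detection scale (km).
#' @param n_occasions number of sampling occasions.
#' @param trap_spacing_km grid spacing of the trap array (km).
#' @export
secr_truth <- function(density_true = 1.0, p0_true = 0.1, sigma_true = 2,
                       n_occasions = 60, trap_spacing_km = 2) {
  vals <- c(density_true, p0_true, sigma_true, n_occasions, trap_spacing_km)
  if (any(vals <= 0)) stop("all truth parameters must be positive",
                           call. = FALSE)
  if (p0_true >= 1) stop("p0_true must be < 1", call. = FALSE)
  structure(list(density_true = density_true, p0_true = p0_true,
                 sigma_true = sigma_true,
                 n_occasions = as.integer(n_occasions),
                 trap_spacing_km = trap_spacing_km),
            class = "secr_truth")
}

#' Regular camera-trap grid
#'
#' @param n_side traps per side.
#' @param spacing_km spacing (km).
#' @param center centre of the array, `c(x, y)` in km.
#' @return data.frame `trap_id`, `x_km`, `y_km`.
#' @export
make_trap_grid <- function(n_side, spacing_km, center = c(0, 0)) {
  off <- (seq_len(n_side) - (n_side + 1) / 2) * spacing_km
  g <- expand.grid(x = off + center[1L], y = off + center[2L])
  data.frame(trap_id = sprintf("T%03d", seq_len(nrow(g))),
             x_km = g$x, y_km = g$y)
}

#' Camera-trap capture data
#'
#' Binary detections of identified individuals across traps and occasions.
#'
#' @param traps data.frame `trap_id`, `x_km`, `y_km`.
#' @param detections binary array `individuals x traps x occasions` (may
#'   have zero rows when nothing was detected).
#' @param individuals data.frame `individual_id`, `sex` in `{F,M,U}`,
#'   `age` in `{adult,cub}`; one row per detection-array row.
#' @export
capture_data <- function(traps, detections, individuals) {
  stopifnot(is.data.frame(traps),
            all(c("trap_id", "x_km", "y_km") %in% names(traps)))
  if (length(dim(detections)) != 3L) {
    stop("`detections` must be a 3-d array", call. = FALSE)
  }
  if (dim(detections)[2L] != nrow(traps)) {
    stop("detections/trap dimension mismatch", call. = FALSE)
  }
  if (dim(detections)[3L] < 1L) stop("need >= 1 occasion", call. = FALSE)
  if (!all(detections %in% c(0, 1))) {
    stop("detections must be binary", call. = FALSE)
  }
  n <- dim(detections)[1L]
  if (nrow(individuals) != n) {
    stop("one individuals row per detection-array row required",
         call. = FALSE)
  }
  if (n > 0 && any(apply(detections, 1L, sum) == 0)) {
    stop("every listed individual must have >= 1 detection", call. = FALSE)
  }
  if (!all(individuals$sex %in% c("F", "M", "U"))) {
    stop("sex must be one of F, M, U", call. = FALSE)
  }
  if (!all(individuals$age %in% c("adult", "cub"))) {
    stop("age must be adult or cub", call. = FALSE)
  }
  structure(list(traps = traps, detections = detections,
                 n_occasions = dim(detections)[3L],
                 individuals = individuals),
            class = "capture_data")
}

#' @export
print.capture_data <- function(x, ...) {
  cat(sprintf("<capture_data> %d individuals, %d traps, %d occasions, %d detections\n",
              dim(x$detections)[1L], nrow(x$traps), x$n_occasions,
              sum(x$detections)))
  invisible(x)
}

half_normal_p <- function(d, p0, sigma) p0 * exp(-d^2 / (2 * sigma^2))

#' Simulate SECR capture histories
#'
#' Places `N ~ Poisson(density_true * area / 100)` individuals (or exactly
#' `fixed_N` when given) with activity centres uniform on the rectangular
#' state space, then detects individual `i` at trap `j` on each occasion as
#' a Bernoulli draw with probability
#' `p0 * exp(-d_ij^2 / (2 sigma^2))`. Only detected individuals appear in
#' the output; the realized truth (N, centres) is attached as attribute
#' `"truth"` for recovery tests.
#'
#' @param truth a [secr_truth()].
#' @param state_space named vector `c(xmin, xmax, ymin, ymax)` (km).
#' @param seed integer seed.
#' @param traps optional trap data.frame; defaults to a grid built from
#'   `truth$trap_spacing_km` centred in the state space with margin
#'   `>= 3 * sigma_true` (enforced for auto-built grids only).
#' @param fixed_N exact number of individuals (disables the Poisson draw).
#' @param female_fraction probability an individual is female.
#' @return a [capture_data()].
#' @export
simulate_secr <- function(truth, state_space, seed = 1, traps = NULL,
                          fixed_N = NULL, female_fraction = 0.5) {
  stopifnot(inherits(truth, "secr_truth"))
  ss <- as.numeric(state_space)
  if (length(ss) != 4L || ss[2L] <= ss[1L] || ss[4L] <= ss[3L]) {
    stop("state_space must be c(xmin, xmax, ymin, ymax) with positive area",
         call. = FALSE)
  }
  w <- ss[2L] - ss[1L]; h <- ss[4L] - ss[3L]
  if (is.null(traps)) {
    # auto-built grids must leave a >= 3 sigma margin so that edge effects
    # on realized detection are negligible; explicitly supplied trap
    # layouts are taken as-is (degenerate designs are legitimate in tests)
    margin <- 3 * truth$sigma_true
    if (min(w, h) <= 2 * margin) {
      stop("state space too small for a trap grid with margin >= 3*sigma",
           call. = FALSE)
    }
    n_side <- max(2L, floor((min(w, h) - 2 * margin) /
                              truth$trap_spacing_km) + 1L)
    traps <- make_trap_grid(n_side, truth$trap_spacing_km,
                            center = c(mean(ss[1:2]), mean(ss[3:4])))
  }
  with_seed(seed, {
    area <- w * h
    N <- if (is.null(fixed_N)) {
      rpois(1L, truth$density_true * area / 100)
    } else as.integer(fixed_N)
    centers <- cbind(x = runif(N, ss[1L], ss[2L]),
                     y = runif(N, ss[3L], ss[4L]))
    K <- truth$n_occasions
    J <- nrow(traps)
    det <- array(0L, c(N, J, K))
    if (N > 0) {
      d2 <- outer(centers[, 1L], traps$x_km, "-")^2 +
        outer(centers[, 2L], traps$y_km, "-")^2
      p <- truth$p0_true * exp(-d2 / (2 * truth$sigma_true^2))
      for (k in seq_len(K)) {
        det[, , k] <- rbinom(N * J, 1L, p)
      }
    }
    seen <- if (N > 0) apply(det, 1L, sum) > 0 else logical(0)
    det_seen <- det[seen, , , drop = FALSE]
    n <- sum(seen)
    ind <- data.frame(
      individual_id = if (n) sprintf("J%03d", seq_len(n)) else character(0),
      sex = if (n) ifelse(runif(n) < female_fraction, "F", "M")
            else character(0),
      age = rep("adult", n)
    )
    out <- capture_data(traps, det_seen, ind)
    attr(out, "truth") <- list(N = N, centers = centers, seen = seen)
    out
  })
}

#' Write / read capture data as the two-CSV interchange format
#'
#' Traps CSV: `trap_id`, `x_km`, `y_km`. Detections CSV (long form):
#' `individual_id`, `sex`, `age`, `trap_id`, `occasion`.
#'
#' @param data a [capture_data()].
#' @param traps_path,detections_path CSV paths.
#' @export
write_capture_csv <- function(data, traps_path, detections_path) {
  stopifnot(inherits(data, "capture_data"))
  write.csv(data$traps, traps_path, row.names = FALSE)
  hit <- which(data$detections == 1L, arr.ind = TRUE)
  long <- data.frame(
    individual_id = data$individuals$individual_id[hit[, 1L]],
    sex = data$individuals$sex[hit[, 1L]],
    age = data$individuals$age[hit[, 1L]],
    trap_id = data$traps$trap_id[hit[, 2L]],
    occasion = hit[, 3L]
  )
  long <- long[order(long$individual_id, long$trap_id, long$occasion), ]
  write.csv(long, detections_path, row.names = FALSE)
  invisible(detections_path)
}

#' @rdname write_capture_csv
#' @param n_occasions total occasions (the long format only records hits).
#' @export
read_capture_csv <- function(traps_path, detections_path, n_occasions) {
  traps <- read.csv(traps_path, stringsAsFactors = FALSE)
  long <- read.csv(detections_path, stringsAsFactors = FALSE)
  bad <- setdiff(long$trap_id, traps$trap_id)
  if (length(bad)) {
    stop("detections reference unknown trap_id: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (nrow(long) && max(long$occasion) > n_occasions) {
    stop("occasion index exceeds n_occasions", call. = FALSE)
  }
  ids <- unique(long$individual_id)
  det <- array(0L, c(length(ids), nrow(traps), n_occasions))
  if (nrow(long)) {
    det[cbind(match(long$individual_id, ids),
              match(long$trap_id, traps$trap_id),
              long$occasion)] <- 1L
  }
  ind <- long[!duplicated(long$individual_id),
              c("individual_id", "sex", "age"), drop = FALSE]
  ind <- ind[match(ids, ind$individual_id), ]
  rownames(ind) <- NULL
  capture_data(traps, det, ind)
}
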