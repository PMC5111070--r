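# Post-processing and evaluation of a continuous habitat-suitability
# surface: spatial thinning of presence records, presence/background AUC,
# maximum sensitivity + specificity threshold selection, four-class
# reclassification, and omission/binomial evaluation. Model fitting itself
# is out of scope: the pipeline consumes a finished suitability raster.

#' Spatially thin presence records
#'
#' Overlays a square grid whose cells have area `cell_area_km2` (the
#' default, 144 km^2, is a female home-range-sized cell) and keeps one
#' record per occupied cell, selected uniformly at random. Reduces spatial
#' pseudo-replication of records of the same individual.
#'
#' @param records data.frame with `x_km`, `y_km`.
#' @param cell_area_km2 thinning cell area (km^2), default 144.
#' @param seed integer seed.
#' @return the retained subset of `records`.
#' @export
thin_records <- function(records, cell_area_km2 = 144, seed = 1) {
  if (cell_area_km2 <= 0) stop("cell_area_km2 must be > 0", call. = FALSE)
  if (nrow(records) == 0) return(records)
  side <- sqrt(cell_area_km2)
  key <- paste(floor(records$x_km / side), floor(records$y_km / side))
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }), use.names = FALSE)
    records[sort(keep), , drop = FALSE]
  })
}

#' Random train/test partitions
#'
#' Draws `n_replicates` independent random partitions of the records into
#' training and testing sets (default 70/30). Each record falls in exactly
#' one side of each partition. Set `bootstrap = TRUE` for the alternative
#' reading in which the training side is resampled with replacement (the
#' test side is then the out-of-bag records).
#'
#' @param records data.frame of records.
#' @param train_fraction proportion in (0, 1) assigned to training.
#' @param n_replicates number of partitions.
#' @param seed integer seed.
#' @param bootstrap resample the training side with replacement.
#' @return list of `n_replicates` lists with elements `train` and `test`.
#' @export
split_train_test <- function(records, train_fraction = 0.7,
                             n_replicates = 10, seed = 1,
                             bootstrap = FALSE) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to partition", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  n_train <- min(max(n_train, 1L), n - 1L)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      if (bootstrap) {
        ix <- sample.int(n, n_train, replace = TRUE)
        list(train = records[ix, , drop = FALSE],
             test = records[setdiff(seq_len(n), unique(ix)), , drop = FALSE])
      } else {
        ix <- sample.int(n, n_train)
        list(train = records[sort(ix), , drop = FALSE],
             test = records[setdiff(seq_len(n), ix), , drop = FALSE])
      }
    })
  })
}

#' Rank-statistic AUC for presence vs background scores
#'
#' `AUC = P(presence score > background score) + 0.5 P(tie)`, computed via
#' the Mann-Whitney rank formulation.
#'
#' @param presence_scores,background_scores non-empty numeric vectors of
#'   suitability values.
#' @return AUC in `[0, 1]`.
#' @export
auc_presence_background <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) {
    stop("presence and background score sets must be non-empty",
         call. = FALSE)
  }
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans candidate thresholds (midpoints between adjacent distinct pooled
#' scores, plus 0 and 1) and returns the one maximizing
#' `sensitivity + specificity`, where sensitivity is the fraction of
#' presences `>= t` and specificity the fraction of background `< t`.
#' Ties go to the smallest maximizing threshold.
#'
#' @inheritParams auc_presence_background
#' @return the selected threshold.
#' @export
select_threshold_max_ss <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0) {
    stop("presence and background score sets must be non-empty",
         call. = FALSE)
  }
  pooled <- sort(unique(c(presence_scores, background_scores)))
  cand <- sort(unique(c(0, 1, if (length(pooled) > 1L) {
    (pooled[-1L] + pooled[-length(pooled)]) / 2
  })))
  ss <- vapply(cand, function(t) {
    mean(presence_scores >= t) + mean(background_scores < t)
  }, 0)
  cand[which.max(ss)]  # which.max returns the first (smallest) maximizer
}

SUIT_CLASSES <- c("unsuitable", "marginal", "medium", "high")

# The canonical class bounds assume the decision threshold sits below 0.5.
# A data-driven threshold on an arbitrary surface can exceed that; fall
# back to equal-width classes over the suitable range (threshold, 1] so
# the four-class scheme stays well formed.
adapt_class_bounds <- function(threshold, bounds = c(0.5, 0.75)) {
  if (threshold < bounds[1L]) return(bounds)
  threshold + (1 - threshold) * c(1, 2) / 3
}

#' Reclassify a suitability raster into four classes
#'
#' Classes are half-open intervals `[lo, hi)` except the top class which
#' closes at 1: `unsuitable` below the decision threshold, then `marginal`,
#' `medium` (from `bounds[1]`) and `high` (from `bounds[2]`). A value equal
#' to the threshold is suitable (marginal). NoData is preserved.
#'
#' @param raster a [suit_raster()].
#' @param threshold decision threshold separating unsuitable from marginal.
#' @param bounds upper class bounds `c(medium_from, high_from)`,
#'   default `c(0.5, 0.75)`; must satisfy `threshold < bounds[1] < bounds[2]`.
#' @return a `suit_class_map`: integer grid with codes 0-3 plus the bounds.
#' @export
reclassify <- function(raster, threshold = 0.364, bounds = c(0.5, 0.75)) {
  stopifnot(inherits(raster, "suit_raster"))
  if (length(bounds) != 2L || !(threshold < bounds[1L]) ||
      !(bounds[1L] < bounds[2L]) || bounds[2L] > 1) {
    stop("need threshold < bounds[1] < bounds[2] <= 1", call. = FALSE)
  }
  v <- raster$values
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- 0L
  cls[ok & v >= threshold] <- 1L
  cls[ok & v >= bounds[1L]] <- 2L
  cls[ok & v >= bounds[2L]] <- 3L
  structure(list(classes = cls, cell_km = raster$cell_km,
                 xmin = raster$xmin, ymin = raster$ymin,
                 threshold = threshold, bounds = bounds,
                 labels = SUIT_CLASSES),
            class = "suit_class_map")
}

#' @export
print.suit_class_map <- function(x, ...) {
  cat(sprintf("<suit_class_map> %d x %d cells; threshold %.3f, bounds %.2f/%.2f\n",
              nrow(x$classes), ncol(x$classes), x$threshold,
              x$bounds[1L], x$bounds[2L]))
  print(class_areas(x))
  invisible(x)
}

#' Per-class areas of a class map (km^2)
#' @param class_map a map from [reclassify()].
#' @export
class_areas <- function(class_map) {
  stopifnot(inherits(class_map, "suit_class_map"))
  a <- class_map$cell_km^2
  counts <- tabulate(class_map$classes + 1L, nbins = 4L)
  setNames(counts * a, SUIT_CLASSES)
}

#' Evaluate a suitability model against test records
#'
#' Computes the omission rate (fraction of test records on cells whose
#' suitability is below the threshold) and the one-sided binomial
#' significance probability `P(X >= observed successes)` under a success
#' probability equal to the fraction of non-NoData area predicted suitable.
#'
#' @param raster a [suit_raster()].
#' @param test_records data.frame with `x_km`, `y_km`; must fall on the
#'   raster (off-raster records are an error listing the offenders).
#' @param threshold decision threshold.
#' @return list with `omission_rate`, `binomial_p`, `suitable_fraction`,
#'   `threshold`, `n_test`.
#' @export
evaluate_suitability <- function(raster, test_records, threshold) {
  stopifnot(inherits(raster, "suit_raster"))
  scores <- extract_values(raster, test_records$x_km, test_records$y_km,
                           strict = TRUE)
  if (anyNA(scores)) {
    stop("test records fall on NoData cells at rows: ",
         paste(which(is.na(scores)), collapse = ", "), call. = FALSE)
  }
  n <- length(scores)
  hits <- sum(scores >= threshold)
  v <- raster$values[!is.na(raster$values)]
  p_suit <- mean(v >= threshold)
  binom_p <- if (n == 0) NA_real_ else {
    pbinom(hits - 1L, n, p_suit, lower.tail = FALSE)
  }
  list(omission_rate = if (n == 0) NA_real_ else 1 - hits / n,
       binomial_p = binom_p, suitable_fraction = p_suit,
       threshold = threshold, n_test = n)
}

#' Replicated evaluation report
#'
#' Runs the full evaluation loop the way a presence-only model is judged:
#' thin the records, draw `n_replicates` train/test partitions, score each
#' test set against a seeded uniform background sample, and report mean and
#' SD of AUC plus the omission and binomial test at the selected (or
#' supplied) threshold.
#'
#' @param raster a [suit_raster()].
#' @param records presence records (`x_km`, `y_km`).
#' @param threshold decision threshold; `NULL` selects it by maximum
#'   sensitivity + specificity on the full record set.
#' @param n_background number of uniform background cells (default 10000).
#' @param n_replicates partitions for the AUC spread.
#' @param train_fraction training proportion.
#' @param thin_cell_area_km2 thinning cell area; `NULL` skips thinning.
#' @param seed integer seed.
#' @return list: `auc`, `auc_sd`, `omission_rate`, `binomial_p`,
#'   `threshold`, `n_records_thinned`.
#' @export
suitability_report <- function(raster, records, threshold = NULL,
                               n_background = 10000, n_replicates = 10,
                               train_fraction = 0.7,
                               thin_cell_area_km2 = 144, seed = 1) {
  thinned <- if (is.null(thin_cell_area_km2)) records else {
    thin_records(records, thin_cell_area_km2, seed = seed)
  }
  v <- raster$values[!is.na(raster$values)]
  bg <- with_seed(seed + 1L, sample(v, n_background, replace = TRUE))
  all_scores <- extract_values(raster, thinned$x_km, thinned$y_km,
                               strict = TRUE)
  if (is.null(threshold)) {
    threshold <- select_threshold_max_ss(all_scores, bg)
  }
  parts <- split_train_test(thinned, train_fraction, n_replicates,
                            seed = seed + 2L)
  aucs <- vapply(parts, function(p) {
    s <- extract_values(raster, p$test$x_km, p$test$y_km, strict = TRUE)
    auc_presence_background(s, bg)
  }, 0)
  ev <- evaluate_suitability(raster, thinned, threshold)
  list(auc = mean(aucs), auc_sd = sd(aucs),
       omission_rate = ev$omission_rate, binomial_p = ev$binomial_p,
       threshold = threshold, n_records_thinned = nrow(thinned))
}
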