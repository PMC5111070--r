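# Burnham-Overton jackknife estimator of abundance under individual
# heterogeneity (model Mh), the non-spatial fallback for surveys whose
# spatial recaptures are too sparse for SECR.

#' Burnham-Overton jackknife coefficients
#'
#' Coefficients `a_ik` such that the order-`k` jackknife estimator is
#' `N_k = sum_i a_ik f_i`, where `f_i` is the number of animals captured on
#' exactly `i` of the `t` occasions. For `i > k`, `a_ik = 1`.
#'
#' @param t number of occasions (>= 2).
#' @param max_order highest order (default 5).
#' @return matrix `max_order x t` of coefficients (rows = order).
#' @export
jackknife_coefficients <- function(t, max_order = 5L) {
  if (t < 2L) stop("need t >= 2 occasions", call. = FALSE)
  if (max_order > t - 1L) {
    stop("max_order must be <= t - 1", call. = FALSE)
  }
  a <- matrix(1, max_order, t)
  add <- function(k, i, v) if (i <= t) a[k, i] <<- 1 + v
  add(1L, 1L, (t - 1) / t)
  if (max_order >= 2L) {
    add(2L, 1L, (2 * t - 3) / t)
    add(2L, 2L, -(t - 2)^2 / (t * (t - 1)))
  }
  if (max_order >= 3L) {
    add(3L, 1L, (3 * t - 6) / t)
    add(3L, 2L, -(3 * t^2 - 15 * t + 19) / (t * (t - 1)))
    add(3L, 3L, (t - 3)^3 / (t * (t - 1) * (t - 2)))
  }
  if (max_order >= 4L) {
    add(4L, 1L, (4 * t - 10) / t)
    add(4L, 2L, -(6 * t^2 - 36 * t + 55) / (t * (t - 1)))
    add(4L, 3L, (4 * t^3 - 42 * t^2 + 148 * t - 175) /
          (t * (t - 1) * (t - 2)))
    add(4L, 4L, -(t - 4)^4 / (t * (t - 1) * (t - 2) * (t - 3)))
  }
  if (max_order >= 5L) {
    add(5L, 1L, (5 * t - 15) / t)
    add(5L, 2L, -(10 * t^2 - 70 * t + 125) / (t * (t - 1)))
    add(5L, 3L, (10 * t^3 - 120 * t^2 + 485 * t - 660) /
          (t * (t - 1) * (t - 2)))
    add(5L, 4L, -((t - 4)^5 - (t - 5)^5) /
          (t * (t - 1) * (t - 2) * (t - 3)))
    add(5L, 5L, (t - 5)^5 / (t * (t - 1) * (t - 2) * (t - 3) * (t - 4)))
  }
  a
}

#' Jackknife Mh abundance estimate with order selection
#'
#' Computes the Burnham-Overton jackknife estimators of orders 1-5 from the
#' capture-frequency vector and selects the order by the sequential
#' chi-square test: the first order `k` for which `N_{k+1}` does not differ
#' significantly (alpha = 0.05) from `N_k` is retained. (Program CAPTURE
#' additionally interpolates between adjacent orders; the exact
#' interpolation formula is not reproduced here and the selected-order
#' estimate is returned.)
#'
#' @param capture_frequencies vector `f_1 .. f_t`; `f_i` is the number of
#'   animals caught on exactly `i` occasions.
#' @param n_occasions `t` (>= 2); defaults to `length(capture_frequencies)`.
#' @return list: `N_hat` (never below the observed count `S`), `se`,
#'   `order`, plus `estimates` / `ses` for all orders and the test
#'   statistics.
#' @export
jackknife_mh <- function(capture_frequencies,
                         n_occasions = length(capture_frequencies)) {
  t <- as.integer(n_occasions)
  if (t < 2L) stop("need t >= 2 occasions", call. = FALSE)
  f <- rep(0, t)
  f[seq_along(capture_frequencies)] <- capture_frequencies
  if (any(f < 0)) stop("capture frequencies must be >= 0", call. = FALSE)
  S <- sum(f)
  if (S < 1) stop("need at least one captured animal", call. = FALSE)
  max_order <- min(5L, t - 1L)
  a <- jackknife_coefficients(t, max_order)
  N <- as.vector(a %*% f)
  se <- sqrt(pmax(0, as.vector(a^2 %*% f) - N))
  # sequential tests between successive orders
  chisq <- pvals <- rep(NA_real_, max(0L, max_order - 1L))
  order <- max_order
  for (k in seq_len(max_order - 1L)) {
    b <- a[k + 1L, ] - a[k, ]
    dN <- N[k + 1L] - N[k]
    v <- (S / (S - 1)) * (sum(b^2 * f) - dN^2 / S)
    chisq[k] <- if (v > 0) dN^2 / v else 0
    pvals[k] <- 1 - pchisq_safe(chisq[k])
    if (pvals[k] > 0.05) { order <- k; break }
  }
  # abundance cannot fall below the number of distinct animals observed;
  # higher-order estimates can dip under S, so the reported N_hat is
  # clamped (raw per-order estimates are returned unclamped)
  list(N_hat = max(N[order], S), se = se[order], order = order,
       estimates = N, ses = se, chisq = chisq, p_values = pvals, S = S)
}

pchisq_safe <- function(x) stats::pchisq(x, df = 1)
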