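# Independent oracles and fixture builders shared across the suite. These
# deliberately re-derive results by brute force, never by calling the code
# paths they check.

# --- dense all-pairs shortest path (Bellman-Ford relaxation sweep) on the
# 8-neighbour grid graph with endpoint-mean edge weights ---------------
oracle_grid_distances <- function(resist, cell_km, sources) {
  nr <- nrow(resist); nc <- ncol(resist)
  d <- matrix(Inf, nr, nc)
  d[sources] <- 0
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      for (m in seq_len(nrow(moves))) {
        r2 <- r + moves$dr[m]; c2 <- c + moves$dc[m]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        mult <- if (moves$dr[m] != 0 && moves$dc[m] != 0) sqrt(2) else 1
        w <- (resist[r, c] + resist[r2, c2]) / 2 * cell_km * mult
        if (d[r, c] + w < d[r2, c2] - 1e-15) {
          d[r2, c2] <- d[r, c] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# --- exhaustive-enumeration SECR likelihood: sum over every inclusion
# vector z and every assignment of activity centres to pixels ----------
oracle_secr_lik <- function(y, traps, K, p0, sigma, psi, pixels) {
  y <- as.matrix(y); pixels <- as.matrix(pixels)
  M <- nrow(y); P <- nrow(pixels)
  ind_lik <- function(i, px) {
    d2 <- (pixels[px, 1] - traps$x_km)^2 + (pixels[px, 2] - traps$y_km)^2
    p <- p0 * exp(-d2 / (2 * sigma^2))
    prod(p^y[i, ] * (1 - p)^(K - y[i, ]))
  }
  total <- 0
  for (zcode in 0:(2^M - 1)) {
    z <- as.integer(intToBits(zcode))[1:M]
    for (acode in 0:(P^M - 1)) {
      a <- acode
      centers <- integer(M)
      for (i in 1:M) { centers[i] <- a %% P + 1; a <- a %/% P }
      term <- 1 / P^M
      for (i in 1:M) {
        term <- term * psi^z[i] * (1 - psi)^(1 - z[i])
        term <- term * if (z[i] == 1) ind_lik(i, centers[i]) else {
          as.numeric(all(y[i, ] == 0))
        }
      }
      total <- total + term
    }
  }
  total
}

# --- generalized jackknife derivation of the Burnham-Overton
# coefficients (drop-j occasion resampling) ----------------------------
oracle_jackknife_coef <- function(t, k) {
  sapply(seq_len(t), function(i) {
    sj <- sapply(0:k, function(j) {
      drop <- if (j >= i) choose(t - i, j - i) / choose(t, j) else 0
      1 - drop
    })
    w <- sapply(0:k, function(j) {
      (-1)^j * choose(k, j) * (t - j)^k / factorial(k)
    })
    sum(w * sj)
  })
}

# --- single-linkage grouping as explicit transitive closure -----------
oracle_transitive_groups <- function(dmat, radius, forced = list()) {
  n <- nrow(dmat)
  adj <- dmat < radius
  for (fm in forced) adj[fm[1], fm[2]] <- adj[fm[2], fm[1]] <- TRUE
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n); k <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { k <- k + 1; comp[adj[i, ]] <- k }
  }
  comp
}

# --- fixture builders -------------------------------------------------
uniform_raster <- function(value, n = 10, cell_km = 1) {
  suit_raster(matrix(value, n, n), cell_km)
}

# class map with an explicit suitable mask (1 where suitable)
mask_class_map <- function(mask, cell_km = 1, good = NULL) {
  cls <- matrix(0L, nrow(mask), ncol(mask))
  cls[mask == 1] <- 1L
  if (!is.null(good)) cls[good == 1] <- 2L
  r <- suit_raster(matrix(0.9 * (cls > 0), nrow(cls), ncol(cls)), cell_km)
  reclassify_like <- reclassify(r, threshold = 0.364)
  reclassify_like$classes <- cls
  reclassify_like
}

tiny_capture <- function(y, traps, K) {
  # build a capture_data from a counts matrix by spreading counts over
  # the first occasions
  n <- nrow(y); J <- ncol(y)
  det <- array(0L, c(n, J, K))
  for (i in seq_len(n)) for (j in seq_len(J)) {
    if (y[i, j] > 0) det[i, j, seq_len(y[i, j])] <- 1L
  }
  capture_data(traps,
               det,
               data.frame(individual_id = sprintf("I%02d", seq_len(n)),
                          sex = rep("F", n), age = rep("adult", n)))
}

ref_units_path <- function() {
  system.file("extdata", "af_unit_evidence.csv", package = "onca")
}
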