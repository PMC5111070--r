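test_that("generate_landscape honours the range contract and determinism", {
  spec <- landscape_spec(extent_km = 100, cell_km = 1,
                         autocorrelation_range_km = 8, seed = 7)
  ls1 <- generate_landscape(spec)
  ls2 <- generate_landscape(spec)
  expect_equal(dim(ls1$raster$values), c(100L, 100L))
  expect_true(all(ls1$raster$values >= 0 & ls1$raster$values <= 1))
  expect_identical(ls1$raster$values, ls2$raster$values)
  expect_identical(ls1$roads, ls2$roads)
  expect_length(ls1$roads, 2L)
  # roads cross the extent edge-to-edge
  for (rd in ls1$roads) {
    span <- apply(rd, 2, function(v) diff(range(v)))
    expect_equal(max(span), 100)
  }
  expect_error(landscape_spec(extent_km = -1), "positive")
  expect_error(landscape_spec(extent_km = 10, cell_km = 3), "evenly")
})

test_that("zero autocorrelation range yields spatially independent noise", {
  spec <- landscape_spec(extent_km = 100, cell_km = 1,
                         autocorrelation_range_km = 0, seed = 3)
  v <- generate_landscape(spec)$raster$values
  lag1 <- cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  expect_lt(abs(lag1), 0.1)
  lag1r <- cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))
  expect_lt(abs(lag1r), 0.1)
  # and a positive range produces clearly positive lag-1 correlation
  sm <- generate_landscape(landscape_spec(100, 1, 10, seed = 3))$raster$values
  expect_gt(cor(as.vector(sm[, -1]), as.vector(sm[, -ncol(sm)])), 0.5)
})

test_that("sample_presences follows the suitability distribution", {
  r <- uniform_raster(0.5, n = 20)
  expect_equal(nrow(sample_presences(r, 0)), 0L)

  # degenerate support: single nonzero cell catches every point
  m <- matrix(0, 10, 10); m[4, 7] <- 1
  r1 <- suit_raster(m, 1)
  pts <- sample_presences(r1, 5, seed = 2)
  expect_equal(nrow(pts), 5L)
  expect_true(all(pts$x_km >= 6 & pts$x_km <= 7))
  expect_true(all(pts$y_km >= 6 & pts$y_km <= 7))

  expect_error(sample_presences(suit_raster(matrix(0, 3, 3), 1), 1),
               "no positive suitability")

  # uniform raster: per-quadrant counts within 3 sigma of n/4
  pts <- sample_presences(r, 10000, seed = 5)
  qx <- pts$x_km > 10; qy <- pts$y_km > 10
  counts <- table(qx, qy)
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 3 * sigma))
})

test_that("simulate_secr matches its generative contract", {
  tr <- secr_truth(density_true = 5, p0_true = 0.1, sigma_true = 2,
                   n_occasions = 10)
  expect_error(simulate_secr(tr, c(0, 10, 0, -5)), "positive area")

  # p0 -> 0 gives no detections
  tr0 <- secr_truth(p0_true = 1e-12, sigma_true = 2, n_occasions = 3)
  cap0 <- simulate_secr(tr0, c(0, 26, 0, 26), seed = 1)
  expect_equal(dim(cap0$detections)[1], 0L)

  # near-certain detection limit: huge sigma, p0 ~ 1, one occasion
  trL <- secr_truth(density_true = 5, p0_true = 0.999, sigma_true = 500,
                    n_occasions = 1, trap_spacing_km = 2)
  capL <- simulate_secr(trL, c(0, 20, 0, 20), seed = 2,
                        traps = make_trap_grid(2, 2, c(10, 10)),
                        fixed_N = 20)
  expect_equal(dim(capL$detections)[1], 20L)

  # Poisson mean of realized N: density 1/100 km2 on 20x20 km -> mean 4
  Ns <- vapply(1:1000, function(s) {
    tr4 <- secr_truth(density_true = 1, p0_true = 0.5, sigma_true = 1,
                      n_occasions = 1, trap_spacing_km = 2)
    cap <- simulate_secr(tr4, c(0, 20, 0, 20), seed = s,
                         traps = make_trap_grid(2, 2, c(10, 10)))
    attr(cap, "truth")$N
  }, 0)
  expect_lt(abs(mean(Ns) - 4), 3 * sqrt(4 / 1000) + 0.05)

  # determinism
  c1 <- simulate_secr(tr, c(0, 26, 0, 26), seed = 9)
  c2 <- simulate_secr(tr, c(0, 26, 0, 26), seed = 9)
  expect_identical(c1$detections, c2$detections)
})

test_that("detection frequencies follow the half-normal curve", {
  # one trap at the origin; individuals planted at fixed distances via
  # fixed centres is not exposed, so accumulate (distance, hit) pairs
  # from the truth attribute over many simulations and compare binned
  # detection counts to the half-normal expectation
  tr <- secr_truth(density_true = 40, p0_true = 0.6, sigma_true = 2,
                   n_occasions = 1, trap_spacing_km = 1)
  traps <- data.frame(trap_id = "T1", x_km = 10, y_km = 10)
  dist_all <- hit_all <- numeric(0)
  for (s in 1:40) {
    cap <- simulate_secr(tr, c(4, 16, 4, 16), seed = s, traps = traps)
    truth <- attr(cap, "truth")
    d <- sqrt((truth$centers[, 1] - 10)^2 + (truth$centers[, 2] - 10)^2)
    hit <- as.integer(truth$seen)
    dist_all <- c(dist_all, d); hit_all <- c(hit_all, hit)
  }
  expect_gt(length(dist_all), 1000)
  bins <- cut(dist_all, c(0, 1, 2, 3, 4, Inf))
  obs <- tapply(hit_all, bins, sum)
  expectd <- tapply(0.6 * exp(-dist_all^2 / 8), bins, sum)
  vars <- tapply(0.6 * exp(-dist_all^2 / 8) *
                   (1 - 0.6 * exp(-dist_all^2 / 8)), bins, sum)
  z <- (obs - expectd) / sqrt(vars)
  # per-bin normal check at alpha = 0.01 with Bonferroni over 5 bins
  expect_true(all(abs(z) < qnorm(1 - 0.005 / 5)))
  # monotone decay of empirical detection rate with distance
  rate <- tapply(hit_all, bins, mean)
  expect_true(all(diff(rate) < 0.05))
})
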