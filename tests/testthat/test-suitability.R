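test_that("thin_records keeps one record per home-range cell", {
  # two records in one 12x12 cell -> one kept
  rec <- data.frame(x_km = c(1, 2), y_km = c(1, 2))
  expect_equal(nrow(thin_records(rec, 144, seed = 1)), 1L)

  # records in distinct cells -> identity
  rec2 <- data.frame(x_km = c(1, 20, 40), y_km = c(1, 20, 40))
  expect_equal(thin_records(rec2, 144, seed = 1), rec2)

  # 100 uniform records over 24x24 km, 144 km2 cells: exactly the number
  # of occupied 12x12 cells is retained (oracle: count occupied cells)
  set.seed(42)
  rec3 <- data.frame(x_km = runif(100, 0, 24), y_km = runif(100, 0, 24))
  occupied <- length(unique(paste(floor(rec3$x_km / 12),
                                  floor(rec3$y_km / 12))))
  expect_equal(occupied, 4L)
  expect_equal(nrow(thin_records(rec3, 144, seed = 3)), occupied)

  # retained records are a subset of the input, deterministic per seed
  t1 <- thin_records(rec3, 144, seed = 5)
  expect_identical(t1, thin_records(rec3, 144, seed = 5))
  expect_true(all(t1$x_km %in% rec3$x_km))
})

test_that("split_train_test produces valid independent partitions", {
  rec <- data.frame(x_km = 1:10, y_km = 1:10)
  parts <- split_train_test(rec, 0.7, n_replicates = 10, seed = 1)
  expect_length(parts, 10L)
  for (p in parts) {
    expect_equal(nrow(p$train), 7L)
    expect_equal(nrow(p$test), 3L)
    both <- rbind(p$train, p$test)
    expect_setequal(both$x_km, rec$x_km)  # union is the input
    expect_equal(nrow(both), 10L)         # no overlap
  }
  # replicates differ (independent re-draws)
  expect_false(identical(parts[[1]]$train, parts[[2]]$train))
  expect_error(split_train_test(rec[1, , drop = FALSE]), "at least 2")
  expect_error(split_train_test(rec, 1.2), "in \\(0, 1\\)")
})

test_that("auc_presence_background is the rank statistic", {
  expect_equal(auc_presence_background(c(0.9, 0.8), c(0.1, 0.6)), 1.0)
  expect_equal(auc_presence_background(0.5, 0.5), 0.5)
  # enumerate the 4 pairs: (.9>.5),(.9>.1),(.4<.5),(.4>.1) -> 3/4
  expect_equal(auc_presence_background(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(auc_presence_background(numeric(0), 0.3), "non-empty")

  # invariance under strictly monotone transforms
  set.seed(8)
  for (i in 1:20) {
    p <- runif(7); b <- runif(11)
    a0 <- auc_presence_background(p, b)
    expect_equal(auc_presence_background(p^3, b^3), a0)
    expect_equal(auc_presence_background(exp(p), exp(b)), a0)
  }
})

test_that("select_threshold_max_ss equals an exhaustive candidate scan", {
  expect_equal(select_threshold_max_ss(c(0.9, 0.8), c(0.1, 0.2)), 0.5)
  # identical sets: sens + spec constant, smallest candidate returned
  expect_equal(select_threshold_max_ss(c(0.3, 0.7), c(0.3, 0.7)), 0)

  brute <- function(p, b) {
    pooled <- sort(unique(c(p, b)))
    cand <- sort(unique(c(0, 1, (pooled[-1] + pooled[-length(pooled)]) / 2)))
    ss <- sapply(cand, function(t) mean(p >= t) + mean(b < t))
    cand[which(ss == max(ss))[1]]
  }
  expect_equal(select_threshold_max_ss(c(0.9, 0.8, 0.4), c(0.1, 0.2, 0.6)),
               brute(c(0.9, 0.8, 0.4), c(0.1, 0.2, 0.6)))
  set.seed(11)
  for (i in 1:25) {
    p <- round(runif(sample(2:50, 1)), 2)
    b <- round(runif(sample(2:50, 1)), 2)
    expect_equal(select_threshold_max_ss(p, b), brute(p, b))
  }
})

test_that("reclassify applies the documented class bounds", {
  r <- suit_raster(matrix(c(0.1, 0.364, 0.49, 0.5, 0.74, 0.75, 1, NA, 0.2),
                          3, 3), 1)
  cm <- reclassify(r, threshold = 0.364)
  expect_equal(as.vector(cm$classes)[1:7], c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_true(is.na(cm$classes[2, 3]))
  expect_error(reclassify(r, threshold = 0.6), "threshold < bounds")

  # uniform 0.6 raster over 100 km2 -> all medium
  cm2 <- reclassify(uniform_raster(0.6, 10), 0.364)
  expect_equal(unname(class_areas(cm2)), c(0, 0, 100, 0))

  # conservation: class areas sum to the non-NoData area
  set.seed(3)
  m <- matrix(runif(400), 20, 20); m[sample(400, 30)] <- NA
  rr <- suit_raster(m, 2)
  expect_equal(sum(class_areas(reclassify(rr, 0.364))),
               raster_area_km2(rr))
})

test_that("evaluate_suitability computes omission and the binomial test", {
  r <- uniform_raster(0.8, 4)
  rec <- data.frame(x_km = c(1, 2), y_km = c(1, 2))
  ev <- evaluate_suitability(r, rec, 0.364)
  expect_equal(ev$omission_rate, 0)

  # suitable fraction 0.5, 9 of 10 records suitable:
  # P(X >= 9 | 10, 0.5) = 11/1024
  m <- matrix(rep(c(0.2, 0.8), each = 50), 10, 10)
  r2 <- suit_raster(m, 1)
  xs <- c(rep(7.5, 9), 2.5)  # 9 on the suitable half, 1 off
  rec2 <- data.frame(x_km = xs, y_km = seq(0.5, 9.5, 1))
  ev2 <- evaluate_suitability(r2, rec2, 0.5)
  expect_equal(ev2$suitable_fraction, 0.5)
  expect_equal(ev2$omission_rate, 0.1)
  expect_equal(ev2$binomial_p, 11 / 1024)

  # threshold 0 -> zero omission whatever the records
  expect_equal(evaluate_suitability(r2, rec2, 0)$omission_rate, 0)

  # raising the threshold never decreases omission
  oms <- sapply(seq(0, 1, 0.1), function(t) {
    evaluate_suitability(r2, rec2, t)$omission_rate
  })
  expect_true(all(diff(oms) >= 0))

  expect_error(evaluate_suitability(r2, data.frame(x_km = 50, y_km = 1),
                                    0.5), "outside raster")
})
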