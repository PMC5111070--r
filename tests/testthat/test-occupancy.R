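test_that("extract_fragments splits suitable habitat by roads", {
  # 10x10 uniform suitable block, no roads -> one 100 km2 fragment
  cm <- mask_class_map(matrix(1, 10, 10))
  frags <- extract_fragments(cm)
  expect_length(frags, 1L)
  expect_equal(frags[[1]]$area_km2, 100)
  expect_equal(frags[[1]]$size_class, "100-1000")

  # vertical road bisects it: two fragments, areas sum to 100 - road cells
  road <- list(cbind(x = c(5.5, 5.5), y = c(-1, 11)))
  frags2 <- extract_fragments(cm, road)
  expect_length(frags2, 2L)
  areas <- sort(vapply(frags2, `[[`, 0, "area_km2"))
  expect_equal(sum(areas), 100 - 10)
  expect_equal(areas, c(40, 50))

  # empty suitable mask is an empty list, not an error
  expect_equal(extract_fragments(mask_class_map(matrix(0, 5, 5))), list())
})

test_that("diagonal-touching arms are separate under 4-connectivity", {
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 1   # block A
  m[4:6, 4:6] <- 1   # block B touches A only at one corner
  frags <- extract_fragments(mask_class_map(m))
  expect_length(frags, 2L)
  expect_equal(sort(vapply(frags, `[[`, 0, "area_km2")), c(9, 9))
})

test_that("good_area tracks medium+high cells", {
  m <- matrix(1, 4, 4)
  good <- matrix(0, 4, 4); good[1:2, ] <- 1
  frags <- extract_fragments(mask_class_map(m, good = good))
  expect_equal(frags[[1]]$area_km2, 16)
  expect_equal(frags[[1]]$good_area_km2, 8)
})

test_that("median_outside_distance follows the rule", {
  cm <- mask_class_map(matrix(1, 10, 10))
  frags <- extract_fragments(cm)
  # outside records at 1.0, 1.7 and 3.0 km east of the fragment edge
  rec <- data.frame(x_km = c(11, 11.7, 13), y_km = 5)
  expect_equal(median_outside_distance(rec, frags), 1.7)
  # a single outside record is its own median
  expect_equal(median_outside_distance(data.frame(x_km = 12.4, y_km = 5),
                                       frags), 2.4)
  # inside records are ignored
  rec2 <- rbind(rec, data.frame(x_km = c(5, 2), y_km = c(5, 3)))
  expect_equal(median_outside_distance(rec2, frags), 1.7)
  # all-inside is an error pointing at the config
  expect_error(median_outside_distance(data.frame(x_km = 5, y_km = 5),
                                       frags), "radius")
})

two_fragment_setup <- function(gap_cols = 2) {
  # two 5-wide suitable blocks separated by gap_cols unsuitable columns
  m <- matrix(0, 10, 12 + gap_cols)
  m[, 1:5] <- 1
  m[, (6 + gap_cols):(12 + gap_cols)] <- 1
  extract_fragments(mask_class_map(m))
}

test_that("classify_occupancy implements AJO/APJO without chaining", {
  frags <- two_fragment_setup()
  # record inside fragment 1 only; fragments are 2 km apart edge-to-edge
  rec <- data.frame(x_km = 2.5, y_km = 5)
  lab <- classify_occupancy(frags, rec, radius_km = 1.7)
  expect_equal(lab$label[1], "AJO")
  expect_equal(lab$label[2], "empty")     # 2 km > 1.7 km

  lab2 <- classify_occupancy(frags, rec, radius_km = 2.5)
  expect_equal(lab2$label[2], "APJO")     # within 2.5 km of an AJO

  # record 1 km outside fragment 1 makes it AJO by proximity
  rec3 <- data.frame(x_km = 6, y_km = 5)
  lab3 <- classify_occupancy(frags, rec3, radius_km = 1.7)
  expect_equal(lab3$label[1], "AJO")

  # no chaining: a third fragment near only an APJO stays empty
  m <- matrix(0, 10, 19)
  m[, 1:5] <- 1; m[, 8:12] <- 1; m[, 15:19] <- 1
  frags3 <- extract_fragments(mask_class_map(m))
  lab4 <- classify_occupancy(frags3, rec, radius_km = 2.5)
  expect_equal(lab4$label, c("AJO", "APJO", "empty"))
})

test_that("radius 0 reduces to containment with empty APJO set", {
  frags <- two_fragment_setup()
  rec <- data.frame(x_km = c(2.5, 5.2), y_km = c(5, 5))  # one in, one out
  lab <- classify_occupancy(frags, rec, radius_km = 0)
  expect_equal(lab$label, c("AJO", "empty"))
  expect_false(any(lab$label == "APJO"))
})

test_that("the AJO set is monotone in the radius", {
  set.seed(21)
  m <- matrix(rbinom(400, 1, 0.4), 20, 20)
  frags <- extract_fragments(mask_class_map(m))
  rec <- data.frame(x_km = runif(15, 0, 20), y_km = runif(15, 0, 20))
  prev <- character(0)
  for (rad in c(0, 0.5, 1, 2, 4, 8)) {
    lab <- classify_occupancy(frags, rec, rad)
    ajo <- lab$fragment_id[lab$label == "AJO"]
    expect_true(all(prev %in% ajo))
    prev <- ajo
  }
})

test_that("occupancy_summary conserves counts and areas", {
  frags <- two_fragment_setup()
  rec <- data.frame(x_km = 2.5, y_km = 5)
  lab <- classify_occupancy(frags, rec, 1.7)
  summ <- occupancy_summary(frags, lab)
  expect_equal(sum(summ$n), length(frags))
  expect_equal(sum(summ$area_km2), sum(vapply(frags, `[[`, 0, "area_km2")))
  # hand count: both fragments are 50 km2, one AJO and one empty
  expect_equal(summ$n[summ$size_class == "<100" & summ$label == "AJO"], 1)
  expect_equal(summ$n[summ$size_class == "<100" & summ$label == "empty"], 1)

  # all-AJO case: empty fraction zero in every class
  lab_all <- lab; lab_all$label <- "AJO"
  s2 <- occupancy_summary(frags, lab_all)
  expect_equal(sum(s2$n[s2$label == "empty"]), 0)
})

test_that("occupancy_ratios reproduces share arithmetic", {
  out <- occupancy_ratios(c(marginal = 50, medium = 30, high = 20), 25, 10)
  expect_equal(out$suitable_km2, 100)
  expect_equal(out$pct_ajo, 25)
  expect_equal(out$pct_apjo, 10)
  expect_equal(out$pct_empty, 65)
  expect_error(occupancy_ratios(0, 1, 1), "positive")
})
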