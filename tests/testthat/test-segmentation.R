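gaussian_pit <- function(n = 41, depth = 100, sigma = 4, noise = 1e-3,
                         seed = 1) {
  set.seed(seed)
  ctr <- (n + 1) / 2
  d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, `+`)
  z <- -depth * exp(-d2 / (2 * sigma^2)) +
    matrix(rnorm(n * n, 0, noise), n, n)
  z - mean(z)
}

test_that("a single Gaussian pit segments into one dale of the right depth", {
  depth <- 100
  hm <- hm_fixture(gaussian_pit(depth = depth))
  fs <- wolf_prune(watershed_segment(hm, "dale"), hm)
  at <- feature_attributes(fs, hm)
  expect_identical(nrow(at), 1L)
  expect_equal(at$magnitude, -min(hm$z))    # the pit bottom is the extreme
  # magnitude is the drawn depth up to the mean-plane offset of the pit
  expect_equal(at$magnitude, depth, tolerance = 0.1 * depth)
})

test_that("a tilted plane has no significant interior dale", {
  z <- outer(1:20, 1:20, function(i, j) 0.5 * j + 0.1 * i)
  hm <- preprocess(heightmap(z, 5, 5))
  fs <- wolf_prune(watershed_segment(hm, "dale"), hm)
  expect_identical(setdiff(unique(as.vector(fs$labels)), 0L), integer(0))
})

test_that("watershed labels match the steepest-descent oracle exactly", {
  for (seed in 1:4) {
    set.seed(seed)
    z <- matrix(sample(1:64), 8, 8)   # distinct integers
    for (conn in c(4L, 8L)) {
      got <- watershed_segment(hm_fixture(z - mean(z)), "dale", conn)$labels
      ora <- oracle_watershed(z, conn)
      expect_true(same_partition(got, ora),
                  label = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("watershed with ties (plateaus) is deterministic and oracle-equal", {
  set.seed(99)
  z <- matrix(sample(1:8, 64, replace = TRUE), 8, 8)  # many ties
  a <- watershed_segment(hm_fixture(z - mean(z)), "dale")$labels
  b <- watershed_segment(hm_fixture(z - mean(z)), "dale")$labels
  expect_identical(a, b)
  expect_true(same_partition(a, oracle_watershed(z, 8)))
})

test_that("Wolf pruning matches the naive full-recompute oracle on toy grids", {
  for (seed in 1:6) {
    set.seed(seed)
    z <- matrix(sample(1:100), 10, 10)
    z <- z - mean(z)
    hm <- hm_fixture(z)
    for (kind in c("dale", "hill")) {
      w <- if (kind == "dale") z else -z
      fs <- watershed_segment(hm, kind)
      for (pf in c(0.05, 0.15, 0.3)) {
        cfg <- segmentation_config(prune_fraction = pf, kind = kind)
        got <- wolf_prune(fs, hm, cfg)$labels
        ora <- oracle_wolf_prune(oracle_watershed(w, 8), w,
                                 pf * diff(range(z)))
        expect_true(same_partition(got, ora),
                    label = sprintf("seed %d kind %s pf %.2f", seed, kind, pf))
      }
    }
  }
})

test_that("a shallow companion pit merges away at the 10% threshold", {
  n <- 41
  d2a <- outer((1:n - 11)^2, (1:n - 11)^2, `+`)
  d2b <- outer((1:n - 31)^2, (1:n - 31)^2, `+`)
  set.seed(2)
  z <- -100 * exp(-d2a / 18) - 5 * exp(-d2b / 18) +
    matrix(rnorm(n * n, 0, 1e-3), n, n)
  z <- z - mean(z)
  hm <- hm_fixture(z)
  fs0 <- watershed_segment(hm, "dale")
  pruned <- wolf_prune(fs0, hm, segmentation_config(0.10, kind = "dale"))
  expect_identical(length(setdiff(unique(as.vector(pruned$labels)), 0L)), 1L)
  # a tiny threshold keeps both pits
  both <- wolf_prune(fs0, hm, segmentation_config(0.02, kind = "dale"))
  expect_identical(length(setdiff(unique(as.vector(both$labels)), 0L)), 2L)
})

test_that("a near-zero threshold leaves the segmentation partition unchanged", {
  set.seed(7)
  z <- matrix(rnorm(144), 12, 12); z <- z - mean(z)
  hm <- hm_fixture(z)
  fs <- watershed_segment(hm, "dale")
  # border escape heights can be exactly zero for basins whose minimum
  # sits on the map edge, so the limit case is about internal saddles
  pruned <- wolf_prune(fs, hm, segmentation_config(1e-9, kind = "dale",
                                                   border_saddle = FALSE))
  expect_true(same_partition(fs$labels, pruned$labels))
})

test_that("retained feature count is non-increasing in the pruning threshold", {
  set.seed(13)
  z <- matrix(rnorm(400, 0, 10), 20, 20); z <- z - mean(z)
  hm <- hm_fixture(z)
  fs <- watershed_segment(hm, "dale")
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8), function(pf) {
    lab <- wolf_prune(fs, hm, segmentation_config(pf, kind = "dale"))$labels
    length(setdiff(unique(as.vector(lab)), 0L))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pruning is idempotent at a fixed threshold", {
  set.seed(23)
  z <- matrix(rnorm(225, 0, 10), 15, 15); z <- z - mean(z)
  hm <- hm_fixture(z)
  once <- wolf_prune(watershed_segment(hm, "dale"), hm,
                     segmentation_config(0.15, kind = "dale"))
  twice <- wolf_prune(once, hm, segmentation_config(0.15, kind = "dale"))
  expect_identical(once$labels, twice$labels)
})

test_that("hill segmentation of z equals dale segmentation of -z with negated attributes", {
  set.seed(37)
  z <- matrix(sample(1:400), 20, 20); z <- z - mean(z)
  hm_pos <- hm_fixture(z); hm_neg <- hm_fixture(-z)
  hills <- wolf_prune(watershed_segment(hm_pos, "hill"), hm_pos,
                      segmentation_config(0.1, kind = "hill"))
  dales <- wolf_prune(watershed_segment(hm_neg, "dale"), hm_neg,
                      segmentation_config(0.1, kind = "dale"))
  expect_true(same_partition(hills$labels, dales$labels))
  ah <- feature_attributes(hills, hm_pos)
  ad <- feature_attributes(dales, hm_neg)
  expect_equal(sort(ah$magnitude), sort(ad$magnitude))
  expect_equal(sort(ah$extreme), sort(-ad$extreme))
})

test_that("feature attributes: single pit table, partition area bound, empty case", {
  hm <- hm_fixture(gaussian_pit())
  fs <- wolf_prune(watershed_segment(hm, "dale"), hm)
  at <- feature_attributes(fs, hm)
  expect_identical(nrow(at), 1L)
  expect_lte(sum(at$area_mm2),
             nrow(hm$z) * ncol(hm$z) * hm$step_x * hm$step_y / 1e6)
  empty <- feature_attributes(
    wolf_prune(watershed_segment(
      hm_fixture(outer(1:10, 1:10, `+`) - 11), "dale"),
      hm_fixture(outer(1:10, 1:10, `+`) - 11)),
    hm_fixture(outer(1:10, 1:10, `+`) - 11))
  expect_identical(nrow(empty), 0L)
})

test_that("S5v equals the mean of the five deepest engineered pits", {
  n <- 81
  depths <- c(10, 20, 30, 40, 50)
  ctrs <- cbind(c(15, 15, 40, 65, 65), c(15, 65, 40, 15, 65))
  set.seed(3)
  z <- matrix(rnorm(n * n, 0, 1e-3), n, n)
  for (k in 1:5) {
    d2 <- outer((1:n - ctrs[k, 1])^2, (1:n - ctrs[k, 2])^2, `+`)
    z <- z - depths[k] * exp(-d2 / 12)
  }
  zoff <- mean(z)
  z <- z - zoff
  hm <- hm_fixture(z)
  fp <- feature_params(hm, segmentation_config(0.05))
  # pit magnitudes are measured from the mean plane, which sits -zoff
  # below the original flat background
  expect_equal(fp$S_5v, mean(depths) - zoff, tolerance = 0.2)
})

test_that("feature parameters respect order-statistic bounds and mirror symmetry", {
  set.seed(41)
  z <- matrix(rnorm(40 * 40, 0, 20), 40, 40); z <- z - mean(z)
  hm <- hm_fixture(z)
  hp <- height_params(hm)
  fp <- feature_params(hm, segmentation_config(0.05))
  expect_lte(fp$S_5p, hp$S_p); expect_lte(fp$S_5v, hp$S_v)
  expect_lte(fp$S_10z, hp$S_z)
  fpm <- feature_params(hm_fixture(-z), segmentation_config(0.05))
  expect_equal(fp$S_5p, fpm$S_5v, tolerance = 1e-9)
  expect_equal(fp$S_5v, fpm$S_5p, tolerance = 1e-9)
})

test_that("site classification applies the hill and dale height thresholds", {
  z <- matrix(c(3500, -50, 1500, 3000, 0, 2999), 2, 3)
  hm <- heightmap(z, 5, 5)
  sites <- data.frame(row = c(1, 2, 1, 2, 1, 2), col = c(1, 1, 2, 2, 3, 3))
  out <- classify_sites(hm, sites)
  expect_equal(as.character(out$label),
               c("hill", "dale", "neither", "hill", "dale", "neither"))
  expect_equal(attr(out, "hill_fraction"), 100 * 2 / 6)
  all_high <- classify_sites(hm, data.frame(row = c(1, 2), col = c(1, 2)))
  expect_equal(attr(all_high, "hill_fraction"), 100)
  expect_error(classify_sites(hm, data.frame(row = 5, col = 1)),
               "out of bounds")
  expect_error(classify_sites(hm, data.frame(row = integer(), col = integer())),
               "empty")
  expect_error(site_classification_config(0, 0), "exceed")
})
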