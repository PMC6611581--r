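test_that("screening ANOVA equals the squared pooled t and stats::aov", {
  set.seed(3)
  tbl <- data.frame(group = rep(c("colonized", "bare"), c(12, 9)),
                    p1 = rnorm(21, 10, 2), p2 = rnorm(21, 5, 1))
  out <- screen_parameters(tbl)
  for (pn in c("p1", "p2")) {
    x1 <- tbl[[pn]][tbl$group == "colonized"]  # levels sort bare first
    x2 <- tbl[[pn]][tbl$group == "bare"]
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    expect_equal(out$F[out$parameter == pn], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(out$p_value[out$parameter == pn], tt$p.value,
                 tolerance = 1e-10)
    fit <- stats::aov(tbl[[pn]] ~ factor(tbl$group))
    expect_equal(out$F[out$parameter == pn],
                 stats::anova(fit)$`F value`[1], tolerance = 1e-10)
  }
})

test_that("identical groups are never significant; constant columns flagged", {
  x <- c(rnorm(10, 5))
  tbl <- data.frame(group = rep(c("a", "b"), each = 10),
                    same = c(x, x), const = 1)
  out <- screen_parameters(tbl)
  expect_equal(out$F[out$parameter == "same"], 0, tolerance = 1e-12)
  expect_false(out$significant[out$parameter == "same"])
  expect_true(out$degenerate[out$parameter == "const"])
  expect_true(is.na(out$p_value[out$parameter == "const"]))
  expect_error(screen_parameters(data.frame(group = c("a", "b"), v = 1:2)),
               "at least 2")
  expect_error(screen_parameters(data.frame(v = 1:4)), "group")
})

test_that("screening at the configured group contrast matches analytic power", {
  cfg <- study_config()
  nsim <- 300
  hits <- 0L
  for (k in seq_len(nsim)) {
    tbl <- gen_feature_table(cfg, seed = 9000 + k)
    out <- screen_parameters(tbl)
    hits <- hits + out$significant[out$parameter == "S_v"]
  }
  n <- 21
  d <- (203.94 - 163.63) / sqrt((49.14^2 + 55.86^2) / 2)
  ncp <- d / sqrt(2 / n)
  pow <- 1 - stats::pf(stats::qf(0.95, 1, 2 * n - 2), 1, 2 * n - 2,
                       ncp = ncp^2)
  expect_equal(hits / nsim, pow, tolerance = 0.1)
})

test_that("multiplicity adjustment is off by default but available", {
  set.seed(11)
  tbl <- gen_feature_table(study_config(), seed = 4)
  raw <- screen_parameters(tbl)
  bon <- screen_parameters(tbl, p_adjust = "bonferroni")
  ok <- !is.na(raw$p_value)
  expect_true(all(bon$p_value[ok] >= raw$p_value[ok]))
})

test_that("biomass comparison reports the ratio, ANOVA, Tukey and normality pieces", {
  ds <- gen_biomass(study_config(), seed = 2)
  rep <- compare_biomass(ds)
  expect_equal(rep$df, c(1, 70))
  expect_true(rep$significant)
  expect_equal(rep$ratio_of_means, 1.86 / 0.50, tolerance = 0.25)
  expect_length(rep$tukey_lanes, 2)
  expect_true(all(vapply(rep$tukey_lanes, nrow, integer(1)) == 6))  # 4 lanes
  expect_true(is.finite(rep$anderson_darling$statistic))
  expect_gte(rep$anderson_darling$p_value, 0)
  # the configured level means reproduce the reference ratio
  expect_equal(round(1.86 / 0.50, 1), 3.7)
})

test_that("biomass main effect is invariant to lane and trial relabeling", {
  ds <- gen_biomass(study_config(), seed = 8)
  f0 <- compare_biomass(ds)$F
  set.seed(1)
  ds2 <- ds
  for (lv in levels(ds2$level)) {
    sel <- ds2$level == lv
    ds2$lane[sel] <- sample(ds2$lane[sel])
    ds2$trial[sel] <- sample(ds2$trial[sel])
  }
  expect_equal(compare_biomass(ds2)$F, f0, tolerance = 1e-12)
})

test_that("biomass comparison keeps the type-I error near alpha under the null", {
  cfg <- study_config(biomass_level1 = c(1, 0.3), biomass_level2 = c(1, 0.3))
  rej <- 0L
  nsim <- 400
  for (k in seq_len(nsim)) {
    ds <- gen_biomass(cfg, seed = 5000 + k)
    fit <- stats::aov(biomass ~ level, data = ds)
    rej <- rej + (stats::anova(fit)$`Pr(>F)`[1] < 0.05)
  }
  expect_equal(rej / nsim, 0.05, tolerance = 0.6)  # 0.02 .. 0.08
})

test_that("degenerate biomass designs error out", {
  ds <- gen_biomass(study_config(), seed = 3)
  expect_error(compare_biomass(ds[ds$level == "1", ]), "two treatment")
  ds$biomass[1] <- -1
  expect_error(compare_biomass(ds), "non-negative")
})

test_that("hill localization returns the site fraction and attract ratio", {
  z <- matrix(1000, 30, 30)
  z[1:15, ] <- 4000                      # the top half is hill-class
  hm <- heightmap(z, 5, 5)
  sites <- data.frame(row = c(rep(3, 8), rep(20, 2)),
                      col = c(2:9, 4:5))
  out <- hill_localization(hm, sites)
  expect_equal(out$fraction_on_hills, 80)
  expect_identical(nrow(out$site_labels), 10L)
  # all sites high -> 100%; half deep -> bounded by 50%
  all_high <- data.frame(row = rep(2, 5), col = 1:5)
  expect_equal(hill_localization(hm, all_high)$fraction_on_hills, 100)
  zlow <- z; zlow[16:30, ] <- -100
  hm2 <- heightmap(zlow, 5, 5)
  half <- data.frame(row = c(2, 2, 20, 20), col = c(1, 2, 1, 2))
  expect_lte(hill_localization(hm2, half)$fraction_on_hills, 50)
  expect_error(hill_localization(hm, sites[0, ]), "empty")
})

test_that("the per-feature attract ratio counts hills with and without sites", {
  set.seed(6)
  n <- 60
  z <- matrix(rnorm(n * n, 0, 10), n, n)
  for (ctr in list(c(15, 15), c(15, 45), c(45, 15), c(45, 45))) {
    d2 <- outer((1:n - ctr[1])^2, (1:n - ctr[2])^2, `+`)
    z <- z + 5000 * exp(-d2 / 30)
  }
  hm <- preprocess(heightmap(z, 5, 5))
  hills <- wolf_prune(watershed_segment(hm, "hill"), hm,
                      segmentation_config(0.2, kind = "hill"))
  sites <- data.frame(row = c(15, 15), col = c(15, 45))  # two of the bumps
  out <- hill_localization(hm, sites, hill_features = hills)
  expect_true(is.finite(out$hill_attract_ratio) ||
                is.infinite(out$hill_attract_ratio))
  n_hills <- length(setdiff(unique(as.vector(hills$labels)), 0L))
  if (n_hills > 2) expect_equal(out$hill_attract_ratio, 2 / (n_hills - 2))
})
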