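checkerboard <- function(n = 16) {
  outer(1:n, 1:n, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
}

test_that("height parameters have their closed-form values on a checkerboard", {
  hp <- height_params(hm_fixture(checkerboard()))
  expect_equal(hp$S_a, 1); expect_equal(hp$S_q, 1)
  expect_equal(hp$S_sk, 0); expect_equal(hp$S_ku, 1)
  expect_equal(hp$S_p, 1); expect_equal(hp$S_v, 1); expect_equal(hp$S_z, 2)
})

test_that("amplitude parameters are homogeneous of degree one, shape ones invariant", {
  set.seed(21)
  z <- matrix(rnorm(24 * 24), 24, 24); z <- z - mean(z)
  for (c in c(0.5, 3, 120)) {
    a <- height_params(hm_fixture(z)); b <- height_params(hm_fixture(c * z))
    for (nm in c("S_a", "S_q", "S_p", "S_v", "S_z"))
      expect_equal(b[[nm]], c * a[[nm]], tolerance = 1e-12)
    expect_equal(b$S_sk, a$S_sk, tolerance = 1e-12)
    expect_equal(b$S_ku, a$S_ku, tolerance = 1e-12)
    expect_equal(smr(hm_fixture(c * z)), smr(hm_fixture(z)))
    cva <- material_ratio_curve(hm_fixture(z))
    cvb <- material_ratio_curve(hm_fixture(c * z))
    sta <- stratified_params(cva); stb <- stratified_params(cvb)
    expect_equal(stb$S_k, c * sta$S_k, tolerance = 1e-9)
    expect_equal(stb$S_mr1, sta$S_mr1, tolerance = 1e-9)
    va <- volume_params(cva); vb <- volume_params(cvb)
    expect_equal(vb$V_vc, c * va$V_vc, tolerance = 1e-9)
  }
})

test_that("all curve-based parameters equal brute-force oracles to 1e-9 relative", {
  for (seed in c(5, 17)) {
    set.seed(seed)
    z <- matrix(rnorm(32 * 32, 0, 40), 32, 32); z <- z - mean(z)
    hm <- hm_fixture(z)
    hp <- height_params(hm); ohp <- oracle_height_params(z)
    for (nm in names(ohp))
      expect_equal(hp[[nm]], ohp[[nm]], tolerance = 1e-9)
    expect_equal(smr(hm), oracle_smr(z), tolerance = 1e-12)
    curve <- material_ratio_curve(hm)
    for (c0 in quantile(z, c(0.1, 0.5, 0.9)))
      expect_equal(100 * mean(z >= c0), oracle_mr_at(z, c0))
    fp <- functional_params(curve); ofp <- oracle_functional(z)
    expect_equal(fp$S_mc, ofp$S_mc, tolerance = 1e-9)
    expect_equal(fp$S_xp, ofp$S_xp, tolerance = 1e-9)
    vp <- volume_params(curve); ovp <- oracle_volume(z)
    for (nm in names(ovp))
      expect_equal(vp[[nm]], ovp[[nm]], tolerance = 1e-9)
    st <- stratified_params(curve); ost <- oracle_stratified(z)
    for (nm in names(ost))
      expect_equal(st[[nm]], ost[[nm]], tolerance = 1e-9)
  }
})

test_that("material ratio curve is monotone with correct end conventions", {
  set.seed(31)
  z <- matrix(rnorm(400), 20, 20); z <- z - mean(z)
  curve <- material_ratio_curve(hm_fixture(z))
  expect_true(all(diff(curve$mr) >= 0))        # mr grows as section drops
  expect_equal(curve$mr[length(curve$mr)], 100)  # at the minimum height
  expect_equal(curve$mr[1], 100 * mean(z >= max(z)))
  expect_error(material_ratio_curve(hm_fixture(z), n_levels = 1), "at least")
})

test_that("Smr follows the material-at-mean-height convention", {
  expect_equal(smr(hm_fixture(matrix(0, 8, 8))), 100)   # flat surface
  expect_equal(smr(hm_fixture(checkerboard())), 50)
  # symmetric Gaussian surface: about half the material above the mean
  set.seed(8)
  z <- matrix(rnorm(200 * 200), 200, 200); z <- z - mean(z)
  expect_equal(smr(hm_fixture(z)), 50, tolerance = 0.02)
})

test_that("functional parameters behave on ramps, flats and normal surfaces", {
  a <- 10
  ramp <- matrix(seq(a, -a, length.out = 64 * 64), 64, 64)
  fp <- functional_params(material_ratio_curve(hm_fixture(ramp)))
  expect_equal(fp$S_xp, 0.95 * a, tolerance = 0.01)
  flat <- functional_params(material_ratio_curve(hm_fixture(matrix(0, 8, 8))))
  expect_equal(flat$S_xp, 0)
  set.seed(12)
  z <- matrix(rnorm(300 * 300), 300, 300); z <- z - mean(z)
  hm <- hm_fixture(z)
  fp2 <- functional_params(material_ratio_curve(hm))
  expect_equal(fp2$S_xp, 1.96 * height_params(hm)$S_q, tolerance = 0.03)
  expect_error(functional_params(material_ratio_curve(hm), p = 60, q = 50),
               "smaller")
})

test_that("ramp material ratio curve is linear with mr(mean) = 50%", {
  a <- 5
  ramp <- matrix(seq(a, -a, length.out = 50 * 50), 50, 50)
  hm <- hm_fixture(ramp)
  expect_equal(smr(hm), 50, tolerance = 0.1)
  curve <- material_ratio_curve(hm)
  fitres <- stats::lm(curve$mr ~ curve$levels)$residuals
  expect_lt(max(abs(fitres)), 0.2)
})

test_that("volume parameters: flat is zero, checkerboard void volume is exact", {
  flat <- volume_params(material_ratio_curve(hm_fixture(matrix(0, 8, 8))))
  for (nm in names(flat)) expect_equal(flat[[nm]], 0, tolerance = 1e-9)
  cb <- material_ratio_curve(hm_fixture(checkerboard(32)))
  vv0 <- volume_params(cb, p = 0.0001, q = 80)$V_v
  expect_equal(vv0, 1, tolerance = 0.01)   # mean depth below the top plane
  set.seed(4)
  z <- matrix(rnorm(15 * 15), 15, 15); z <- z - mean(z)
  vp <- volume_params(material_ratio_curve(hm_fixture(z)))
  expect_true(all(unlist(vp) >= 0))
})

test_that("stratified construction is exact on a linear curve and degenerates cleanly", {
  a <- 8
  ramp <- matrix(seq(a, -a, length.out = 80 * 80), 80, 80)
  st <- stratified_params(material_ratio_curve(hm_fixture(ramp)))
  expect_equal(st$S_k, 2 * a, tolerance = 0.05)
  expect_equal(st$S_pk, 0, tolerance = 0.02)
  expect_equal(st$S_vk, 0, tolerance = 0.02)
  expect_equal(st$S_mr1, 0, tolerance = 0.3)
  expect_equal(st$S_mr2, 100, tolerance = 0.3)
  flat <- stratified_params(material_ratio_curve(hm_fixture(matrix(2, 6, 6))))
  expect_equal(flat$S_k, 0); expect_equal(flat$S_pk, 0)
  expect_equal(flat$S_vk, 0)
  expect_equal(flat$S_mr1, 0); expect_equal(flat$S_mr2, 100)
})

test_that("a deep spike pit raises S_vk and leaves S_pk essentially unchanged", {
  a <- 8
  ramp <- matrix(seq(a, -a, length.out = 64 * 64), 64, 64)
  st0 <- stratified_params(material_ratio_curve(hm_fixture(ramp)))
  spiked <- ramp; spiked[31:33, 31:33] <- spiked[31:33, 31:33] - 200
  spiked <- spiked - mean(spiked)
  st1 <- stratified_params(material_ratio_curve(hm_fixture(spiked)))
  expect_gt(st1$S_vk, st0$S_vk + 0.1)
  expect_equal(st1$S_pk, st0$S_pk, tolerance = 0.05)
})

test_that("spatial parameters resolve isotropy and texture direction", {
  set.seed(77)
  wn <- matrix(rnorm(64 * 64), 64, 64); wn <- wn - mean(wn)
  sp <- spatial_params(hm_fixture(wn, step = 5))
  expect_lt(sp$S_al, 1.5 * 5)          # decays within one sample spacing
  expect_gt(sp$S_tr, 0.8)              # isotropic

  xs <- 0:63
  sine <- matrix(sin(2 * pi * 4 * xs / 64), 64, 64, byrow = TRUE)
  sine <- sine + matrix(rnorm(64 * 64, 0, 1e-6), 64, 64)
  sps <- spatial_params(hm_fixture(sine - mean(sine), step = 5))
  expect_equal(sps$S_td, 90, tolerance = 1.5)  # ridges run along y
  expect_lt(sps$S_tr, 0.2)

  rot <- t(sine)[, 64:1]               # rotate 90 degrees
  spr <- spatial_params(hm_fixture(rot - mean(rot), step = 5))
  expect_equal((spr$S_td - sps$S_td) %% 180, 90, tolerance = 1.5)
  expect_error(spatial_params(hm_fixture(matrix(1:4, 2, 2))), "too small")
})

test_that("compute_all returns the full named 26-parameter set", {
  set.seed(55)
  base <- matrix(rnorm(40 * 40, 0, 10), 40, 40)
  # add a few resolvable pits/hills so feature parameters are defined
  for (ctr in list(c(10, 10), c(10, 30), c(30, 10), c(30, 30), c(20, 20))) {
    d <- sqrt(outer((1:40 - ctr[1])^2, (1:40 - ctr[2])^2, `+`))
    base <- base - 60 * exp(-(d / 3)^2) + 55 * exp(-((d - 9) / 2.5)^2)
  }
  hm <- preprocess(heightmap(base, 5, 5))
  p <- compute_all(hm)
  expect_s3_class(p, "parameter_set")
  expect_length(unclass(p), 26)
  expect_named(p, c("S_q", "S_sk", "S_ku", "S_p", "S_v", "S_z", "S_a",
                    "S_mr", "S_mc", "S_xp", "S_al", "S_tr", "S_td",
                    "V_m", "V_v", "V_mp", "V_mc", "V_vc", "V_vv",
                    "S_k", "S_pk", "S_vk", "S_mr1", "S_mr2",
                    "S_10z", "S_5v"))
  expect_equal(p$S_z, p$S_p + p$S_v, tolerance = 1e-12)
  expect_true(all(is.finite(unlist(p))))
  expect_true(p$S_mr1 <= p$S_mr2)
  expect_gte(p$S_q, p$S_a)
})

test_that("zero-variance surfaces flag undefined shape moments loudly", {
  expect_warning(hp <- height_params(hm_fixture(matrix(0, 5, 5))),
                 "undefined")
  expect_true(is.nan(hp$S_sk) && is.nan(hp$S_ku))
})

test_that("adding a constant then re-leveling changes nothing", {
  set.seed(66)
  z <- matrix(rnorm(144, 0, 7), 12, 12)
  a <- preprocess(heightmap(z, 5, 5))
  b <- preprocess(heightmap(z + 123.4, 5, 5))
  expect_equal(a$z, b$z, tolerance = 1e-9)
})
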