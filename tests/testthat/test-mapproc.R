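# Map levelling, smoothing, correlation, region medians, stripes.

test_that("levelling removes polynomial backgrounds and line offsets", {
  n <- 32
  xh <- (col(matrix(0, n, n)) - (n + 1) / 2) / (n / 2)
  yh <- (row(matrix(0, n, n)) - (n + 1) / 2) / (n / 2)
  poly <- 5 + 3 * xh - 2 * yh + 1.5 * xh^2 * yh + 0.7 * xh^3 - yh^3
  lv <- level_topography(scalar_map(poly, 0.5, "nm"))
  expect_lt(max(abs(lv$values)), 1e-9)

  set.seed(1)
  offs <- matrix(rnorm(n, 0, 10), n, n)       # per-line constants
  lv2 <- level_topography(scalar_map(poly + offs, 0.5, "nm"))
  expect_lt(max(abs(rowMeans(lv2$values))), 1e-9)
})

test_that("levelling is idempotent", {
  geom <- scan_geometry(10, 48)
  tr <- gen_truth_fields(genotype_presets("control"), geom, seed = 13)
  once <- level_topography(tr$topography)
  twice <- level_topography(once)
  expect_lt(max(abs(twice$values - once$values)), 1e-9)
})

test_that("levelling rejects degenerate masks", {
  v <- matrix(rnorm(64), 8, 8)
  mask <- matrix(FALSE, 8, 8)
  mask[1:2, 1:2] <- TRUE
  expect_error(level_topography(scalar_map(v, 1, "nm", mask)), "valid")
})

test_that("smoothing preserves constants and ramps, removes spikes", {
  const <- scalar_map(matrix(7, 16, 16), 0.5, "kPa")
  expect_equal(smooth_map(const)$values, const$values)

  ramp <- scalar_map(matrix(seq(0, 15), 16, 16, byrow = TRUE), 0.5, "nm")
  sm <- smooth_map(ramp)
  inner <- 4:13
  expect_equal(sm$values[inner, inner], ramp$values[inner, inner],
               tolerance = 1e-9)

  spiky <- matrix(10, 16, 16); spiky[8, 8] <- 1000
  sm2 <- smooth_map(scalar_map(spiky, 0.5, "kPa"))
  expect_lt(max(abs(sm2$values - 10)), 1e-9)

  expect_error(smooth_map(scalar_map(matrix(1, 4, 4), 1, "nm"),
                          sg_window = 5), "window")
})

test_that("map correlation covers the exact and null cases", {
  set.seed(3)
  a <- matrix(rnorm(128 * 128), 128, 128)
  sa <- scalar_map(a, 0.156, "nm")
  sb <- scalar_map(-a, 0.156, "kPa", mask = matrix(TRUE, 128, 128))
  expect_equal(map_correlation(sa, sb), -1)
  indep <- scalar_map(matrix(rnorm(128 * 128), 128, 128), 0.156, "kPa")
  expect_lt(abs(map_correlation(sa, indep)), 0.1)
})

test_that("processed synthetic pair keeps the preset correlation", {
  geom <- scan_geometry(20, 128)
  tr <- gen_truth_fields(genotype_presets("control"), geom, seed = 6)
  topo <- smooth_map(level_topography(tr$topography))
  stiff <- smooth_map(tr$stiffness)
  expect_equal(map_correlation(topo, stiff), -0.4, tolerance = 0.1)
})

test_that("region median handles exact and simulated cases", {
  const <- scalar_map(matrix(20, 64, 64), 10 / 64, "kPa")
  expect_equal(region_median(const), 20)

  # half 10 / half 20 split inside the square -> even-count median 15
  split <- matrix(10, 64, 64); split[, 33:64] <- 20
  expect_equal(region_median(scalar_map(split, 10 / 64, "kPa")), 15)

  geom <- scan_geometry(10, 64)
  tr <- gen_truth_fields(genotype_presets("control"), geom, seed = 8)
  expect_equal(region_median(smooth_map(tr$stiffness)), 20,
               tolerance = 0.05)
})

test_that("stripe quantification recovers preset elevations", {
  geom <- scan_geometry(20, 128)
  ctrl <- gen_truth_fields(genotype_presets("control"), geom, seed = 5)
  st <- quantify_stripes(ctrl$stiffness)
  expect_equal(st$elevation_percent, 10, tolerance = 0.2)   # +/- 2 points
  expect_equal(st$stripe_orientation, 90, tolerance = 5)
  expect_lt(st$band_p, 0.01)

  dw <- gen_truth_fields(genotype_presets("dwirs"), geom, seed = 5)
  std <- quantify_stripes(dw$stiffness)
  expect_equal(std$elevation_percent, 7, tolerance = 2 / 7)  # +/- 2 points
})

test_that("stripe-free maps yield no stripes", {
  geom <- scan_geometry(20, 128)
  tn <- gen_truth_fields(genotype_presets("fat2null"), geom, seed = 5)
  st <- quantify_stripes(tn$stiffness)
  expect_identical(st$n_stripes, 0L)
  expect_true(is.na(st$elevation_percent))
  expect_gt(st$band_p, 0.01)
})

test_that("stripe lengths shorten from control to the short-stripe preset", {
  geom <- scan_geometry(20, 128)
  lens <- vapply(c("control", "dwirs"), function(nm) {
    st <- quantify_stripes(gen_truth_fields(genotype_presets(nm), geom,
                                            seed = 6)$stiffness)
    mean(st$stripe_lengths)
  }, numeric(1))
  expect_gt(lens["control"], lens["dwirs"])
})

test_that("elevation is invariant under multiplicative rescaling", {
  geom <- scan_geometry(20, 128)
  tr <- gen_truth_fields(genotype_presets("control"), geom, seed = 7)
  st1 <- quantify_stripes(tr$stiffness)
  scaled <- tr$stiffness
  scaled$values <- scaled$values * 1000    # kPa -> Pa
  st2 <- quantify_stripes(scaled)
  expect_equal(st2$elevation_percent, st1$elevation_percent,
               tolerance = 1e-6)
})
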