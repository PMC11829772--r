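# Center-to-pole ratio statistics and group comparisons.

# Samples engineered to exact means and SEMs: mean 20 SEM 1 and mean 15
# SEM 1 at n = 4 (sd = 2, i.e. deviations +/- sqrt(3)).
center_20_1 <- 20 + sqrt(3) * c(-1, 1, -1, 1)
pole_15_1 <- 15 + sqrt(3) * c(-1, 1, -1, 1)

test_that("ratio and propagated SEM match the closed form", {
  rs <- ratio_sem(center_20_1, pole_15_1)
  expect_equal(rs$ratio, 4 / 3, tolerance = 1e-12)
  expect_equal(rs$sem, (4 / 3) * sqrt((1 / 20)^2 + (1 / 15)^2),
               tolerance = 1e-12)
  expect_equal(rs$sem, 0.11111, tolerance = 1e-4)

  same <- c(10, 10, 10, 10)
  rs2 <- ratio_sem(same, same)
  expect_equal(rs2$ratio, 1)
  expect_equal(rs2$sem, 0)

  x <- c(12, 19, 25, 14)
  expect_equal(ratio_sem(x, x)$ratio, 1)
})

test_that("Welch-Satterthwaite dof matches identities and examples", {
  # symmetric case: nu_eff = 2 (n - 1) exactly
  for (n in c(4, 8, 16)) {
    x <- seq(10, 20, length.out = n)
    expect_equal(welch_satterthwaite_dof(x, 2 * x), 2 * (n - 1),
                 tolerance = 1e-12)
  }

  # a_c = 0.01, a_p = 0.04, n = 8 + 8 -> 0.0025 / (0.0017 / 7) ~ 10.29
  mk <- function(mean, rel_sem, n) {
    sdv <- rel_sem * mean * sqrt(n)
    base <- scale(seq_len(n))[, 1]
    mean + base / sd(base) * sdv
  }
  c8 <- mk(10, 0.1, 8); p8 <- mk(10, 0.2, 8)
  expect_equal(welch_satterthwaite_dof(c8, p8),
               0.05^2 / ((0.0001 + 0.0016) / 7), tolerance = 1e-9)
  expect_equal(welch_satterthwaite_dof(c8, p8), 10.294, tolerance = 1e-4)

  # one vanishing component: nu_eff -> n_c - 1
  p_tiny <- mk(10, 1e-9, 8)
  expect_equal(welch_satterthwaite_dof(c8, p_tiny), 7, tolerance = 1e-4)

  expect_error(welch_satterthwaite_dof(c(1, 2), c(3)), "n >= 2")
})

test_that("dof stays within its algebraic bounds", {
  set.seed(20)
  for (i in 1:50) {
    nc <- sample(3:12, 1); np <- sample(3:12, 1)
    x <- rlnorm(nc, 2, 0.3); y <- rlnorm(np, 2, 0.5)
    d <- welch_satterthwaite_dof(x, y)
    expect_gte(d, min(nc, np) - 1)
    expect_lte(d, nc + np - 2)
  }
})

test_that("ratio test composes and handles degenerate input", {
  rt <- ratio_test(center_20_1, pole_15_1)
  expect_equal(rt$T, (4 / 3 - 1) / rt$sem, tolerance = 1e-12)
  expect_equal(rt$p, 2 * pt(abs(rt$T), rt$dof, lower.tail = FALSE))

  same <- c(10, 10, 10)
  deg <- ratio_test(same, same)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  deg2 <- ratio_test(c(20, 20, 20), c(10, 10, 10))
  expect_true(deg2$degenerate)
  expect_equal(deg2$p, 0)
})

test_that("ratio test is invariant under common rescaling", {
  set.seed(21)
  x <- rlnorm(8, 3, 0.2); y <- rlnorm(8, 2.8, 0.2)
  a <- ratio_test(x, y)
  b <- ratio_test(1000 * x, 1000 * y)   # kPa -> Pa
  expect_equal(a$ratio, b$ratio)
  expect_equal(a$T, b$T)
  expect_equal(a$p, b$p)
})

test_that("type-I error is calibrated at the nominal level", {
  cal <- ratio_test_calibration(n_reps = 10000, n = 8, cv = 0.2,
                                alpha = 0.05, seed = 7)
  expect_equal(cal$type1, 0.05, tolerance = 0.01 / 0.05)
  # p values approximately uniform under the null
  expect_equal(mean(cal$p), 0.5, tolerance = 0.02)
})

test_that("group comparisons behave on identical, shifted and null data", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(group_compare(x, x, "welch_t"), 1)
  expect_equal(group_compare(c(-1, 0, 1, 0), method = "one_sample_t_zero"),
               1)

  # 3-SD shift at n = 10: power at the 0.001 level is ~0.99
  set.seed(22)
  hits <- mean(replicate(500, {
    a <- rnorm(10); b <- rnorm(10, 3)
    group_compare(a, b, "welch_t") < 0.001
  }))
  expect_gt(hits, 0.95)

  w <- group_compare(rnorm(10), rnorm(10, 5), "wilcoxon_rank_sum")
  expect_lt(w, 0.001)
})

test_that("preset chambers reproduce the significance pattern", {
  ps <- vapply(c("control", "dwirs", "fat2null"), function(nm) {
    s <- gen_chamber_samples(genotype_presets(nm), n_chambers = 8, seed = 3)
    ratio_test(s$center, s$pole)$p
  }, numeric(1))
  expect_lt(ps["control"], 0.05)
  expect_lt(ps["dwirs"], 0.05)
  expect_gt(ps["fat2null"], 0.05)
})
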