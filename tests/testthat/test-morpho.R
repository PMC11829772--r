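# Orientation distributions, S_AP, fiber lengths, aspect ratios.

test_that("S_AP endpoints and the uniform case are exact", {
  expect_equal(order_parameter_SAP(delta_distribution(90)), 1)
  expect_equal(order_parameter_SAP(delta_distribution(0)), -1)
  expect_equal(order_parameter_SAP(delta_distribution(180)), -1)
  expect_equal(order_parameter_SAP(uniform_distribution()), 0,
               tolerance = 1e-9)
  expect_equal(order_parameter_SAP(delta_distribution(45)), 0,
               tolerance = 1e-12)
})

test_that("unnormalized distributions are normalized with a warning", {
  d <- list(bin_centers = c(89, 91), frequency = c(2, 2))
  expect_warning(s <- order_parameter_SAP(d), "normaliz")
  expect_equal(s, cos(2 * pi / 180), tolerance = 1e-12)
})

test_that("orientation distribution peaks at the fiber angle", {
  fi <- gen_fiber_image(300, mean_angle = 90, kappa = Inf,
                        length_mean = 4, image_size = 192, seed = 2)
  od <- orientation_distribution(fi$image)
  peak <- od$bin_centers[which.max(od$frequency)]
  expect_lt(min(abs(peak - 90), 180 - abs(peak - 90)), 4)
  expect_equal(sum(od$frequency), 1, tolerance = 1e-9)
})

test_that("orientation estimation is equivariant in the mean angle", {
  circ_mean <- function(od) {
    (atan2(sum(od$frequency * sin(2 * od$bin_centers * pi / 180)),
           sum(od$frequency * cos(2 * od$bin_centers * pi / 180))) / 2 *
       180 / pi) %% 180
  }
  m1 <- circ_mean(orientation_distribution(
    gen_fiber_image(400, 60, Inf, 4, 192, seed = 3)$image))
  m2 <- circ_mean(orientation_distribution(
    gen_fiber_image(400, 90, Inf, 4, 192, seed = 3)$image))
  expect_equal((m2 - m1) %% 180, 30, tolerance = 2)
})

test_that("isotropic fields are flat and S_AP rises with concentration", {
  iso <- orientation_distribution(
    gen_fiber_image(500, 90, 0, 4, 256, seed = 4)$image)
  expect_lt(max(iso$frequency) / max(min(iso$frequency), 1e-6), 3)

  sap <- vapply(c(0, 1, 4, 64), function(k) {
    order_parameter_SAP(orientation_distribution(
      gen_fiber_image(400, 90, k, 4, 192, seed = 5)$image))
  }, numeric(1))
  expect_true(all(diff(sap) > 0))
  expect_lt(abs(sap[1]), 0.2)
  expect_gt(sap[4], 0.8)
})

test_that("S_AP flips sign when a symmetric distribution rotates 90 deg", {
  d <- list(bin_centers = c(80, 90, 100), frequency = c(0.25, 0.5, 0.25))
  d90 <- list(bin_centers = (d$bin_centers + 90) %% 180,
              frequency = d$frequency)
  expect_equal(order_parameter_SAP(d90), -order_parameter_SAP(d),
               tolerance = 1e-12)
})

test_that("flat images are rejected", {
  expect_error(orientation_distribution(matrix(1, 32, 32)), "flat")
})

test_that("fiber lengths recover straight-fiber ground truth", {
  img <- matrix(0, 256, 256)
  img[128, 29:228] <- 1                       # 200 px * 0.1 um = 20 um
  fl <- fiber_lengths(img, pixel_size = 0.1, threshold_method = "quantile",
                      threshold_quantile = 0.98)
  expect_equal(fl$n_fibers, 1L)
  expect_equal(fl$lengths, 20, tolerance = 0.05)

  # 45-degree fiber measured through the diagonal chain metric
  img2 <- matrix(0, 256, 256)
  for (i in 0:140) img2[58 + i, 58 + i] <- 1  # 140*sqrt(2)*0.1 ~ 19.8 um
  fl2 <- fiber_lengths(img2, pixel_size = 0.1,
                       threshold_method = "quantile",
                       threshold_quantile = 0.98)
  expect_equal(fl2$lengths, 140 * sqrt(2) * 0.1, tolerance = 0.05)
})

test_that("blank images yield no fibers and preset ordering holds", {
  blank <- matrix(0, 64, 64)
  expect_identical(fiber_lengths(blank, 0.1)$n_fibers, 0L)

  mean_len <- vapply(c(8, 2.5), function(L) {
    fi <- gen_fiber_image(60, 90, 8, L, 256, seed = 6, background_sd = 0.02)
    fiber_lengths(fi$image, pixel_size = fi$pixel_size)$mean_length
  }, numeric(1))
  expect_gt(mean_len[1], mean_len[2])
})

test_that("aspect ratio matches ellipse geometry and is rotation
           invariant", {
  e <- gen_chamber_mask(230, 100, 256)
  expect_equal(aspect_ratio(e$mask), 2.3, tolerance = 0.02 / 2.3)
  c <- gen_chamber_mask(120, 120, 256)
  expect_equal(aspect_ratio(c$mask), 1, tolerance = 0.01)

  # rotated ellipse: same ratio within 0.01
  n <- 256; px <- 1
  xs <- (col(matrix(0, n, n)) - (n + 1) / 2) * px
  ys <- (row(matrix(0, n, n)) - (n + 1) / 2) * px
  th <- 35 * pi / 180
  xr <- cos(th) * xs + sin(th) * ys
  yr <- -sin(th) * xs + cos(th) * ys
  rot <- (xr / 115)^2 + (yr / 50)^2 <= 1
  expect_equal(aspect_ratio(rot), aspect_ratio(e$mask), tolerance = 0.005)
})
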