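# Synthetic generators: determinism, ground-truth contracts, limit cases.

test_that("truth fields honour the preset contract", {
  geom <- scan_geometry(20, 128)
  tr <- gen_truth_fields(genotype_presets("control"), geom, seed = 42)
  m <- tr$labels$stripe_mask
  v <- tr$stiffness$values

  # stripe-pixel median over bulk-pixel median ~ 1 + elevation
  expect_equal(median(v[m]) / median(v[!m]), 1.10, tolerance = 0.015)
  # bulk median at the preset level
  expect_equal(median(v[!m]), 20, tolerance = 0.02)
  # exact sample correlation between clean topography and stiffness
  expect_equal(cor(as.vector(tr$labels$topo_clean), as.vector(v)), -0.4,
               tolerance = 1e-10)

  # zero-elevation preset: empty stripe mask, pure bulk field
  tn <- gen_truth_fields(genotype_presets("fat2null"), geom, seed = 42)
  expect_false(any(tn$labels$stripe_mask))
  expect_equal(tn$stiffness$values, tn$labels$bulk_field)
})

test_that("generators are deterministic for a fixed seed", {
  geom <- scan_geometry(10, 32)
  a <- gen_truth_fields(genotype_presets("control"), geom, seed = 7)
  b <- gen_truth_fields(genotype_presets("control"), geom, seed = 7)
  expect_identical(a$stiffness$values, b$stiffness$values)
  expect_identical(a$topography$values, b$topography$values)

  fa <- gen_force_volume(a$stiffness, a$topography, seed = 3)
  fb <- gen_force_volume(b$stiffness, b$topography, seed = 3)
  expect_identical(fa$force, fb$force)

  ia <- gen_fiber_image(50, 90, 4, 5, 64, seed = 9)
  ib <- gen_fiber_image(50, 90, 4, 5, 64, seed = 9)
  expect_identical(ia$image, ib$image)

  ra <- gen_rotation_frames(0.5, 30, 20, 64, seed = 11)
  rb <- gen_rotation_frames(0.5, 30, 20, 64, seed = 11)
  expect_identical(ra$frame1, rb$frame1)
})

test_that("stripe clipping warns and invalid presets are rejected", {
  geom <- scan_geometry(5, 32)
  expect_warning(gen_truth_fields(genotype_presets("control"), geom, 1),
                 "clipped")
  expect_error(genotype_preset("x", bulk_modulus = NaN,
                               stripe_elevation = 0, stripe_length = 0))
  expect_error(genotype_preset("x", bulk_modulus = -1,
                               stripe_elevation = 0, stripe_length = 0))
  expect_error(genotype_preset("x", bulk_modulus = 10,
                               stripe_elevation = 0, stripe_length = 0,
                               topo_stiffness_corr = 1.5))
})

test_that("force model evaluates to the closed-form values", {
  p <- probe_params()
  C <- hertz_coefficient(20, p)
  # C ~ 13.9 kPa equivalent: 0.0139 pN/nm^2; F(200 nm) ~ 557 pN
  expect_equal(C, 0.0139164, tolerance = 1e-5)
  expect_equal(C * 200^2, 556.66, tolerance = 1e-4)
  expect_equal(hertz_modulus(C, p), 20, tolerance = 1e-12)

  # E -> 0 gives a flat zero-force curve (up to noise)
  zero <- scalar_map(matrix(1e-9, 4, 4), 0.5, "kPa")
  topo <- scalar_map(matrix(0, 4, 4), 0.5, "nm")
  fv <- gen_force_volume(zero, topo, p, force_noise_sd = 0, seed = 1)
  expect_lt(max(fv$force, na.rm = TRUE), 1e-3)
  expect_true(all(fv$unreachable))
})

test_that("force volume curves match the contact model pointwise", {
  p <- probe_params()
  E <- scalar_map(matrix(20, 4, 4), 0.5, "kPa")
  topo <- scalar_map(matrix(0, 4, 4), 0.5, "nm")
  fv <- gen_force_volume(E, topo, p, z_step = 2, force_noise_sd = 0, seed = 1)
  cv <- fv_curve(fv, 2, 3)
  C <- hertz_coefficient(20, p)
  k <- p$spring_constant * 1000
  # invert each sampled force and check z = z_contact + delta + F/k
  f <- cv$force[cv$force > 1]
  z <- cv$z[cv$force > 1]
  delta <- sqrt(f / C)
  expect_equal(z, (fv$z_ref - 0) + delta + f / k, tolerance = 1e-9)
})

test_that("trail and chamber-mask generators follow closed forms", {
  # one full turn in 10 h at 36 deg/h
  expect_equal(gen_trail(36, 10, 300)$trail_length, 300)
  expect_equal(gen_trail(0, 10, 300)$trail_length, 0)
  # 82 deg/h for 10 h wraps: arc / C = 227.8%
  expect_equal(trail_ratio(gen_trail(82, 10, 300)), 227.7778,
               tolerance = 1e-6)

  cm <- gen_chamber_mask(230, 100, 256)
  area_um2 <- sum(cm$mask) * cm$pixel_size^2
  expect_equal(area_um2, pi * 230 * 100 / 4, tolerance = 0.01)
  circle <- gen_chamber_mask(80, 80, 128)
  expect_equal(aspect_ratio(circle$mask), 1, tolerance = 0.01)
})

test_that("axial von Mises sampler covers its limit cases", {
  expect_equal(rvonmises_axial(5, 90, Inf), rep(90, 5))
  set.seed(1)
  iso <- rvonmises_axial(2000, 90, 0)
  expect_gt(suppressWarnings(ks.test(iso / 180, "punif"))$p.value, 0.01)
  conc <- rvonmises_axial(500, 90, 50)
  expect_lt(diff(range(conc)), 40)
  expect_equal(mean(conc), 90, tolerance = 2)
})

test_that("rotation frames rotate by the commanded angle", {
  fr <- gen_rotation_frames(0, dt = 30, radius = 20, image_size = 64,
                            seed = 2, noise_sd = 0)
  expect_identical(fr$frame0, fr$frame1)
  fr2 <- gen_rotation_frames(0.5, dt = 30, radius = 20, image_size = 64,
                             seed = 2, noise_sd = 0)
  expect_equal(fr2$angle, 0.5 * 30 / 20)
  expect_gt(max(abs(fr2$frame0 - fr2$frame1)), 0.1)
})
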