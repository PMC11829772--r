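# Force-curve processing: contact detection, indentation, model fitting.

test_that("contact threshold is 20% of the setpoint and is interpolated", {
  p <- probe_params()
  expect_equal(0.2 * p$setpoint_force * 1000, 120)  # pN

  cv <- make_curve(20, zc = 150)
  h <- detect_contact_point(cv)
  C <- hertz_coefficient(20, p)
  # the crossing sits sqrt(thr/C) past the true contact (height frame:
  # detected surface is lower by that offset)
  offset <- sqrt(120 / C)
  expect_equal(as.numeric(h), -(150) - offset, tolerance = 2)

  # fit-based contact estimate recovers the true contact within a z-step
  hc <- estimate_contact_point(cv)
  expect_equal(as.numeric(hc), -150, tolerance = 2)
})

test_that("curves that never reach the threshold are invalid", {
  p <- probe_params()
  z <- seq(0, 300, by = 2)
  cv <- force_curve(z, rep(0.05, length(z)) * 1000 * 0, p)  # flat zero
  expect_true(is.na(detect_contact_point(cv)))
  fit <- fit_force_curve(cv)
  expect_false(fit$valid)

  # max force 50 pN < 120 pN threshold -> invalid
  cv2 <- force_curve(z, pmin(pmax(z - 150, 0)^2 * 0.01, 50), p)
  expect_true(is.na(detect_contact_point(cv2)))
})

test_that("non-monotonic z is rejected", {
  expect_error(force_curve(c(1:20, 19), rep(0, 21)), "increasing")
})

test_that("indentation limits behave physically", {
  p <- probe_params()
  cv <- make_curve(20, zc = 150)
  ind <- compute_indentation(cv, -150)
  C <- hertz_coefficient(20, p)
  # delta at the setpoint matches the model inversion within a z-step
  expect_equal(max(ind$indentation), sqrt(max(ind$force) / C),
               tolerance = 2)

  # rigid cantilever: delta = z - z_contact exactly
  stiffp <- probe_params(spring_constant = 1e9)
  cvr <- make_curve(20, zc = 150, probe = stiffp)
  indr <- compute_indentation(cvr, -150)
  expect_equal(indr$indentation,
               cvr$z[cvr$z > 150] - 150, tolerance = 1e-9)

  # zero force everywhere: delta equals the z displacement
  z <- seq(0, 100, by = 2)
  cv0 <- force_curve(z, rep(0, length(z)), p)
  ind0 <- compute_indentation(cv0, -50)
  expect_equal(ind0$indentation, z[z > 50] - 50)
})

test_that("noiseless round trip recovers the modulus to machine precision", {
  for (E in c(7, 11, 20)) {
    cv <- make_curve(E, zc = 150)
    fit <- fit_force_curve(cv)
    expect_true(fit$valid)
    expect_equal(fit$youngs_modulus, E, tolerance = 1e-9)
  }
})

test_that("restricting the fit range does not change an exact quadratic", {
  cv <- make_curve(20, zc = 150)
  contact <- estimate_contact_point(cv)
  ind <- compute_indentation(cv, contact)
  full <- fit_hertz_sneddon(ind$indentation, ind$force, cv$probe, 500)
  # 50 nm indentation range instead of the 500 pN force range
  sel <- ind$indentation <= 50
  short <- fit_hertz_sneddon(ind$indentation[sel], ind$force[sel],
                             cv$probe, 500)
  expect_equal(short$youngs_modulus, full$youngs_modulus, tolerance = 1e-9)
})

test_that("fit is scale-equivariant and monotone in stiffness", {
  cv <- make_curve(15, zc = 150)
  contact <- estimate_contact_point(cv)
  ind <- compute_indentation(cv, contact)
  base <- fit_hertz_sneddon(ind$indentation, ind$force, cv$probe,
                            fit_max_force = Inf)
  for (s in c(0.5, 2, 3)) {
    scaled <- fit_hertz_sneddon(ind$indentation, s * ind$force, cv$probe,
                                fit_max_force = Inf)
    expect_equal(scaled$youngs_modulus, s * base$youngs_modulus,
                 tolerance = 1e-9)
  }
  fits <- vapply(c(5, 10, 20, 40), function(E) {
    fit_force_curve(make_curve(E, zc = 150))$youngs_modulus
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("median modulus over noisy curves is within 3% of truth", {
  p <- probe_params()
  n <- 32   # 1024 curves
  E <- scalar_map(matrix(20, n, n), 10 / n, "kPa")
  topo <- scalar_map(matrix(0, n, n), 10 / n, "nm")
  fv <- gen_force_volume(E, topo, p, z_step = 2, force_noise_sd = 10,
                         seed = 5)
  fit <- fit_force_volume(fv)
  med <- median(fit$stiffness$values, na.rm = TRUE)
  expect_equal(med, 20, tolerance = 0.03)
})

test_that("contact-based topography is stiffness-independent, the
           threshold surface is not", {
  geom <- scan_geometry(10, 24)
  tr <- gen_truth_fields(genotype_presets("control"), geom, seed = 9)
  fv <- gen_force_volume(tr$stiffness, tr$topography, force_noise_sd = 0,
                         seed = 1)
  fit <- fit_force_volume(fv)
  # contact surface reproduces the true topography almost exactly
  expect_lt(max(abs(fit$topography_contact$values - tr$topography$values)),
            0.1)
  # threshold surface carries the sqrt(thr/C) stiffness-dependent offset
  resid <- fit$topography$values - tr$topography$values
  expect_gt(sd(resid), 1)
  # the offset shrinks as stiffness grows, so the apparent height error
  # rises monotonically with local stiffness
  expect_gt(cor(as.vector(resid), as.vector(tr$stiffness$values)), 0.9)
})
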