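# Synthetic data generators.
#
# Every generator is deterministic for a fixed seed and also returns the
# ground-truth labels the downstream quantifications are checked against.

#' Generate ground-truth stiffness and topography fields
#'
#' The stiffness field is a lognormal bulk (median = `bulk_modulus`,
#' pixel CV = `noise_cv`) multiplied by `1 + stripe_elevation` inside stripe
#' segments: elongated bands of width `stripe_width` whose long axis lies at
#' `stripe_angle` degrees from the AP (x) axis, spaced `stripe_spacing`
#' apart, broken into segments of length `stripe_length` separated by
#' `stripe_gap` gaps. The topography is built from a standardized copy of
#' the stiffness field plus an independent smooth field, with the mixing
#' weight chosen so that the sample Pearson correlation with stiffness
#' equals `topo_stiffness_corr` exactly; a random 3rd-order polynomial
#' tilt/bow and per-scan-line offsets/slopes are then added so the levelling
#' stage has something to remove.
#'
#' @param preset a [genotype_preset].
#' @param geom a [scan_geometry].
#' @param seed integer seed.
#' @param stripe_width stripe width (um).
#' @param stripe_gap gap between consecutive segments along a stripe (um).
#' @param topo_amplitude standard deviation of the clean topography (nm).
#' @param topo_corr_len correlation length of the smooth topography
#'   component (um).
#' @return list with `stiffness` and `topography` ([scalar_map]s; the
#'   topography includes tilt and line offsets) and `labels` (ground truth:
#'   binary `stripe_mask`, clean topography `topo_clean`, the stripe-free
#'   `bulk_field`, and the preset).
#' @export
gen_truth_fields <- function(preset, geom, seed,
                             stripe_width = 1.25, stripe_gap = 1,
                             topo_amplitude = 30, topo_corr_len = 0.8) {
  stopifnot(inherits(preset, "genotype_preset"),
            inherits(geom, "scan_geometry"))
  set.seed(seed)
  n <- geom$n_pixels
  px <- geom$side_length / n
  if (preset$stripe_length > geom$side_length) {
    warning("stripe_length exceeds the scan side; stripes are clipped")
  }

  sdlog <- sqrt(log(1 + preset$noise_cv^2))
  bulk <- matrix(stats::rlnorm(n * n, log(preset$bulk_modulus), sdlog), n, n)

  # stripe mask in physical coordinates (x = column, y = row)
  xy <- list(x = ((col(bulk) - 0.5) * px), y = ((row(bulk) - 0.5) * px))
  th <- preset$stripe_angle * pi / 180
  along  <-  xy$x * cos(th) + xy$y * sin(th)
  across <- -xy$x * sin(th) + xy$y * cos(th)
  mask <- matrix(FALSE, n, n)
  if (preset$stripe_elevation > 0 && preset$stripe_length > 0) {
    sp <- preset$stripe_spacing
    offset <- stats::runif(1, 0, sp)
    d <- (across - offset) - sp * round((across - offset) / sp)
    in_band <- abs(d) <= stripe_width / 2
    band_id <- round((across - offset) / sp)
    period <- preset$stripe_length + stripe_gap
    phases <- stats::runif(diff(range(band_id)) + 1L, 0, period)
    ph <- matrix(phases[band_id - min(band_id) + 1L], n, n)
    in_seg <- ((along - ph) %% period) < preset$stripe_length
    mask <- in_band & in_seg
  }
  # sub-pixel edge softening only: wider blurs would make the realized
  # stripe-pixel elevation fall short of the preset for short segments
  soft <- gaussian_blur(matrix(as.numeric(mask), n, n), 0.35)
  stiffness <- bulk * (1 + preset$stripe_elevation * soft)

  # topography: exact-correlation mixture of the stiffness field and an
  # independent field, orthogonalized sample-wise. The independent field
  # mixes pixel-scale (measurement) roughness and a smooth ridge field in
  # the same variance proportions as the stiffness field itself, so the
  # correlation survives any common smoothing applied to both maps
  # downstream (a purely smooth independent field would make the
  # correlation collapse once the white component of the stiffness copy
  # is filtered out).
  std <- function(v) (v - mean(v)) / stats::sd(v)
  s <- std(as.vector(stiffness))
  s_sm <- gaussian_blur(stiffness, 2)
  k2sum <- 1 / (4 * pi * 2^2)       # white-noise leakage through the blur
  structure_share <- min(max(stats::var(as.vector(s_sm)) /
                               stats::var(as.vector(stiffness)) - k2sum,
                             0.01), 0.5)
  g_smooth <- std(as.vector(gaussian_blur(matrix(stats::rnorm(n * n), n, n),
                                          topo_corr_len / px)))
  g_white <- std(stats::rnorm(n * n))
  g <- sqrt(1 - structure_share) * g_white + sqrt(structure_share) * g_smooth
  g <- std(g)
  g <- g - sum(g * s) / sum(s * s) * s        # remove sample covariance
  g <- g / stats::sd(g)
  rho <- preset$topo_stiffness_corr
  topo_clean <- topo_amplitude * (rho * s + sqrt(1 - rho^2) * g)
  topo_clean <- matrix(topo_clean, n, n)

  # scanner tilt/bow: random polynomial of total degree 3 (no constant)
  xh <- (xy$x - mean(xy$x)) / (geom$side_length / 2)
  yh <- (xy$y - mean(xy$y)) / (geom$side_length / 2)
  tilt <- matrix(0, n, n)
  for (p in 0:3) for (q in 0:(3 - p)) {
    if (p + q == 0) next
    tilt <- tilt + stats::rnorm(1, 0, 40) * xh^p * yh^q
  }
  line_off <- stats::rnorm(n, 0, 5)      # per fast-axis line (row) offsets
  line_slp <- stats::rnorm(n, 0, 2)      # per-line linear trend across x
  lines <- matrix(line_off, n, n) + matrix(line_slp, n, n) * xh
  topography <- topo_clean + tilt + lines

  list(
    stiffness = scalar_map(stiffness, px, "kPa"),
    topography = scalar_map(topography, px, "nm"),
    labels = list(stripe_mask = mask, topo_clean = topo_clean,
                  bulk_field = bulk, preset = preset, geometry = geom,
                  seed = seed)
  )
}

#' Force-volume container
#'
#' @param z common piezo-extension grid (nm, increasing along approach).
#' @param force matrix of forces (pN), `length(z)` rows by one column per
#'   pixel (column-major pixel order of the `ny x nx` grid); `NA` beyond the
#'   setpoint truncation.
#' @param dim_grid integer vector `c(ny, nx)`.
#' @param probe a [probe_params].
#' @param pixel_size um per pixel.
#' @param z_ref extension origin: a pixel whose surface sits at height `h`
#'   (nm) makes contact at extension `z_ref - h`.
#' @param unreachable logical vector flagging pixels whose curve never
#'   reaches the setpoint.
#' @return object of class `force_volume`.
#' @export
force_volume <- function(z, force, dim_grid, probe, pixel_size, z_ref,
                         unreachable = NULL) {
  stopifnot(length(z) == nrow(force), prod(dim_grid) == ncol(force))
  if (is.null(unreachable)) unreachable <- rep(FALSE, ncol(force))
  structure(list(z = z, force = force, dim_grid = as.integer(dim_grid),
                 probe = probe, pixel_size = pixel_size, z_ref = z_ref,
                 unreachable = unreachable),
            class = "force_volume")
}

#' @export
print.force_volume <- function(x, ...) {
  cat(sprintf("<force_volume> %d x %d pixels, %d z-samples (%.3g nm step)\n",
              x$dim_grid[1], x$dim_grid[2], length(x$z), x$z[2] - x$z[1]))
  invisible(x)
}

#' Simulate a force volume from ground-truth fields
#'
#' For each pixel one approach curve is generated from the pyramidal contact
#' model: beyond contact the force solves F = C * delta^2 with the
#' indentation delta = (z - z_contact) - F/k accounting for cantilever
#' deflection (closed form via the quadratic formula). Gaussian force noise
#' is added everywhere and the curve is truncated once the noiseless force
#' reaches the setpoint.
#'
#' @param stiffness_truth stiffness [scalar_map] (kPa).
#' @param topography_truth topography [scalar_map] (nm); pixel value is the
#'   contact height.
#' @param probe a [probe_params].
#' @param z_step piezo step (nm).
#' @param force_noise_sd Gaussian force noise (pN).
#' @param seed integer seed.
#' @return a [force_volume].
#' @export
gen_force_volume <- function(stiffness_truth, topography_truth,
                             probe = probe_params(), z_step = 2,
                             force_noise_sd = 10, seed = 1) {
  check_congruent(stiffness_truth, topography_truth)
  stopifnot(z_step > 0)
  set.seed(seed)
  E <- as.vector(stiffness_truth$values)
  h <- as.vector(topography_truth$values)
  k <- spring_pN_per_nm(probe)
  C <- hertz_coefficient(E, probe)
  fmax <- setpoint_pN(probe)

  # generous free-approach tail so baseline estimation has a clean
  # pre-contact segment at every pixel
  z_ref <- max(h) + 150
  z_contact <- z_ref - h
  # extension needed to reach the setpoint: indentation + deflection;
  # capped so near-zero moduli (unreachable setpoint) keep the grid finite
  z_end <- z_contact + pmin(sqrt(fmax / C), 2000) + fmax / k
  z <- seq(0, max(z_end) + 2 * z_step, by = z_step)

  u <- outer(z, z_contact, "-")                  # extension past contact
  r <- rep(C / k, each = length(z))
  # stable form of the quadratic-formula root (finite as C -> 0)
  delta <- ifelse(u > 0, 2 * u / (1 + sqrt(pmax(1 + 4 * r * u, 1))), 0)
  f0 <- rep(C, each = length(z)) * delta^2
  force <- f0 + stats::rnorm(length(f0), 0, force_noise_sd)
  force[f0 > fmax] <- NA_real_                   # truncate at setpoint
  dim(force) <- dim(f0) <- dim(u)
  unreachable <- apply(f0, 2, max, na.rm = TRUE) < fmax

  force_volume(z, force, dim(stiffness_truth$values), probe,
               stiffness_truth$pixel_size, z_ref, unreachable)
}

#' Extract one curve from a force volume
#' @param fv a [force_volume].
#' @param i,j pixel row / column (1-based).
#' @return a [force_curve].
#' @export
fv_curve <- function(fv, i, j) {
  idx <- (j - 1L) * fv$dim_grid[1] + i
  f <- fv$force[, idx]
  ok <- !is.na(f)
  force_curve(fv$z[ok], f[ok], fv$probe, z_ref = fv$z_ref)
}

#' Generate a synthetic fiber image
#'
#' Line segments with von Mises distributed orientations (period 180
#' degrees) on a noisy background, emulating stained Collagen-IV
#' fiber-like structures or basal actin bundles.
#'
#' @param n_fibers number of segments.
#' @param mean_angle mean orientation, degrees from the AP (x) axis.
#' @param kappa von Mises concentration (0 = isotropic, `Inf` = delta).
#' @param length_mean mean segment length (um).
#' @param image_size image side in pixels.
#' @param seed integer seed.
#' @param pixel_size um per pixel.
#' @param background_sd Gaussian background noise level.
#' @return list: `image` (matrix), `angles` (deg), `lengths` (um),
#'   `pixel_size`.
#' @export
gen_fiber_image <- function(n_fibers, mean_angle = 90, kappa = 4,
                            length_mean = 5, image_size = 256L, seed = 1,
                            pixel_size = 0.1, background_sd = 0.05) {
  stopifnot(kappa >= 0, n_fibers >= 1, length_mean > 0)
  set.seed(seed)
  n <- as.integer(image_size)
  ang <- rvonmises_axial(n_fibers, mean_angle, kappa)
  len <- pmax(length_mean * 0.2,
              stats::rnorm(n_fibers, length_mean, 0.2 * length_mean))
  img <- matrix(0, n, n)
  cx <- stats::runif(n_fibers, 1, n)
  cy <- stats::runif(n_fibers, 1, n)
  for (f in seq_len(n_fibers)) {
    L_px <- len[f] / pixel_size
    t <- seq(-L_px / 2, L_px / 2, by = 0.4)
    xs <- cx[f] + t * cos(ang[f] * pi / 180)
    ys <- cy[f] + t * sin(ang[f] * pi / 180)
    ii <- round(ys); jj <- round(xs)
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
    idx <- unique(cbind(ii[ok], jj[ok]))
    img[idx] <- img[idx] + 1
  }
  img <- gaussian_blur(img, 0.7)
  img <- img / max(max(img), 1e-12)
  img <- img + matrix(stats::rnorm(n * n, 0, background_sd), n, n)
  list(image = img, angles = ang, lengths = len, pixel_size = pixel_size)
}

#' Axial von Mises sampler (period 180 degrees)
#'
#' Samples orientations in `[0, 180)` whose doubled angles follow a von
#' Mises distribution centred on `2 * mean_angle` with concentration
#' `kappa`. Best-Fisher rejection sampling; `kappa = 0` gives the uniform
#' distribution and `kappa = Inf` the point mass at `mean_angle`.
#'
#' @param n number of draws.
#' @param mean_angle mean orientation (degrees).
#' @param kappa concentration.
#' @return orientations in degrees, `[0, 180)`.
#' @export
rvonmises_axial <- function(n, mean_angle, kappa) {
  if (is.infinite(kappa)) return(rep(mean_angle %% 180, n))
  if (kappa == 0) return(stats::runif(n, 0, 180))
  mu <- 2 * mean_angle * pi / 180
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    zz <- cos(pi * u[1])
    ff <- (1 + rr * zz) / (rr + zz)
    cc <- kappa * (rr - ff)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(ff)
      out[i] <- (theta / 2 * 180 / pi) %% 180
      i <- i + 1L
    }
  }
  out
}

#' Generate a matrix-trail record
#'
#' A clone deposits a collagen trail while the egg chamber rotates; the arc
#' length after `duration` hours at `angular_velocity` deg/h is
#' `angular_velocity * duration / 360 * circumference` (it may exceed the
#' circumference when the chamber completes more than one turn).
#'
#' @param angular_velocity rotation rate (deg/h).
#' @param duration deposition time (h).
#' @param circumference egg-chamber circumference (um).
#' @param seed accepted for interface symmetry; the record is deterministic.
#' @return a [trail_record].
#' @export
gen_trail <- function(angular_velocity, duration, circumference, seed = 1) {
  stopifnot(angular_velocity >= 0, duration >= 0, circumference > 0)
  arc <- angular_velocity * duration / 360 * circumference
  trail_record(arc, circumference, duration)
}

#' Generate a rotating textured frame pair
#'
#' A band-limited random texture (sum of random plane waves) on a disc,
#' evaluated at time 0 and after a rigid rotation by
#' `linear_velocity * dt / radius` radians. Because the texture is a
#' continuous function, the second frame contains no resampling error.
#'
#' @param linear_velocity rim speed (um/s).
#' @param dt frame interval (s).
#' @param radius disc radius (um).
#' @param image_size image side (pixels).
#' @param seed integer seed.
#' @param pixel_size um per pixel; default scales the disc to ~90% of the
#'   frame.
#' @param n_waves number of plane-wave components.
#' @param noise_sd additive Gaussian pixel noise.
#' @return list: `frame0`, `frame1`, `pixel_size`, `center` (pixel coords),
#'   `radius`, `angle` (true rotation, rad).
#' @export
gen_rotation_frames <- function(linear_velocity, dt, radius,
                                image_size = 128L, seed = 1,
                                pixel_size = NULL, n_waves = 40,
                                noise_sd = 0.02) {
  stopifnot(radius > 0, dt > 0)
  set.seed(seed)
  n <- as.integer(image_size)
  if (is.null(pixel_size)) pixel_size <- 2 * radius / (0.9 * n)
  angle <- linear_velocity * dt / radius
  kmag <- stats::runif(n_waves, 2 * pi / (radius / 1.5), 2 * pi / (radius / 6))
  kdir <- stats::runif(n_waves, 0, 2 * pi)
  phase <- stats::runif(n_waves, 0, 2 * pi)
  amp <- stats::rnorm(n_waves, 0, 1) / sqrt(n_waves)
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  xs <- ((col(matrix(0, n, n)) - cx)) * pixel_size
  ys <- ((row(matrix(0, n, n)) - cy)) * pixel_size
  texture <- function(theta) {
    ct <- cos(-theta); st <- sin(-theta)
    xr <- ct * xs - st * ys
    yr <- st * xs + ct * ys
    f <- matrix(0, n, n)
    for (m in seq_len(n_waves)) {
      f <- f + amp[m] * cos(kmag[m] * (cos(kdir[m]) * xr + sin(kdir[m]) * yr) +
                              phase[m])
    }
    f[xs^2 + ys^2 > radius^2] <- 0
    f
  }
  f0 <- texture(0)
  f1 <- texture(angle)
  if (noise_sd > 0) {
    f0 <- f0 + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    f1 <- f1 + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  }
  list(frame0 = f0, frame1 = f1, pixel_size = pixel_size,
       center = c(x = cx, y = cy), radius = radius, angle = angle)
}

#' Generate a filled-ellipse chamber mask
#'
#' @param major,minor full axis lengths (um); the major axis lies along x
#'   (the AP axis).
#' @param image_size image side (pixels).
#' @param pixel_size um per pixel; default fits the ellipse with a 10%
#'   margin.
#' @return list: `mask` (logical matrix), `pixel_size`.
#' @export
gen_chamber_mask <- function(major, minor, image_size = 256L,
                             pixel_size = NULL) {
  stopifnot(major > 0, minor > 0)
  n <- as.integer(image_size)
  if (is.null(pixel_size)) pixel_size <- 1.1 * max(major, minor) / n
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  xs <- (col(matrix(0, n, n)) - cx) * pixel_size
  ys <- (row(matrix(0, n, n)) - cy) * pixel_size
  mask <- (xs / (major / 2))^2 + (ys / (minor / 2))^2 <= 1
  list(mask = mask, pixel_size = pixel_size)
}

#' Generate per-chamber stiffness samples for the ratio test
#'
#' Per-chamber stiffness summaries (e.g. 5x5 um medians) for the center and
#' the posterior pole of `n_chambers` chambers: lognormal across chambers
#' around the preset bulk modulus (center) and around bulk divided by the
#' preset center:pole ratio (pole).
#'
#' @param preset a [genotype_preset].
#' @param n_chambers chambers per region.
#' @param chamber_cv between-chamber coefficient of variation.
#' @param seed integer seed.
#' @return list with `center` and `pole` [group_sample]s.
#' @export
gen_chamber_samples <- function(preset, n_chambers = 8, chamber_cv = 0.15,
                                seed = 1) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + chamber_cv^2))
  mu_c <- preset$bulk_modulus
  mu_p <- preset$bulk_modulus / preset$center_pole_ratio
  center <- stats::rlnorm(n_chambers, log(mu_c) - sdlog^2 / 2, sdlog)
  pole <- stats::rlnorm(n_chambers, log(mu_p) - sdlog^2 / 2, sdlog)
  list(center = group_sample(center), pole = group_sample(pole))
}
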