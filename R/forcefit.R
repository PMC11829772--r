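# Per-curve AFM processing: contact point, indentation, Hertz-Sneddon fit.
#
# Conventions. A curve stores piezo extension z (nm, increasing along the
# approach) and force (pN). The deflection-corrected tip position is
# z - F/k. Surface heights are reported in a "height" frame,
# height = z_ref - tip position, so that a higher sample surface gives a
# larger height; z_ref is an arbitrary per-scan origin (0 for standalone
# curves).

#' Construct a force curve
#'
#' @param z piezo extensions (nm), strictly increasing along approach.
#' @param force forces (pN), same length as `z` (>= 16 samples).
#' @param probe a [probe_params].
#' @param z_ref height-frame origin (nm).
#' @return object of class `force_curve`.
#' @export
force_curve <- function(z, force, probe = probe_params(), z_ref = 0) {
  stopifnot(length(z) == length(force), length(z) >= 16,
            all(is.finite(force)))
  if (any(diff(z) <= 0)) stop("z must be strictly increasing (approach)")
  structure(list(z = z, force = force, probe = probe, z_ref = z_ref),
            class = "force_curve")
}

# Baseline: median force over the first quarter of the approach (the free
# tail before contact). Selecting samples by *position* rather than by
# force value keeps the estimate unbiased under noise (the median of the
# lowest-force samples would sit in the lower tail of the noise).
#' @keywords internal
baseline_correct <- function(force) {
  nlow <- max(4L, floor(length(force) * 0.25))
  force - stats::median(force[seq_len(nlow)])
}

#' Detect the contact point (surface height)
#'
#' The vertical position of the sample surface is defined as the
#' deflection-corrected cantilever tip position at which the
#' baseline-corrected force first crosses `fraction` of the setpoint force
#' (20% by default, i.e. 0.12 nN for a 0.6 nN setpoint), linearly
#' interpolated between samples. The baseline is the median force over
#' the first quarter of the approach (the pre-contact free tail).
#'
#' Note that with a quadratic contact model this threshold crossing sits
#' `sqrt(fraction * F_set / C)` beyond the true contact; the offset is the
#' price of a noise-robust topography definition and is common to all
#' pixels of comparable stiffness.
#'
#' @param curve a [force_curve].
#' @param fraction threshold as a fraction of the setpoint force.
#' @return surface height (nm) in the curve's height frame, or `NA` with
#'   attribute `reason` when the threshold is never reached.
#' @export
detect_contact_point <- function(curve, fraction = 0.2) {
  stopifnot(inherits(curve, "force_curve"), fraction > 0, fraction < 1)
  f0 <- baseline_correct(curve$force)
  thr <- fraction * setpoint_pN(curve$probe)
  above <- f0 >= thr
  if (!any(above)) {
    return(structure(NA_real_, reason = "threshold never reached"))
  }
  i <- which(above)[1]
  if (i == 1L) {
    z_cross <- curve$z[1]
  } else {
    # first upward crossing, linear interpolation (ties toward smaller z)
    w <- (thr - f0[i - 1]) / (f0[i] - f0[i - 1])
    z_cross <- curve$z[i - 1] + w * (curve$z[i] - curve$z[i - 1])
  }
  tip <- z_cross - thr / spring_pN_per_nm(curve$probe)
  curve$z_ref - tip
}

#' Estimate the true contact point of a quadratic indentation curve
#'
#' Exact linearization of the pyramidal model: on post-contact samples
#' F = C (x - x0)^2 with x the tip position, so sqrt(F) is linear in x; an
#' ordinary least-squares line through (x, sqrt(F)) for forces between
#' `min_fraction` of the setpoint and `fit_max_force` yields the contact
#' tip position x0 (and a starting value for C). Exact for noiseless
#' curves, which is what makes the zero-noise round trip recover the
#' modulus to machine precision.
#'
#' @param curve a [force_curve].
#' @param fit_max_force upper force bound (pN).
#' @param min_fraction lower force bound as a fraction of the setpoint.
#' @return contact surface height (nm, height frame), or `NA` when fewer
#'   than 4 samples fall in the force window.
#' @export
estimate_contact_point <- function(curve, fit_max_force = 500,
                                   min_fraction = 0.1) {
  f0 <- baseline_correct(curve$force)
  k <- spring_pN_per_nm(curve$probe)
  sel <- f0 >= min_fraction * setpoint_pN(curve$probe) & f0 <= fit_max_force
  if (sum(sel) < 4) return(NA_real_)
  x <- (curve$z - f0 / k)[sel]
  y <- sqrt(f0[sel])
  sxx <- stats::var(x)
  if (sxx <= 0) return(NA_real_)
  slope <- stats::cov(x, y) / sxx
  if (slope <= 0) return(NA_real_)
  x0 <- mean(x) - mean(y) / slope
  curve$z_ref - x0
}

#' Compute the indentation from a surface height
#'
#' delta = (z - z_contact) - F/k on the post-contact portion, i.e. the tip
#' position past the contact tip position, clipped at zero; the deflection
#' F/k uses the calibrated spring constant.
#'
#' @param curve a [force_curve].
#' @param surface_height contact height (nm, height frame), e.g. from
#'   [estimate_contact_point()].
#' @return list with `indentation` (nm) and `force` (pN,
#'   baseline-corrected), post-contact samples only.
#' @export
compute_indentation <- function(curve, surface_height) {
  k <- spring_pN_per_nm(curve$probe)
  if (k <= 0) stop("spring constant must be positive")
  f0 <- baseline_correct(curve$force)
  z_contact_tip <- curve$z_ref - surface_height
  delta <- (curve$z - z_contact_tip) - f0 / k
  keep <- delta > 0
  list(indentation = delta[keep], force = f0[keep])
}

#' Fit the pyramidal Hertz-Sneddon model
#'
#' Least-squares fit of F = C delta^2 over samples with F <=
#' `fit_max_force` (500 pN by default, ~200 nm indentation at the control
#' modulus). The fit is linear in C on delta^2 (closed form):
#' C = sum(F delta^2) / sum(delta^4). The modulus is
#' E = C (1 - nu^2) / (b tan(alpha)).
#'
#' @param indentation indentations (nm).
#' @param force forces (pN), same length.
#' @param probe a [probe_params].
#' @param fit_max_force upper force bound of the fit range (pN).
#' @param min_samples minimum post-contact samples required.
#' @return list (class `pixel_fit`): `youngs_modulus` (kPa), `fit_rss`
#'   (pN^2), `fit_range_max_force`, `n_fit`, `valid`.
#' @export
fit_hertz_sneddon <- function(indentation, force, probe = probe_params(),
                              fit_max_force = 500, min_samples = 8) {
  stopifnot(length(indentation) == length(force))
  sel <- force <= fit_max_force
  d2 <- indentation[sel]^2
  f <- force[sel]
  invalid <- function() {
    structure(list(youngs_modulus = NA_real_, fit_rss = NA_real_,
                   fit_range_max_force = fit_max_force, n_fit = sum(sel),
                   valid = FALSE), class = "pixel_fit")
  }
  if (sum(sel) < min_samples) return(invalid())
  C <- sum(f * d2) / sum(d2^2)
  if (!is.finite(C) || C <= 0) return(invalid())
  rss <- sum((f - C * d2)^2)
  structure(list(youngs_modulus = hertz_modulus(C, probe), fit_rss = rss,
                 fit_range_max_force = fit_max_force, n_fit = sum(sel),
                 valid = TRUE),
            class = "pixel_fit")
}

#' Fit a single force curve end to end
#'
#' Chains the per-curve processing: baseline correction, surface height by
#' the 20%-of-setpoint rule (topography), contact refinement by the
#' sqrt-linearization, indentation, and the Hertz-Sneddon fit up to
#' `fit_max_force`.
#'
#' @param curve a [force_curve].
#' @param fraction threshold fraction for the topography surface height.
#' @param fit_max_force fit-range bound (pN).
#' @return list (class `pixel_fit`): `surface_height` (nm),
#'   `youngs_modulus` (kPa), `fit_rss`, `fit_range_max_force`, `valid`.
#' @export
fit_force_curve <- function(curve, fraction = 0.2, fit_max_force = 500) {
  surface <- detect_contact_point(curve, fraction)
  if (is.na(surface)) {
    return(structure(list(surface_height = NA_real_,
                          youngs_modulus = NA_real_, fit_rss = NA_real_,
                          fit_range_max_force = fit_max_force,
                          valid = FALSE), class = "pixel_fit"))
  }
  contact <- estimate_contact_point(curve, fit_max_force)
  fit <- if (is.na(contact)) {
    fit_hertz_sneddon(numeric(0), numeric(0), curve$probe, fit_max_force)
  } else {
    ind <- compute_indentation(curve, contact)
    fit_hertz_sneddon(ind$indentation, ind$force, curve$probe, fit_max_force)
  }
  fit$surface_height <- as.numeric(surface)
  fit
}

#' Fit every pixel of a force volume
#'
#' Two surface maps are returned: `topography` uses the
#' fraction-of-setpoint threshold rule, whose crossing sits
#' sqrt(fraction * F_set / C) past the true contact and therefore couples
#' the local stiffness into the apparent height; `topography_contact`
#' uses the fitted contact point, which is independent of local stiffness
#' and is what the topography-stiffness correlation analysis should use.
#'
#' @param fv a [force_volume].
#' @param fraction threshold fraction for topography heights.
#' @param fit_max_force fit-range bound (pN).
#' @return list with `stiffness`, `topography`, `topography_contact`
#'   [scalar_map]s (invalid pixels masked) and `fits` (per-pixel data
#'   frame).
#' @export
fit_force_volume <- function(fv, fraction = 0.2, fit_max_force = 500) {
  stopifnot(inherits(fv, "force_volume"))
  npix <- prod(fv$dim_grid)
  E <- h <- hc <- rep(NA_real_, npix)
  rss <- rep(NA_real_, npix)
  k <- spring_pN_per_nm(fv$probe)
  thr_topo <- fraction * setpoint_pN(fv$probe)
  thr_lo <- 0.1 * setpoint_pN(fv$probe)
  for (p in seq_len(npix)) {
    f <- fv$force[, p]
    ok <- !is.na(f)
    z <- fv$z[ok]; f <- f[ok]
    f0 <- f - stats::median(f[seq_len(max(4L, floor(length(f) * 0.25)))])
    above <- f0 >= thr_topo
    if (!any(above)) next
    i <- which(above)[1]
    z_cross <- if (i == 1L) z[1] else {
      w <- (thr_topo - f0[i - 1]) / (f0[i] - f0[i - 1])
      z[i - 1] + w * (z[i] - z[i - 1])
    }
    h[p] <- fv$z_ref - (z_cross - thr_topo / k)
    sel <- f0 >= thr_lo & f0 <= fit_max_force
    if (sum(sel) < 4) next
    x <- (z - f0 / k)[sel]
    y <- sqrt(f0[sel])
    sxx <- sum((x - mean(x))^2)
    if (sxx <= 0) next
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    if (slope <= 0) next
    x0 <- mean(x) - mean(y) / slope
    hc[p] <- fv$z_ref - x0
    delta <- (z - f0 / k) - x0
    keep <- delta > 0 & f0 <= fit_max_force
    if (sum(keep) < 8) next
    d2 <- delta[keep]^2
    C <- sum(f0[keep] * d2) / sum(d2^2)
    if (!is.finite(C) || C <= 0) next
    E[p] <- hertz_modulus(C, fv$probe)
    rss[p] <- sum((f0[keep] - C * d2)^2)
  }
  nyx <- fv$dim_grid
  list(
    stiffness = scalar_map(matrix(E, nyx[1], nyx[2]), fv$pixel_size, "kPa"),
    topography = scalar_map(matrix(h, nyx[1], nyx[2]), fv$pixel_size, "nm"),
    topography_contact = scalar_map(matrix(hc, nyx[1], nyx[2]),
                                    fv$pixel_size, "nm"),
    fits = data.frame(pixel = seq_len(npix), surface_height = h,
                      contact_height = hc, youngs_modulus = E,
                      fit_rss = rss, valid = is.finite(E))
  )
}
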