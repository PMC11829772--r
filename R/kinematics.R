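# Rotation kinematics: matrix-trail geometry and ex vivo frame
# registration.

#' Construct a trail record
#'
#' @param trail_length deposited trail arc length (um); may exceed the
#'   circumference when the chamber wraps past a full turn.
#' @param circumference egg-chamber circumference (um).
#' @param elapsed_time deposition time (h).
#' @return object of class `trail_record`.
#' @export
trail_record <- function(trail_length, circumference, elapsed_time) {
  stopifnot(trail_length >= 0, circumference > 0)
  if (elapsed_time <= 0) stop("elapsed_time must be positive")
  structure(list(trail_length = trail_length, circumference = circumference,
                 elapsed_time = elapsed_time),
            class = "trail_record")
}

#' Trail-to-circumference ratio (percent)
#'
#' @param rec a [trail_record].
#' @return 100 * trail_length / circumference.
#' @export
trail_ratio <- function(rec) {
  stopifnot(inherits(rec, "trail_record"))
  100 * rec$trail_length / rec$circumference
}

#' Angular velocity from a trail record
#'
#' omega = (trail_length / circumference) * 360 / elapsed_time; one full
#' turn in 10 h gives 36 deg/h.
#'
#' @param rec a [trail_record].
#' @return angular velocity (deg/h).
#' @export
angular_velocity <- function(rec) {
  stopifnot(inherits(rec, "trail_record"))
  (rec$trail_length / rec$circumference) * 360 / rec$elapsed_time
}

#' Rotation velocity from a frame pair
#'
#' Estimates the rigid rotation between two frames of a rotating chamber:
#' both frames are resampled to polar coordinates about `center`, and the
#' angular shift maximizing the radius-summed circular cross-correlation
#' (with quadratic sub-bin peak interpolation) gives the rotation angle;
#' the linear (rim) velocity is angle * radius / dt. Positive angles are
#' rotations from +x toward +y.
#'
#' @param frame0,frame1 numeric matrices (congruent).
#' @param dt frame interval (s).
#' @param center `c(x, y)` rotation centre in pixel coordinates.
#' @param radius_um chamber radius (um).
#' @param pixel_size um per pixel.
#' @param n_theta angular samples.
#' @param n_r radial samples.
#' @param min_peak minimum normalized correlation peak; below it the
#'   rotation is reported as not detected (`NA`).
#' @return list (class `rotation_fit`): `velocity` (um/s), `angle` (rad),
#'   `peak_corr`, `detected`.
#' @export
rotation_velocity <- function(frame0, frame1, dt, center, radius_um,
                              pixel_size, n_theta = 720L, n_r = 40L,
                              min_peak = 0.2) {
  stopifnot(identical(dim(frame0), dim(frame1)), dt > 0, radius_um > 0)
  radius_px <- radius_um / pixel_size
  rr <- seq(0.35, 0.95, length.out = n_r) * radius_px
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  sample_polar <- function(fr) {
    xs <- center[1] + outer(rr, cos(th))
    ys <- center[2] + outer(rr, sin(th))
    bilinear_at(fr, xs, ys)
  }
  p0 <- sample_polar(frame0)
  p1 <- sample_polar(frame1)
  p0 <- p0 - rowMeans(p0)
  p1 <- p1 - rowMeans(p1)
  # circular cross-correlation along theta, summed over radii (via FFT)
  f0 <- stats::mvfft(t(p0))
  f1 <- stats::mvfft(t(p1))
  cc <- rowSums(Re(stats::mvfft(Conj(f0) * f1, inverse = TRUE))) / n_theta
  norm <- sqrt(sum(p0^2) * sum(p1^2))
  if (norm == 0) {
    return(structure(list(velocity = NA_real_, angle = NA_real_,
                          peak_corr = 0, detected = FALSE),
                     class = "rotation_fit"))
  }
  ccn <- cc / norm
  ipk <- which.max(ccn)
  # quadratic sub-bin interpolation around the peak
  im <- if (ipk == 1L) n_theta else ipk - 1L
  ip <- if (ipk == n_theta) 1L else ipk + 1L
  denom <- ccn[im] - 2 * ccn[ipk] + ccn[ip]
  frac <- if (denom != 0) 0.5 * (ccn[im] - ccn[ip]) / denom else 0
  shift <- (ipk - 1 + frac)
  angle <- shift * 2 * pi / n_theta
  if (angle > pi) angle <- angle - 2 * pi
  detected <- max(ccn) >= min_peak
  structure(list(velocity = if (detected) angle * radius_um / dt else NA_real_,
                 angle = if (detected) angle else NA_real_,
                 peak_corr = max(ccn), detected = detected),
            class = "rotation_fit")
}

#' Bilinear sampling at arbitrary coordinates
#' @param x matrix; `xs`, `ys` coordinate matrices (x = column, y = row).
#' @keywords internal
bilinear_at <- function(x, xs, ys) {
  n <- nrow(x); m <- ncol(x)
  j0 <- floor(xs); i0 <- floor(ys)
  wj <- xs - j0;   wi <- ys - i0
  cl <- function(idx, k) pmin(pmax(idx, 1), k)
  g <- function(ii, jj) {
    out <- x[cbind(as.vector(cl(ii, n)), as.vector(cl(jj, m)))]
    matrix(out, nrow(xs), ncol(xs))
  }
  g(i0, j0) * (1 - wi) * (1 - wj) + g(i0 + 1, j0) * wi * (1 - wj) +
    g(i0, j0 + 1) * (1 - wi) * wj + g(i0 + 1, j0 + 1) * wi * wj
}

#' Trail midline length from a binary trail mask
#'
#' Skeletonizes the mask and returns the geodesic midline length; wrapping
#' trails are supported in the sense that the returned length may exceed
#' the chamber circumference supplied downstream.
#'
#' @param mask logical matrix.
#' @param pixel_size um per pixel.
#' @return midline length (um).
#' @export
trail_length_from_mask <- function(mask, pixel_size) {
  if (!any(mask)) return(0)
  skel <- prune_spurs(zhang_suen_thin(mask), 3L)
  skeleton_length_px(skel) * pixel_size
}
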