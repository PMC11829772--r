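# Map processing: levelling, smoothing, correlation, region medians and
# stripe quantification.

#' Level a topography map
#'
#' Removes the scanner background: a best-fit bivariate polynomial of total
#' degree 3 (plane fit) and per-fast-axis-line linear trends (1st-order line
#' levelling), computed over valid pixels only. The two fits are alternated
#' until convergence, which makes the operation a projection and therefore
#' idempotent; the output mean over valid pixels is set to zero.
#'
#' @param topo a topography [scalar_map] (nm).
#' @param max_iter maximum alternation passes.
#' @param tol convergence tolerance on the maximum change (nm).
#' @return levelled [scalar_map].
#' @export
level_topography <- function(topo, max_iter = 8L, tol = 1e-10) {
  stopifnot(inherits(topo, "scalar_map"))
  v <- topo$values
  ok <- topo$mask & is.finite(v)
  if (sum(ok) < 16) stop("need at least 4x4 valid pixels")
  n <- nrow(v); m <- ncol(v)
  xh <- (col(v) - (m + 1) / 2) / (m / 2)
  yh <- (row(v) - (n + 1) / 2) / (n / 2)
  terms <- list()
  for (p in 0:3) for (q in 0:(3 - p)) terms[[length(terms) + 1L]] <- xh^p * yh^q
  X <- vapply(terms, function(t) t[ok], numeric(sum(ok)))
  Xf <- vapply(terms, as.vector, numeric(n * m))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("degenerate mask: plane fit is rank-deficient")

  w <- v
  w[!ok] <- NA
  for (iter in seq_len(max_iter)) {
    prev <- w
    beta <- qr.coef(qrX, w[ok])
    w <- w - matrix(Xf %*% beta, n, m)
    # 1st-order line levelling along the fast axis (each row is one line)
    for (i in seq_len(n)) {
      sel <- ok[i, ]
      if (sum(sel) < 2) next
      xr <- xh[i, ]
      fit <- stats::lsfit(xr[sel], w[i, sel])
      w[i, ] <- w[i, ] - (fit$coefficients[1] + fit$coefficients[2] * xr)
    }
    if (max(abs(w - prev), na.rm = TRUE) < tol) break
  }
  w <- w - mean(w[ok])
  out <- topo
  out$values <- w
  out$mask <- ok
  out
}

#' Smooth a map (median then 2D Savitzky-Golay)
#'
#' A median filter removes single-pixel outliers, then a 2D Savitzky-Golay
#' filter (least-squares polynomial surface per window) smooths while
#' preserving features up to the polynomial order; edges are handled by
#' reflection. Invalid pixels are imputed with the valid median before
#' filtering and remain masked afterwards.
#'
#' @param map a [scalar_map].
#' @param median_window median filter window (pixels, odd).
#' @param sg_window Savitzky-Golay window (pixels, odd).
#' @param sg_order Savitzky-Golay polynomial order.
#' @return smoothed [scalar_map].
#' @export
smooth_map <- function(map, median_window = 3L, sg_window = 5L,
                       sg_order = 2L) {
  stopifnot(inherits(map, "scalar_map"))
  n <- nrow(map$values); m <- ncol(map$values)
  if (median_window > min(n, m) || sg_window > min(n, m)) {
    stop("filter window larger than the map")
  }
  v <- map$values
  if (any(!map$mask)) v[!map$mask] <- stats::median(v[map$mask])
  v <- median_filter2(v, median_window)
  v <- filter2_reflect(v, sg2d_kernel(sg_window, sg_order))
  out <- map
  out$values <- v
  out
}

#' Pearson correlation between two maps
#'
#' Computed over jointly valid pixels; in the study pipeline both maps have
#' been levelled/smoothed first.
#'
#' @param topo,stiff congruent [scalar_map]s.
#' @return correlation coefficient.
#' @export
map_correlation <- function(topo, stiff) {
  check_congruent(topo, stiff)
  ok <- topo$mask & stiff$mask
  stats::cor(topo$values[ok], stiff$values[ok])
}

#' Median over a square region
#'
#' Median of valid pixels inside an axis-aligned square of side
#' `square_side` micrometres (5 x 5 by default, the study's summary
#' region), centred on `center` (map centre by default).
#'
#' @param map a [scalar_map].
#' @param square_side square side (um).
#' @param center `c(x, y)` centre in um from the map corner; `NULL` = map
#'   centre.
#' @return median value.
#' @export
region_median <- function(map, square_side = 5, center = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  px <- map$pixel_size
  n <- nrow(map$values); m <- ncol(map$values)
  if (is.null(center)) center <- c(m, n) * px / 2
  xs <- (col(map$values) - 0.5) * px
  ys <- (row(map$values) - 0.5) * px
  sel <- abs(xs - center[1]) <= square_side / 2 &
    abs(ys - center[2]) <= square_side / 2 & map$mask
  if (!any(sel)) stop("region contains no valid pixels")
  stats::median(map$values[sel])
}

#' Quantify stiffness stripes
#'
#' Segments the Collagen-IV-like stripes of elevated stiffness and
#' measures their excess over bulk. The map is smoothed along the expected
#' stripe direction (perpendicular to the AP axis) to accumulate stripe
#' evidence against pixel noise; pixels above the `q`-th percentile of
#' that directional field form the candidate mask, whose connected
#' components are kept if elongated (major/minor >= `elongation_min`) and
#' long enough (`min_length_um`).
#'
#' Three safeguards keep the estimate honest on noisy maps. (1) The
#' segmentation field excludes each pixel's own value (leave-self-out
#' directional smoothing), so thresholding does not select pixels for
#' their own noise; for this reason the function expects the *unsmoothed*
#' stiffness map and does its own noise suppression (feeding it a
#' pre-smoothed map reintroduces selection bias through the spatial noise
#' correlation). (2) Stripes must show the band structure they have by
#' construction (elongated structures at a common orientation recurring
#' along the across-stripe axis): the across-stripe profile of bin means
#' is tested against spatial homogeneity with a chi-squared variance
#' test, and a map whose profile is compatible with a flat field
#' (p >= `band_alpha`) is reported as stripe-free. (3) Components whose
#' across-stripe position falls outside the detected bands are treated as
#' bulk noise and excluded from the stripe mask.
#'
#' @param stiff an unsmoothed stiffness [scalar_map] (kPa).
#' @param ap_axis AP-axis direction in image coordinates (degrees; 0 = x
#'   axis, the scan fast axis).
#' @param q percentile threshold (0-100).
#' @param elongation_min minimum component elongation.
#' @param min_area_px minimum component area (pixels).
#' @param min_length_um minimum component major-axis length (um); rejects
#'   smoothing-scale noise blobs.
#' @param sigma_along_um directional smoothing scale along the stripe (um).
#' @param band_alpha significance level of the across-stripe band test.
#' @return list (class `stripe_stats`): `elevation_percent` (100 *
#'   (stripe median / bulk median - 1); `NA` when the stripe pixel
#'   fraction is outside (0.02, 0.6)), `stripe_lengths` (um),
#'   `stripe_orientation` (degrees from AP), `stripe_pixel_fraction`,
#'   `n_stripes`, `band_p` (band-test p value), `mask`.
#' @export
quantify_stripes <- function(stiff, ap_axis = 0, q = 75,
                             elongation_min = 2, min_area_px = 5,
                             min_length_um = 2, sigma_along_um = 1.5,
                             band_alpha = 0.01) {
  stopifnot(inherits(stiff, "scalar_map"))
  v <- stiff$values
  px <- stiff$pixel_size
  stripe_dir <- ap_axis + 90
  sigma_px <- sigma_along_um / px
  sm <- directional_smooth_loo(v, stripe_dir, sigma_px)
  thr <- stats::quantile(sm, q / 100)
  cand <- sm >= thr & stiff$mask

  # band structure along the across-stripe axis: chi-squared homogeneity
  # test of per-bin means of the raw map (pixel noise is independent, so
  # under a stripe-free field the statistic is chi-squared distributed)
  th <- stripe_dir * pi / 180
  across <- -((col(v) - 0.5) * px) * sin(th) + ((row(v) - 0.5) * px) * cos(th)
  bin <- round((across - min(across)) / px) + 1L
  ok <- stiff$mask
  nb <- as.vector(tapply(v[ok], bin[ok], length))
  Pb <- as.vector(tapply(v[ok], bin[ok], mean))
  chi2 <- sum(nb * (Pb - mean(v[ok]))^2) / stats::var(v[ok])
  band_p <- stats::pchisq(chi2, df = length(Pb) - 1, lower.tail = FALSE)

  labels <- label8(cand)
  nlab <- max(labels)
  empty <- structure(
    list(elevation_percent = NA_real_, stripe_lengths = numeric(0),
         stripe_orientation = NA_real_, stripe_pixel_fraction = 0,
         n_stripes = 0L, band_p = band_p,
         mask = matrix(FALSE, nrow(v), ncol(v))),
    class = "stripe_stats")
  if (nlab == 0 || band_p >= band_alpha) return(empty)

  # bands = across-bins whose leave-self-out smoothed profile lies in the
  # top quartile; a component belongs to a band if its centroid does.
  # The profile at a bin excludes the bin's own pixels, so selecting bins
  # by it does not bias statistics computed from their pixel values.
  bins_present <- sort(unique(bin[ok]))
  Pfull <- rep(mean(v[ok]), max(bin))
  Pfull[bins_present] <- Pb
  hB <- 4L
  wB <- exp(-(seq(-hB, hB))^2 / (2 * 1.5^2))
  wB[hB + 1L] <- 0
  Ppad <- c(rep(NA, hB), Pfull, rep(NA, hB))
  Ploo <- vapply(seq_along(Pfull), function(b) {
    seg <- Ppad[b:(b + 2L * hB)]
    w <- wB; w[is.na(seg)] <- 0
    sum(w * seg, na.rm = TRUE) / sum(w)
  }, numeric(1))
  band_bins <- which(Ploo >= stats::quantile(Ploo, 0.75))
  # band cores: close single-bin gaps, drop runs shorter than 3 bins
  # (isolated noise bins), then trim each contiguous band to the bins
  # above 60% of its peak rise over bulk, dropping partially elevated
  # edge bins; bulk reference bins sit at least 3 bins away from bands
  bulkP <- stats::median(Ploo)
  in_band <- seq_along(Ploo) %in% band_bins
  nB <- length(in_band)
  gap1 <- which(!in_band & c(FALSE, in_band[-nB]) & c(in_band[-1], FALSE))
  in_band[gap1] <- TRUE
  runs0 <- rle(in_band)
  runs0$values[runs0$values & runs0$lengths < 3] <- FALSE
  in_band <- inverse.rle(runs0)
  band_bins <- which(in_band)
  if (!length(band_bins)) return(empty)
  runs <- rle(in_band)
  stops <- cumsum(runs$lengths)
  core_bins <- integer(0)
  bulkPf <- stats::median(Pfull)
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    bb <- (stops[r] - runs$lengths[r] + 1L):stops[r]
    rise <- Pfull[bb] - bulkPf
    # robust peak: mean of the top half of the run's (unsmoothed) rises;
    # the smoothed profile would smear the band edges outward
    peak <- mean(sort(rise, decreasing = TRUE)[seq_len(ceiling(length(bb) / 2))])
    core_bins <- c(core_bins, bb[rise >= 0.6 * peak])
  }
  if (!length(core_bins)) core_bins <- band_bins
  far <- !vapply(seq_along(Ploo), function(b) {
    any(abs(b - band_bins) <= 3L)
  }, logical(1))
  bulk_bins <- which(far)
  if (!length(bulk_bins)) bulk_bins <- which(!in_band)

  keep <- logical(nlab)
  lens <- oris <- areas <- rep(NA_real_, nlab)
  for (l in seq_len(nlab)) {
    idx <- which(labels == l, arr.ind = TRUE)
    a <- nrow(idx)
    if (a < min_area_px) next
    xs <- idx[, 2]; ys <- idx[, 1]
    mxx <- stats::var(xs) + 1 / 12
    myy <- stats::var(ys) + 1 / 12
    mxy <- stats::cov(xs, ys)
    tr <- mxx + myy
    det_ <- mxx * myy - mxy^2
    l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det_, 0))
    l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det_, 0))
    elong <- sqrt(l1 / max(l2, 1e-9))
    if (elong < elongation_min) next
    # major-axis extent; sqrt(12)*sd is exact for a uniform bar profile
    len_um <- sqrt(12) * sqrt(l1) * px
    if (len_um < min_length_um) next
    if (!round(mean(bin[cbind(idx[, 1], idx[, 2])])) %in% band_bins) next
    keep[l] <- TRUE
    areas[l] <- a
    lens[l] <- len_um
    oris[l] <- (0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi) %% 180
  }
  if (!any(keep)) return(empty)

  # the coarse directional scale bridges the gaps between consecutive
  # segments of a stripe; a second leave-self-out criterion at a finer
  # scale removes those gap (bulk) pixels from the final mask
  sm_fine <- directional_smooth_loo(v, stripe_dir, 0.4 / px)
  coarse <- matrix(labels %in% which(keep), nrow(v), ncol(v))
  mask <- coarse & sm_fine >= stats::quantile(sm_fine, q / 100)
  if (!any(mask)) mask <- coarse
  frac <- mean(mask[stiff$mask])
  # elevation by mixture-amplitude estimation. The band amplitude
  # a = elevation * fill is measured precisely as the mean over band-core
  # bins relative to the mean over far-from-band bulk bins (core-bin
  # selection uses only other bins' data, so the means are unbiased). The
  # along-stripe fill fraction is then estimated by thresholding the
  # per-band along profiles at the level midpoint, correcting the count
  # for the (symmetric) misclassification probability, and iterating
  # elevation = amplitude / fill to a fixed point. This avoids per-pixel
  # segment classification, which is noise-limited at these SNRs.
  bulk_px <- matrix(bin %in% bulk_bins, nrow(v), ncol(v)) & !coarse &
    stiff$mask
  if (!any(bulk_px)) bulk_px <- !mask & stiff$mask
  core_px <- matrix(bin %in% core_bins, nrow(v), ncol(v)) & stiff$mask
  bulk_level <- mean(v[bulk_px])
  amp <- mean(v[core_px]) / bulk_level - 1
  # per-band along profiles over their core bins
  band_id <- cumsum(c(1, diff(core_bins) > 1))
  rel_sd <- stats::sd(v[bulk_px]) / bulk_level
  ky <- gaussian_kernel1d(0.3 / px)     # along-profile smoothing; a
  hk <- (length(ky) - 1L) %/% 2L        # symmetric kernel keeps midpoint
  A <- c(); sigmas <- c()               # crossings of a step unbiased
  for (b in unique(band_id)) {
    cols <- core_bins[band_id == b]
    sel <- matrix(bin %in% cols, nrow(v), ncol(v))
    prof <- vapply(seq_len(nrow(v)), function(i) {
      sr <- sel[i, ] & stiff$mask[i, ]
      if (!any(sr)) return(NA_real_)
      mean(v[i, sr])
    }, numeric(1))
    prof <- prof[!is.na(prof)]
    pp <- c(rev(prof[seq_len(hk)]), prof, rev(prof)[seq_len(hk)])
    prof_s <- vapply(seq_along(prof),
                     function(i) sum(ky * pp[i:(i + 2L * hk)]), numeric(1))
    A <- c(A, prof_s / bulk_level - 1)
    sigmas <- c(sigmas, rel_sd / sqrt(length(cols)) * sqrt(sum(ky^2)))
  }
  sigma_eff <- mean(sigmas)
  # profile values are a two-level mixture: gap level 0 (weight 1 - fill)
  # and segment level e (weight fill), blurred by noise of known scale;
  # fit fill by matching the empirical CDF under the constraint
  # e * fill = amp
  amp <- max(amp, 1e-4)
  ts <- seq(min(A), max(A), length.out = 101)
  emp <- stats::ecdf(A)(ts)
  fills <- seq(0.25, 1, by = 0.01)
  sse <- vapply(fills, function(f) {
    ee <- amp / f
    model <- (1 - f) * stats::pnorm(ts, 0, sigma_eff) +
      f * stats::pnorm(ts, ee, sigma_eff)
    sum((model - emp)^2)
  }, numeric(1))
  fill <- fills[which.min(sse)]
  e <- amp / fill
  elev <- if (frac > 0.02 && frac < 0.6) 100 * e else NA_real_
  # segment lengths and orientations from the final (gap-free) components
  flab <- label8(mask)
  lens <- oris <- areas <- numeric(0)
  for (l in seq_len(max(flab))) {
    idx <- which(flab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) next
    xs <- idx[, 2]; ys <- idx[, 1]
    mxx <- stats::var(xs) + 1 / 12
    myy <- stats::var(ys) + 1 / 12
    mxy <- stats::cov(xs, ys)
    tr <- mxx + myy
    l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - (mxx * myy - mxy^2), 0))
    lens <- c(lens, sqrt(12) * sqrt(l1) * px)
    oris <- c(oris, (0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi) %% 180)
    areas <- c(areas, nrow(idx))
  }
  # area-weighted axial mean orientation (period 180 degrees)
  ang2 <- oris * 2 * pi / 180
  mean_ang <- (atan2(sum(areas * sin(ang2)), sum(areas * cos(ang2))) / 2 *
                 180 / pi) %% 180
  structure(
    list(elevation_percent = elev, stripe_lengths = lens,
         stripe_orientation = mean_ang, stripe_pixel_fraction = frac,
         n_stripes = length(lens), band_p = band_p,
         band_amplitude_pct = 100 * amp, fill_fraction = fill,
         mask = mask),
    class = "stripe_stats")
}

#' @export
print.stripe_stats <- function(x, ...) {
  if (x$n_stripes == 0) {
    cat("<stripe_stats> no stripes detected\n")
  } else {
    cat(sprintf(
      "<stripe_stats> %d stripes, elevation %.2f%%, orientation %.1f deg, fraction %.3f\n",
      x$n_stripes, x$elevation_percent, x$stripe_orientation,
      x$stripe_pixel_fraction))
  }
  invisible(x)
}
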