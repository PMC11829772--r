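# Morphometry: fiber orientation distributions, the nematic order
# parameter relative to the AP axis, fiber lengths and chamber aspect
# ratios.

#' Orientation distribution of image texture
#'
#' Per-pixel orientations from the smoothed structure tensor: image
#' gradients (central differences after a light Gaussian pre-smoothing) are
#' accumulated into the tensor J = G_sigma * (grad grad^T); the local fiber
#' direction is the tensor's minor eigenvector (perpendicular to the
#' dominant gradient). Orientations are histogrammed over [0, 180) degrees
#' with the AP axis at 0/180, weighted by the local gradient energy
#' trace(J).
#'
#' @param image numeric matrix (rows = y, columns = x along the AP axis).
#' @param bin_width histogram bin width (degrees).
#' @param sigma_grad pre-smoothing scale (pixels).
#' @param sigma_tensor tensor smoothing scale (pixels).
#' @return list (class `orientation_distribution`): `bin_centers`
#'   (degrees), `frequency` (sums to 1).
#' @export
orientation_distribution <- function(image, bin_width = 2, sigma_grad = 1,
                                     sigma_tensor = 2) {
  stopifnot(is.matrix(image), 180 %% bin_width == 0)
  if (stats::sd(as.vector(image)) == 0) {
    stop("flat image: orientation undefined")
  }
  x <- gaussian_blur(image, sigma_grad)
  n <- nrow(x); m <- ncol(x)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  gx[, 2:(m - 1)] <- (x[, 3:m] - x[, 1:(m - 2)]) / 2
  gy[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / 2
  jxx <- gaussian_blur(gx * gx, sigma_tensor)
  jyy <- gaussian_blur(gy * gy, sigma_tensor)
  jxy <- gaussian_blur(gx * gy, sigma_tensor)
  # major eigenvector = dominant gradient direction; fiber is perpendicular
  theta <- (0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90) %% 180
  w <- jxx + jyy
  edges <- seq(0, 180, by = bin_width)
  bin <- findInterval(theta, edges, rightmost.closed = FALSE)
  bin[bin > length(edges) - 1] <- 1L   # theta == 180 wraps to 0
  freq <- vapply(seq_len(length(edges) - 1),
                 function(b) sum(w[bin == b]), numeric(1))
  freq <- freq / sum(freq)
  structure(list(bin_centers = edges[-length(edges)] + bin_width / 2,
                 frequency = freq),
            class = "orientation_distribution")
}

#' Nematic order parameter relative to the AP axis
#'
#' S_AP = sum_theta f(theta) cos(2 (theta - 90 deg)): +1 for alignment
#' perpendicular to the AP axis, -1 for parallel alignment, 0 for an
#' isotropic distribution.
#'
#' @param dist an `orientation_distribution`, or any list with
#'   `bin_centers` (degrees) and `frequency`.
#' @return S_AP in `[-1, 1]`.
#' @export
order_parameter_SAP <- function(dist) {
  f <- dist$frequency
  if (abs(sum(f) - 1) > 1e-9) {
    warning("unnormalized distribution; normalizing")
    f <- f / sum(f)
  }
  sum(f * cos(2 * (dist$bin_centers - 90) * pi / 180))
}

#' Fiber lengths by skeletonization
#'
#' Global threshold, Zhang-Suen thinning, pruning of spurs shorter than 3
#' pixels, and per-component geodesic length (8-neighbour chain length)
#' times the pixel size.
#'
#' @param image numeric matrix.
#' @param pixel_size um per pixel.
#' @param threshold_method `"otsu"` or `"quantile"`.
#' @param threshold_quantile quantile used when `threshold_method =
#'   "quantile"`.
#' @param min_length_um discard skeleton fragments shorter than this.
#' @return list (class `fiber_length_stats`): `lengths` (um),
#'   `mean_length`, `n_fibers`.
#' @export
fiber_lengths <- function(image, pixel_size = 0.1,
                          threshold_method = c("otsu", "quantile"),
                          threshold_quantile = 0.9, min_length_um = 0.5) {
  threshold_method <- match.arg(threshold_method)
  rng <- range(image)
  empty <- structure(list(lengths = numeric(0), mean_length = NA_real_,
                          n_fibers = 0L), class = "fiber_length_stats")
  if (diff(rng) == 0) return(empty)
  norm <- (image - rng[1]) / diff(rng)
  thr <- if (threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(norm))
  } else {
    stats::quantile(norm, threshold_quantile)
  }
  bw <- norm > thr
  if (!any(bw)) return(empty)
  skel <- prune_spurs(zhang_suen_thin(bw), 3L)
  if (!any(skel)) return(empty)
  labels <- label8(skel)
  lens <- vapply(seq_len(max(labels)), function(l) {
    skeleton_length_px(labels == l) * pixel_size
  }, numeric(1))
  lens <- lens[lens >= min_length_um]
  if (!length(lens)) return(empty)
  structure(list(lengths = lens, mean_length = mean(lens),
                 n_fibers = length(lens)),
            class = "fiber_length_stats")
}

#' Aspect ratio of a chamber mask
#'
#' Ratio of the major to the minor axis of the mask's second-moment
#' (equivalent) ellipse; >= 1 by construction and invariant under rotation.
#'
#' @param mask logical matrix.
#' @return aspect ratio.
#' @export
aspect_ratio <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("mask too small")
  xs <- idx[, 2]; ys <- idx[, 1]
  mxx <- stats::var(xs) + 1 / 12
  myy <- stats::var(ys) + 1 / 12
  mxy <- stats::cov(xs, ys)
  tr <- mxx + myy
  disc <- sqrt(pmax((mxx - myy)^2 / 4 + mxy^2, 0))
  sqrt((tr / 2 + disc) / (tr / 2 - disc))
}
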