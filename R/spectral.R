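# Fourier analysis of topography maps.

#' Two-dimensional discrete Fourier transform of a map
#'
#' Unnormalized forward transform
#' \eqn{\hat F(u,v) = \sum_{j,k} F(j,k)\,\omega^{ju+kv}} with
#' \eqn{\omega = e^{-2\pi i/N}} and 0-based indices, i.e. the standard DFT
#' convention of `stats::fft`. The map must be square and free of invalid
#' pixels (crop defects first, e.g. with [crop_valid_square()]).
#'
#' @param map a square [scalar_map] with all pixels valid.
#' @return list (class `map_spectrum`): `spectrum` (complex N x N matrix,
#'   `[u+1, v+1]`; v pairs with the x / fast axis), `N`, `L` (map size, um).
#' @export
dft2 <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  v <- map$values
  if (nrow(v) != ncol(v)) stop("map must be square; crop first")
  if (!all(map$mask)) stop("map contains invalid pixels; crop first")
  structure(list(spectrum = stats::fft(v), N = nrow(v), L = map_size(map)),
            class = "map_spectrum")
}

#' Largest centred valid square of a map
#'
#' Helper used before [dft2()]: shrinks symmetrically from the borders
#' until the sub-map has no invalid pixels.
#'
#' @param map a [scalar_map].
#' @return square [scalar_map] with all pixels valid.
#' @export
crop_valid_square <- function(map) {
  v <- map$values; ok <- map$mask
  n <- nrow(v); m <- ncol(v)
  side <- min(n, m)
  r0 <- (n - side) %/% 2; c0 <- (m - side) %/% 2
  ri <- r0 + seq_len(side); ci <- c0 + seq_len(side)
  while (side >= 8 && !all(ok[ri, ci])) {
    side <- side - 2L
    r0 <- (n - side) %/% 2; c0 <- (m - side) %/% 2
    ri <- r0 + seq_len(side); ci <- c0 + seq_len(side)
  }
  if (side < 8) stop("no defect-free square of at least 8x8 pixels")
  scalar_map(v[ri, ci], map$pixel_size, map$units)
}

#' Fourier profile in the x direction
#'
#' Aggregates the spectrum magnitude over the u (slow-axis) frequency index
#' at each x-frequency v: amplitude(v) = mean_u |F(u,v)|, reported for
#' v = 0..floor(N/2) against the inverse wavelength 1/lambda_x = v/L.
#' (Mean rather than sum over u; the two differ by a constant factor and
#' give identical orderings.)
#'
#' @param spec a `map_spectrum` from [dft2()].
#' @return list (class `fourier_profile`): `inverse_wavelength` (1/um),
#'   `amplitude`, `map_size` (um).
#' @export
x_profile <- function(spec) {
  stopifnot(inherits(spec, "map_spectrum"))
  vmax <- floor(spec$N / 2)
  amp <- colMeans(Mod(spec$spectrum))[seq_len(vmax + 1)]
  structure(list(inverse_wavelength = (0:vmax) / spec$L,
                 amplitude = unname(amp), map_size = spec$L),
            class = "fourier_profile")
}

#' Pool Fourier profiles onto a reference grid
#'
#' Profiles from maps smaller than `reference_size` are linearly
#' interpolated onto the inverse-wavelength grid of the reference-size maps
#' before averaging, so Fourier coefficients measured at different
#' frequency spacings can be pooled.
#'
#' @param profiles list of `fourier_profile`s.
#' @param reference_size reference map size (um).
#' @return list (class `pooled_profile`): `inverse_wavelength`, `mean`,
#'   `sem` (`NA` where fewer than 2 profiles contribute), `n_profiles`.
#' @export
pool_profiles <- function(profiles, reference_size = 20) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "fourier_profile")))
  sizes <- vapply(profiles, function(p) p$map_size, numeric(1))
  ref <- which(abs(sizes - reference_size) < 1e-9)
  ref <- if (length(ref)) ref[1] else which.max(sizes)
  grid <- profiles[[ref]]$inverse_wavelength
  vals <- vapply(profiles, function(p) {
    if (length(p$inverse_wavelength) == length(grid) &&
        all(abs(p$inverse_wavelength - grid) < 1e-12)) return(p$amplitude)
    stats::approx(p$inverse_wavelength, p$amplitude, xout = grid)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  nn <- rowSums(!is.na(vals))
  mu <- rowMeans(vals, na.rm = TRUE)
  sem <- apply(vals, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) NA_real_ else stats::sd(r) / sqrt(length(r))
  })
  structure(list(inverse_wavelength = grid, mean = mu, sem = sem,
                 n_profiles = length(profiles), n_per_point = nn),
            class = "pooled_profile")
}
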