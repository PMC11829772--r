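# Plain-text / TIFF serialization: force volumes as TSV + JSON sidecar,
# maps as single-channel TIFF + JSON sidecar, stats as CSV, configs as
# YAML. No proprietary AFM formats; the TSV curve format is the import
# shim for external force data.

#' Write a force volume to TSV (+ JSON sidecar)
#'
#' Long-format TSV with columns `pixel_i`, `pixel_j`, `z_nm`, `force_pN`
#' (truncated samples omitted); the sidecar (`<path>.json`) stores the
#' grid, probe and reference metadata.
#'
#' @param fv a [force_volume].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_force_volume <- function(fv, path) {
  ny <- fv$dim_grid[1]
  idx <- seq_len(ncol(fv$force))
  pixel_i <- ((idx - 1L) %% ny) + 1L
  pixel_j <- ((idx - 1L) %/% ny) + 1L
  df <- data.frame(
    pixel_i = rep(pixel_i, each = length(fv$z)),
    pixel_j = rep(pixel_j, each = length(fv$z)),
    z_nm = rep(fv$z, times = length(idx)),
    force_pN = as.vector(fv$force)
  )
  df <- df[!is.na(df$force_pN), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(dim_grid = fv$dim_grid, pixel_size = fv$pixel_size,
               z_ref = fv$z_ref, z_step = fv$z[2] - fv$z[1],
               probe = unclass(fv$probe))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a force volume written by [write_force_volume()]
#'
#' @param path TSV path (sidecar `<path>.json` must exist).
#' @return a [force_volume].
#' @export
read_force_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(path)
  probe <- do.call(probe_params, meta$probe[c("spring_constant",
                                              "half_angle", "poisson_ratio",
                                              "setpoint_force",
                                              "pyramid_coef")])
  z <- sort(unique(df$z_nm))
  ny <- meta$dim_grid[1]
  npix <- prod(meta$dim_grid)
  force <- matrix(NA_real_, length(z), npix)
  pix <- (df$pixel_j - 1L) * ny + df$pixel_i
  zi <- match(df$z_nm, z)
  force[cbind(zi, pix)] <- df$force_pN
  force_volume(z, force, meta$dim_grid, probe, meta$pixel_size, meta$z_ref)
}

#' Write a scalar map as single-channel TIFF (+ JSON sidecar)
#'
#' The TIFF stores the field rescaled to `[0, 1]` as 32-bit float; the
#' sidecar records the affine scale (`min`, `max`), pixel size and units,
#' so [read_map()] reconstructs physical values exactly up to float
#' precision.
#'
#' @param map a [scalar_map].
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  v <- map$values
  v[!map$mask] <- NA
  rng <- range(v, na.rm = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- (v - rng[1]) / scale
  norm[is.na(norm)] <- 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  meta <- list(min = rng[1], max = rng[2], pixel_size = map$pixel_size,
               units = map$units, mask_invalid = which(!map$mask))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scalar map written by [write_map()]
#' @param path TIFF path.
#' @return a [scalar_map].
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  norm <- tiff::readTIFF(path)
  v <- norm * (meta$max - meta$min) + meta$min
  mask <- matrix(TRUE, nrow(v), ncol(v))
  if (length(meta$mask_invalid)) mask[meta$mask_invalid] <- FALSE
  v[!mask] <- NA
  scalar_map(v, meta$pixel_size, meta$units, mask)
}

#' Write / read a run configuration as YAML
#'
#' Configurations round-trip losslessly through YAML.
#' @param config a [run_config].
#' @param path YAML path.
#' @return `path` invisibly (write); a [run_config] (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  # restore the numeric storage modes the YAML scalar syntax cannot keep
  ints <- c("n_pixels", "seed", "median_window", "sg_window", "sg_order",
            "n_chambers")
  nums <- c("side_length", "z_step", "force_noise_sd", "fit_max_force",
            "stripe_q", "stripe_elongation_min")
  for (f in intersect(ints, names(obj))) obj[[f]] <- as.integer(obj[[f]])
  for (f in intersect(nums, names(obj))) obj[[f]] <- as.numeric(obj[[f]])
  structure(obj, class = "run_config")
}
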