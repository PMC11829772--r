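# End-to-end orchestration: simulate -> fit -> maps -> stripes -> Fourier
# -> ratio statistics, with explicit seeds and a checksummed manifest.

#' Build a run configuration
#'
#' @param preset preset name (`"control"`, `"dwirs"`, `"fat2null"`) or a
#'   [genotype_preset].
#' @param side_length scan side (um).
#' @param n_pixels grid points per side.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param z_step piezo step (nm).
#' @param force_noise_sd force noise (pN).
#' @param fit_max_force Hertz-Sneddon fit range (pN).
#' @param median_window,sg_window,sg_order smoothing parameters.
#' @param stripe_q,stripe_elongation_min stripe segmentation parameters.
#' @param n_chambers chambers per region for the ratio test.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = "control", side_length = 10,
                       n_pixels = 64L, seed = 1L, z_step = 2,
                       force_noise_sd = 10, fit_max_force = 500,
                       median_window = 3L, sg_window = 5L, sg_order = 2L,
                       stripe_q = 75, stripe_elongation_min = 2,
                       n_chambers = 8L, out_dir = tempfile("bmmech_run_")) {
  if (inherits(preset, "genotype_preset")) preset <- preset$name
  structure(list(preset = preset, side_length = side_length,
                 n_pixels = as.integer(n_pixels), seed = as.integer(seed),
                 z_step = z_step, force_noise_sd = force_noise_sd,
                 fit_max_force = fit_max_force,
                 median_window = as.integer(median_window),
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order), stripe_q = stripe_q,
                 stripe_elongation_min = stripe_elongation_min,
                 n_chambers = as.integer(n_chambers), out_dir = out_dir),
            class = "run_config")
}

#' Run the simulated AFM pipeline for one genotype
#'
#' Stages: generate ground-truth fields and a force volume (synthetic
#' scan), fit every curve to stiffness/topography maps, level and smooth,
#' quantify stripes, compute the Fourier x-profile of the topography, the
#' 5 x 5 um region median, the topography-stiffness correlation, and the
#' center-to-pole ratio test on simulated per-chamber samples. Writes the
#' summary tables under `config$out_dir` and returns them with a
#' checksummed manifest; deterministic for a fixed seed.
#'
#' @param config a [run_config].
#' @return list (class `pipeline_run`): `summary` (one-row data frame),
#'   `stripes`, `profile`, `ratio`, `manifest` (file, md5), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  preset <- genotype_presets(config$preset)
  geom <- scan_geometry(config$side_length, config$n_pixels)
  probe <- probe_params()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- gen_truth_fields(preset, geom, seed = config$seed)
  fv <- gen_force_volume(truth$stiffness, truth$topography, probe,
                         z_step = config$z_step,
                         force_noise_sd = config$force_noise_sd,
                         seed = config$seed + 1000L)
  fit <- fit_force_volume(fv, fit_max_force = config$fit_max_force)

  topo <- level_topography(fit$topography_contact)
  topo_s <- smooth_map(topo, config$median_window, config$sg_window,
                       config$sg_order)
  stiff_s <- smooth_map(fit$stiffness, config$median_window,
                        config$sg_window, config$sg_order)

  stripes <- quantify_stripes(fit$stiffness, q = config$stripe_q,
                              elongation_min = config$stripe_elongation_min)
  profile <- x_profile(dft2(crop_valid_square(topo_s)))
  med <- region_median(stiff_s, square_side = 5)
  corr <- map_correlation(topo_s, stiff_s)
  samples <- gen_chamber_samples(preset, n_chambers = config$n_chambers,
                                 seed = config$seed + 2000L)
  rt <- ratio_test(samples$center, samples$pole)

  summary <- data.frame(
    genotype = preset$name, seed = config$seed,
    bulk_truth_kPa = preset$bulk_modulus,
    stiffness_median_kPa = med,
    stripe_elevation_pct = stripes$elevation_percent,
    stripe_mean_length_um = if (stripes$n_stripes) mean(stripes$stripe_lengths)
      else NA_real_,
    stripe_orientation_deg = stripes$stripe_orientation,
    topo_stiffness_corr = corr,
    center_pole_ratio = rt$ratio, ratio_sem = rt$sem,
    ratio_T = rt$T, ratio_dof = rt$dof, ratio_p = rt$p
  )

  paths <- c(summary = file.path(config$out_dir, "summary.csv"),
             profile = file.path(config$out_dir, "fourier_profile.csv"),
             config = file.path(config$out_dir, "config.yaml"))
  utils::write.csv(summary, paths["summary"], row.names = FALSE)
  utils::write.csv(data.frame(inverse_wavelength = profile$inverse_wavelength,
                              amplitude = profile$amplitude),
                   paths["profile"], row.names = FALSE)
  write_config(config, paths["config"])
  manifest <- data.frame(file = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))))

  structure(list(summary = summary, stripes = stripes, profile = profile,
                 ratio = rt, manifest = manifest, config = config),
            class = "pipeline_run")
}

#' Combine pipeline runs into a genotype comparison table
#'
#' @param runs list of `pipeline_run`s (possibly empty).
#' @return data frame with one row per run (medians, stripe stats,
#'   correlation, ratio-test results), mirroring a per-genotype comparison
#'   layout.
#' @export
summarize_runs <- function(runs) {
  if (!length(runs)) {
    return(data.frame(genotype = character(0)))
  }
  stopifnot(all(vapply(runs, inherits, TRUE, "pipeline_run")))
  do.call(rbind, lapply(runs, function(r) r$summary))
}
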