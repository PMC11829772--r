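#!/usr/bin/env Rscript
# Generate the synthetic study data: for each genotype preset (control,
# fat2-ΔWIRS, fat2-null), a ground-truth stiffness/topography field pair,
# a simulated AFM force volume over the central region, fiber images,
# chamber masks, trail records and rotating frame pairs. Everything
# downstream (02-07) consumes these files.
#
# Conditions: 10 um x 64 px force-volume scans (2 nm z-step, 10 pN force
# noise, 0.6 nN setpoint), 20 um x 128 px stiffness maps for stripe
# analysis, stage-14 chamber axes 230 x 100 um, control rotation 82 deg/h
# (trails) and 0.6 um/s (ex vivo).

suppressPackageStartupMessages(library(bmmech))
seed <- 20250101L
out <- "scratch/analysis_data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

presets <- genotype_presets()
probe <- probe_params()

for (nm in names(presets)) {
  # force-volume scan of the chamber center
  geom <- scan_geometry(10, 64)
  tr <- gen_truth_fields(presets[[nm]], geom, seed = seed)
  fv <- gen_force_volume(tr$stiffness, tr$topography, probe,
                         z_step = 2, force_noise_sd = 10, seed = seed + 1L)
  write_force_volume(fv, file.path(out, paste0(nm, "_scan.tsv")))
  write_map(tr$stiffness, file.path(out, paste0(nm, "_stiff_truth.tif")))
  write_map(tr$topography, file.path(out, paste0(nm, "_topo_truth.tif")))

  # wide map for stripe quantification
  geom_w <- scan_geometry(20, 128)
  tw <- gen_truth_fields(presets[[nm]], geom_w, seed = seed + 2L)
  write_map(tw$stiffness, file.path(out, paste0(nm, "_stiff_wide.tif")))
  write_map(tw$topography, file.path(out, paste0(nm, "_topo_wide.tif")))

  seed <- seed + 10L
}

# fiber images: aligned (control-like) and disordered (null-like)
fi_ctrl <- gen_fiber_image(400, mean_angle = 90, kappa = 6,
                           length_mean = 6, image_size = 256, seed = 31L)
fi_null <- gen_fiber_image(400, mean_angle = 90, kappa = 0.2,
                           length_mean = 6, image_size = 256, seed = 32L)
invisible(tiff::writeTIFF(
  (fi_ctrl$image - min(fi_ctrl$image)) / diff(range(fi_ctrl$image)),
  file.path(out, "fibers_control.tif"), bits.per.sample = 32L))
invisible(tiff::writeTIFF(
  (fi_null$image - min(fi_null$image)) / diff(range(fi_null$image)),
  file.path(out, "fibers_null.tif"), bits.per.sample = 32L))

cat("Synthetic inputs written to", out, "\n")
cat("Genotypes:", paste(names(presets), collapse = ", "), "\n")
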