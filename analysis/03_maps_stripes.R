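#!/usr/bin/env Rscript
# Level and smooth the maps, quantify the Collagen-IV-like stiffness
# stripes, and correlate topography with stiffness.
# Findings to check: control stripes ~10% above bulk and perpendicular to
# the AP axis, ΔWIRS stripes ~7% and shorter, no stripes in the null;
# topography-stiffness correlation negative for control only.

suppressPackageStartupMessages(library(bmmech))
out <- "results"
data_dir <- "scratch/analysis_data"
rows <- list()
for (nm in c("control", "dwirs", "fat2null")) {
  stiff_w <- read_map(file.path(data_dir, paste0(nm, "_stiff_wide.tif")))
  st <- quantify_stripes(stiff_w)

  topo_fit <- read_map(file.path(data_dir, paste0(nm, "_topo_fit.tif")))
  stiff_fit <- read_map(file.path(data_dir, paste0(nm, "_stiff_fit.tif")))
  corr <- map_correlation(smooth_map(level_topography(topo_fit)),
                          smooth_map(stiff_fit))

  rows[[nm]] <- data.frame(
    genotype = nm,
    stripes_detected = st$n_stripes > 0,
    elevation_pct = st$elevation_percent,
    mean_length_um = if (st$n_stripes) mean(st$stripe_lengths) else NA,
    orientation_deg = st$stripe_orientation,
    band_p = st$band_p,
    topo_stiff_corr = corr)
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "stripes_correlation.csv"), row.names = FALSE)
print(tab, row.names = FALSE)
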