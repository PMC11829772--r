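Package: bmmech
Title: Basement-Membrane Mechanics of Drosophila Egg Chambers from AFM and
    Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for basement-membrane mechanics of
    Drosophila egg chambers: Hertz-Sneddon (pyramidal indenter) fitting of
    AFM force-volume scans into topography and stiffness maps, map levelling
    and smoothing, quantification of Collagen-IV-like stiffness stripes,
    Fourier topography profiles, fiber orientation distributions and the
    nematic order parameter relative to the anteroposterior axis, fiber
    lengths, egg-chamber aspect ratios, rotation kinematics (matrix-trail
    geometry and ex vivo frame registration), and a center-to-pole
    stiffness-ratio test with Welch-Satterthwaite degrees of freedom. A
    synthetic-data generator emulates the three study genotypes so the full
    pipeline is testable without proprietary microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
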