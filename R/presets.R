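# Genotype presets, scan geometry and probe parameters.
#
# The presets collect the genotype-level magnitudes reported for stage 8 egg
# chambers: bulk basement-membrane stiffness, the elevation and length of the
# Collagen-IV-like stiffness stripes, the sign of the topography-stiffness
# correlation, and the center-to-pole stiffness ratio. They are the ground
# truth that the synthetic generators emulate.

#' Genotype preset
#'
#' Ground-truth parameters of a simulated genotype.
#'
#' @param name label.
#' @param bulk_modulus median of the bulk stiffness field (kPa).
#' @param stripe_elevation fractional stiffness excess of stripes over bulk
#'   (0.10 = stripes 10% stiffer).
#' @param stripe_length stripe segment length (um).
#' @param stripe_spacing distance between stripe center lines (um).
#' @param stripe_angle stripe long-axis angle, degrees from the AP axis.
#' @param topo_stiffness_corr target Pearson correlation between topography
#'   and stiffness, in `[-1, 1]`.
#' @param center_pole_ratio ratio of mean center stiffness to mean posterior
#'   pole stiffness.
#' @param noise_cv pixel-to-pixel lognormal coefficient of variation of the
#'   bulk stiffness field.
#' @return object of class `genotype_preset`.
#' @export
genotype_preset <- function(name, bulk_modulus, stripe_elevation,
                            stripe_length, stripe_spacing = 5,
                            stripe_angle = 90, topo_stiffness_corr = 0,
                            center_pole_ratio = 1, noise_cv = 0.2) {
  vals <- c(bulk_modulus, stripe_elevation, stripe_length, stripe_spacing,
            stripe_angle, topo_stiffness_corr, center_pole_ratio, noise_cv)
  if (any(!is.finite(vals))) stop("preset values must be finite")
  stopifnot(bulk_modulus > 0, stripe_elevation >= 0,
            abs(topo_stiffness_corr) <= 1, center_pole_ratio > 0,
            noise_cv >= 0, stripe_spacing > 0, stripe_length >= 0)
  structure(
    list(name = name, bulk_modulus = bulk_modulus,
         stripe_elevation = stripe_elevation, stripe_length = stripe_length,
         stripe_spacing = stripe_spacing, stripe_angle = stripe_angle,
         topo_stiffness_corr = topo_stiffness_corr,
         center_pole_ratio = center_pole_ratio, noise_cv = noise_cv),
    class = "genotype_preset"
  )
}

#' Shipped genotype presets
#'
#' Three presets matching the study genotypes:
#' \describe{
#'   \item{control}{bulk 20 kPa, 10% stripes of length 8 um, topography
#'     negatively correlated with stiffness (-0.4), center:pole ratio 1.3.}
#'   \item{dwirs}{fat2 lacking the WIRS motifs: bulk 11 kPa (~45% softer
#'     than control), 7% stripes that are short (2.5 um), no
#'     topography-stiffness correlation, center:pole ratio 1.25.}
#'   \item{fat2null}{fat2 null: bulk 7 kPa (~70% softer), no stripes, no
#'     correlation, flat center:pole ratio 1.}
#' }
#'
#' @param name optional preset name; if omitted the full named list is
#'   returned.
#' @return a `genotype_preset` or a named list of the three presets.
#' @export
genotype_presets <- function(name = NULL) {
  presets <- list(
    control = genotype_preset("control", bulk_modulus = 20,
                              stripe_elevation = 0.10, stripe_length = 8,
                              topo_stiffness_corr = -0.4,
                              center_pole_ratio = 1.3),
    dwirs = genotype_preset("dwirs", bulk_modulus = 11,
                            stripe_elevation = 0.07, stripe_length = 2.5,
                            topo_stiffness_corr = 0,
                            center_pole_ratio = 1.25),
    fat2null = genotype_preset("fat2null", bulk_modulus = 7,
                               stripe_elevation = 0, stripe_length = 0,
                               topo_stiffness_corr = 0,
                               center_pole_ratio = 1)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset: ", name, " (use control, dwirs or fat2null)")
  }
  presets[[name]]
}

#' AFM scan geometry
#'
#' @param side_length scan side length in micrometres (5 to 20 in the study).
#' @param n_pixels grid points per side (128 or 180 in the study; >= 8).
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(side_length = 20, n_pixels = 128L) {
  stopifnot(side_length > 0, n_pixels >= 8)
  structure(list(side_length = side_length, n_pixels = as.integer(n_pixels),
                 fast_axis = "x"),
            class = "scan_geometry")
}

#' AFM probe parameters
#'
#' Quadratic pyramidal tip. The pyramid coefficient `b` enters the contact
#' model F = b * E / (1 - nu^2) * tan(alpha) * delta^2; the four-sided
#' pyramid value 0.7453 is the default (the cone coefficient 2/pi is a
#' common alternative).
#'
#' @param spring_constant cantilever spring constant (N/m).
#' @param half_angle tip half-angle to face (degrees).
#' @param poisson_ratio sample Poisson ratio.
#' @param setpoint_force indentation setpoint (nN).
#' @param pyramid_coef geometry coefficient `b` of the contact model.
#' @return object of class `probe_params`.
#' @export
probe_params <- function(spring_constant = 0.03, half_angle = 35,
                         poisson_ratio = 0.5, setpoint_force = 0.6,
                         pyramid_coef = 0.7453) {
  stopifnot(spring_constant > 0, half_angle > 0, setpoint_force > 0,
            pyramid_coef > 0, poisson_ratio >= 0, poisson_ratio < 0.5 + 1e-9)
  structure(
    list(spring_constant = spring_constant, half_angle = half_angle,
         poisson_ratio = poisson_ratio, setpoint_force = setpoint_force,
         pyramid_coef = pyramid_coef),
    class = "probe_params"
  )
}

#' Contact-model prefactor C (pN/nm^2)
#'
#' F(pN) = C * delta(nm)^2 with C = b * E / (1 - nu^2) * tan(alpha),
#' converted so that E is in kPa.
#'
#' @param E_kPa effective Young's modulus (kPa); may be a vector.
#' @param probe a [probe_params] object.
#' @return C in pN/nm^2.
#' @export
hertz_coefficient <- function(E_kPa, probe) {
  probe$pyramid_coef * tan(probe$half_angle * pi / 180) *
    E_kPa / (1 - probe$poisson_ratio^2) * 1e-3
}

#' Invert the contact-model prefactor to a modulus (kPa)
#' @param C prefactor in pN/nm^2.
#' @param probe a [probe_params] object.
#' @return effective Young's modulus in kPa.
#' @export
hertz_modulus <- function(C, probe) {
  C * (1 - probe$poisson_ratio^2) /
    (probe$pyramid_coef * tan(probe$half_angle * pi / 180)) * 1e3
}

#' Indentation depth at a given force
#'
#' Solves F = C * delta^2 for delta; used e.g. to find the indentation at
#' the 500 pN fit-range limit.
#'
#' @param force_pN force (pN).
#' @param E_kPa effective Young's modulus (kPa).
#' @param probe a [probe_params] object.
#' @return indentation depth in nm.
#' @export
indentation_at_force <- function(force_pN, E_kPa, probe = probe_params()) {
  sqrt(force_pN / hertz_coefficient(E_kPa, probe))
}

#' @keywords internal
setpoint_pN <- function(probe) probe$setpoint_force * 1000

#' @keywords internal
spring_pN_per_nm <- function(probe) probe$spring_constant * 1000
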