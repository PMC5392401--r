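#' Schematic eye constants (Liou-Brennan, aphakic use)
#'
#' Named constants of the rotationally symmetric schematic eye hosting the
#' telescopes: anterior/posterior corneal radii and conic constants,
#' corneal thickness, anterior chamber depth (posterior cornea to pupil
#' plane), total axial length, retinal radius, and media indices at
#' 587.6 nm. The nasal pupil decentration and visual-axis tilt of the
#' original model are dropped because the host model used here is
#' rotationally symmetric. Values can be overridden via
#' [simulation_config()].
#'
#' @return named list of constants (mm and refractive indices).
#' @export
eye_constants <- function() {
  list(
    cornea_anterior_radius  = 7.77,   # mm
    cornea_anterior_conic   = -0.18,
    cornea_posterior_radius = 6.40,   # mm
    cornea_posterior_conic  = -0.60,
    cornea_thickness        = 0.50,   # mm
    anterior_chamber_depth  = 3.16,   # mm, posterior cornea to pupil plane
    axial_length            = 23.95,  # mm, anterior cornea to retina
    retina_radius           = -12.0,  # mm, concave toward the cornea
    n_cornea                = 1.376,
    n_aqueous               = 1.336,
    n_lens_material         = 1.55    # telescope lens material
  )
}

#' Simulation configuration
#'
#' Bundles the study conditions: design wavelength (587.6 nm green light),
#' a 3 mm entrance pupil, the object vergence (infinity for the far target,
#' 0.41 m reading distance for near), pupil sampling density, CSF
#' parameters, and any overrides of the schematic-eye constants.
#'
#' @param object_distance_m object distance in metres (`Inf` or 0.41).
#' @param wavelength_nm wavelength in nanometres.
#' @param pupil_diameter_mm stop diameter in mm.
#' @param n_grid pupil sampling: rays are aimed at an `n_grid` x `n_grid`
#'   square grid inscribed about the stop disc.
#' @param pad_factor zero-padding factor for PSF/OTF grids.
#' @param flat_retina if `TRUE`, model the retina as a plane (debugging).
#' @param rms_remove terms removed before RMS: `c("piston","tilt")`
#'   (default) or `"piston"` alone.
#' @param csf_params neural CSF parameters, see [csf_n()].
#' @param eye_overrides named list overriding entries of [eye_constants()].
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(object_distance_m = Inf,
                              wavelength_nm = 587.6,
                              pupil_diameter_mm = 3,
                              n_grid = 64,
                              pad_factor = 4,
                              flat_retina = FALSE,
                              rms_remove = c("piston", "tilt"),
                              csf_params = NULL,
                              eye_overrides = list()) {
  ec <- eye_constants()
  for (nm in names(eye_overrides)) {
    if (!nm %in% names(ec)) stop("unknown eye constant: ", nm)
    ec[[nm]] <- eye_overrides[[nm]]
  }
  cfg <- list(object_distance_m = object_distance_m,
              wavelength_nm = wavelength_nm,
              pupil_diameter_mm = pupil_diameter_mm,
              n_grid = n_grid, pad_factor = pad_factor,
              flat_retina = flat_retina,
              rms_remove = rms_remove,
              csf_params = csf_params %||% csf_default_params(),
              eye = ec)
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the aphakic schematic eye
#'
#' Constructs the host eye with the crystalline lens removed: the
#' two-surface aspheric cornea, an aqueous-filled interior (n = 1.336 from
#' the posterior cornea all the way to the retina), the 3 mm aperture stop
#' at the pupil plane, and a curved retinal image surface. The model is
#' rotationally symmetric about the optical axis.
#'
#' @param config a [simulation_config()].
#' @return an [optical_system()] with 4 surfaces (cornea x2, stop, retina).
#' @export
build_aphakic_eye <- function(config = simulation_config()) {
  ec <- config$eye
  stop_to_retina <- ec$axial_length - ec$cornea_thickness -
    ec$anterior_chamber_depth
  retina_R <- if (config$flat_retina) Inf else ec$retina_radius
  surfaces <- list(
    surface("conic_asphere", radius = ec$cornea_anterior_radius,
            conic_k = ec$cornea_anterior_conic, semi_diameter = 6,
            thickness_after = ec$cornea_thickness, n_after = ec$n_cornea,
            label = "cornea anterior"),
    surface("conic_asphere", radius = ec$cornea_posterior_radius,
            conic_k = ec$cornea_posterior_conic, semi_diameter = 6,
            thickness_after = ec$anterior_chamber_depth,
            n_after = ec$n_aqueous, label = "cornea posterior"),
    surface("stop", semi_diameter = config$pupil_diameter_mm / 2,
            thickness_after = stop_to_retina, n_after = ec$n_aqueous,
            label = "pupil (stop)"),
    surface("image", radius = retina_R, semi_diameter = 14,
            n_after = ec$n_aqueous, label = "retina")
  )
  optical_system(surfaces, stop_index = 3,
                 object_distance = config$object_distance_m,
                 wavelength_nm = config$wavelength_nm)
}
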