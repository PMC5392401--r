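#' Serialize an optical system to YAML
#'
#' Writes the ordered surface list (fields as in [surface()]), the stop
#' index, object distance and wavelength to a YAML document; the inverse
#' reads it back. Infinite radii and object distances are stored as the
#' string `".inf"` understood by the YAML spec.
#'
#' @param sys an [optical_system()].
#' @param file path to write (or `NULL` to return the YAML text).
#' @return invisibly `file`, or the YAML string when `file` is `NULL`.
#' @export
system_to_yaml <- function(sys, file = NULL) {
  doc <- list(
    stop_index = sys$stop_index,
    object_distance = if (is.finite(sys$object_distance))
      sys$object_distance else ".inf",
    wavelength_nm = sys$wavelength_nm,
    n_object = sys$n_object,
    surfaces = lapply(sys$surfaces, function(s) {
      s$radius <- if (is.finite(s$radius)) s$radius else ".inf"
      unclass(s)
    })
  )
  txt <- yaml::as.yaml(doc, precision = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' @rdname system_to_yaml
#' @param file path of a YAML document written by [system_to_yaml()].
#' @export
system_from_yaml <- function(file) {
  doc <- yaml::read_yaml(file)
  inf_fix <- function(x) if (identical(x, ".inf")) Inf else x
  surfaces <- lapply(doc$surfaces, function(s) {
    s$radius <- inf_fix(s$radius)
    do.call(surface, s)
  })
  optical_system(surfaces, stop_index = doc$stop_index,
                 object_distance = inf_fix(doc$object_distance),
                 wavelength_nm = doc$wavelength_nm,
                 n_object = doc$n_object %||% 1)
}

#' Export a wavefront map as a CSV grid
#'
#' One row per pupil sample: grid indices, normalized coordinates, OPD in
#' waves, and the validity mask.
#'
#' @param map a `wavefront_map`.
#' @param file output path.
#' @return invisibly `file`.
#' @export
wavefront_to_csv <- function(map, file) {
  utils::write.csv(data.frame(iu = map$iu, iv = map$iv, u = map$u, v = map$v,
                              opd_waves = map$opd, mask = map$mask),
                   file, row.names = FALSE)
  invisible(file)
}

#' Export a Zernike spectrum as CSV
#'
#' Columns: OSA index, radial order n, azimuthal frequency m, coefficient
#' in waves and in micrometres.
#'
#' @param spec a [fit_zernike()] result.
#' @param file output path.
#' @param wavelength_nm wavelength used for the micrometre conversion.
#' @return invisibly `file`.
#' @export
zernike_to_csv <- function(spec, file, wavelength_nm = 587.6) {
  utils::write.csv(data.frame(spec$index,
                              coefficient_waves = spec$coefficients,
                              coefficient_um = spec$coefficients *
                                wavelength_nm * 1e-3),
                   file, row.names = FALSE)
  invisible(file)
}
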