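#' Optical surface constructor
#'
#' A single optical interface in a sequential system. Conic/aspheric
#' refracting surfaces carry geometry (radius, conic constant, polynomial
#' asphericity terms) and the medium that follows them; coordinate breaks
#' carry only a lateral shift of the local frame; the stop and image
#' surfaces are flat (stop) or conic (image) bookkeeping surfaces.
#'
#' Sign convention: the axial coordinate increases from cornea to retina;
#' a radius is positive when the centre of curvature lies toward the
#' retina. All lengths are millimetres.
#'
#' @param kind one of `"conic_asphere"`, `"coordinate_break"`, `"stop"`,
#'   `"image"`.
#' @param radius signed radius of curvature in mm (`Inf` = flat).
#' @param conic_k conic constant (0 sphere, -1 paraboloid, ...).
#' @param a2,a4 even-asphere polynomial sag coefficients (mm^-1, mm^-3):
#'   sag(r) = conic sag + a2 r^2 + a4 r^4.
#' @param semi_diameter clear semi-diameter in mm; rays beyond it are
#'   vignetted.
#' @param thickness_after vertex-to-vertex distance to the next surface, mm.
#' @param n_after refractive index of the medium following the surface.
#' @param decenter_y lateral (+y) shift applied to the local frame
#'   (`coordinate_break` only); a break with `decenter_y = +d` followed by
#'   one with `-d` decentres the surfaces in between by `d`.
#' @param label free-text tag used in printing and serialization.
#' @return an object of class `its_surface` (a named list).
#' @export
surface <- function(kind = "conic_asphere", radius = Inf, conic_k = 0,
                    a2 = 0, a4 = 0, semi_diameter = 6,
                    thickness_after = 0, n_after = 1,
                    decenter_y = 0, label = "") {
  kind <- match.arg(kind, c("conic_asphere", "coordinate_break", "stop", "image"))
  if (kind != "image" && thickness_after < 0)
    stop("thickness_after must be >= 0 for non-image surfaces")
  if (n_after < 1) stop("refractive index must be >= 1")
  s <- list(kind = kind, radius = radius, conic_k = conic_k,
            a2 = a2, a4 = a4, semi_diameter = semi_diameter,
            thickness_after = thickness_after, n_after = n_after,
            decenter_y = decenter_y, label = label)
  class(s) <- "its_surface"
  s
}

#' Surface sag
#'
#' Axial height z(r) of a conic/aspheric surface relative to its vertex:
#' `z = c r^2 / (1 + sqrt(1 - (1+k) c^2 r^2)) + a2 r^2 + a4 r^4`
#' with curvature `c = 1/radius`. Returns `NaN` where the conic sag is
#' undefined (`(1+k) c^2 r^2 > 1`).
#'
#' @param s an `its_surface`.
#' @param r radial coordinate(s), mm.
#' @return sag in mm (vectorized).
#' @export
surface_sag <- function(s, r) {
  r2 <- r * r
  if (is.finite(s$radius)) {
    cv <- 1 / s$radius
    arg <- 1 - (1 + s$conic_k) * cv^2 * r2
    z <- ifelse(arg >= 0, cv * r2 / (1 + sqrt(pmax(arg, 0))), NaN)
  } else {
    z <- rep(0, length(r))
  }
  z + s$a2 * r2 + s$a4 * r2 * r2
}

# radial derivative dz/dr of the sag (used for surface normals)
surface_sag_deriv <- function(s, r) {
  d <- 2 * s$a2 * r + 4 * s$a4 * r^3
  if (is.finite(s$radius)) {
    cv <- 1 / s$radius
    arg <- 1 - (1 + s$conic_k) * cv^2 * r * r
    d <- d + ifelse(arg > 0, cv * r / sqrt(pmax(arg, 1e-300)), NaN)
  }
  d
}

#' Sequential optical system constructor
#'
#' An ordered list of surfaces from the anterior cornea (vertex at z = 0)
#' to the image surface, with exactly one aperture stop. The medium before
#' the first surface is object space (index `n_object`, air by default).
#'
#' @param surfaces list of [surface()] objects; the last must have
#'   `kind = "image"`.
#' @param stop_index position of the aperture stop in `surfaces`.
#' @param object_distance object distance in metres from the first vertex
#'   (`Inf` = collimated object at infinity).
#' @param wavelength_nm design wavelength in nanometres.
#' @param n_object refractive index of object space.
#' @return object of class `optical_system`.
#' @export
optical_system <- function(surfaces, stop_index, object_distance = Inf,
                           wavelength_nm = 587.6, n_object = 1) {
  stopifnot(length(surfaces) >= 2)
  kinds <- vapply(surfaces, function(s) s$kind, character(1))
  if (sum(kinds == "stop") != 1)
    stop("system must contain exactly one stop surface")
  if (which(kinds == "stop") != stop_index)
    stop("stop_index does not point at the stop surface")
  if (kinds[length(kinds)] != "image")
    stop("last surface must be the image surface")
  sys <- list(surfaces = surfaces, stop_index = stop_index,
              object_distance = object_distance,
              wavelength_nm = wavelength_nm, n_object = n_object)
  class(sys) <- "optical_system"
  sys
}

#' Axial vertex positions of all surfaces
#'
#' Cumulative z coordinate of each surface vertex, anterior cornea at 0.
#'
#' @param sys an `optical_system`.
#' @return numeric vector of vertex z positions, mm.
#' @export
vertex_positions <- function(sys) {
  t_after <- vapply(sys$surfaces, function(s) s$thickness_after, numeric(1))
  c(0, cumsum(t_after[-length(t_after)]))
}

# refractive index of the medium *before* each surface
media_before <- function(sys) {
  n_after <- vapply(sys$surfaces, function(s) s$n_after, numeric(1))
  c(sys$n_object, n_after[-length(n_after)])
}

#' @export
print.optical_system <- function(x, ...) {
  z <- vertex_positions(x)
  nb <- media_before(x)
  cat(sprintf("optical_system: %d surfaces, stop at #%d, object %s m, %.1f nm\n",
              length(x$surfaces), x$stop_index,
              ifelse(is.finite(x$object_distance),
                     format(x$object_distance), "Inf"),
              x$wavelength_nm))
  for (i in seq_along(x$surfaces)) {
    s <- x$surfaces[[i]]
    cat(sprintf(" %2d %-16s z=%8.4f R=%9.4f k=%7.3f n'=%5.3f (n=%5.3f) dy=%5.2f %s\n",
                i, s$kind, z[i], s$radius, s$conic_k, s$n_after, nb[i],
                s$decenter_y, s$label))
  }
  invisible(x)
}
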