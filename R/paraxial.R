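#' Paraxial ray-transfer oracle
#'
#' Composes per-surface refraction and transfer in the paraxial (small
#' angle) limit, marching a ray (height y, real angle u) through every
#' refracting surface. A decentred element contributes the paraxial prism
#' term: refraction acts about the shifted local axis, so
#' `n' u' = n u - (y - dy) P`. This provides an independent closed-form
#' check on the exact tracer.
#'
#' @param sys an [optical_system()].
#' @param y0,u0 initial ray height (mm) and angle (radians) at the first
#'   surface vertex plane.
#' @return list with the output `y`, `u` at the last refracting surface
#'   vertex, its axial position `z`, and the index `n` there.
#' @export
paraxial_trace <- function(sys, y0, u0) {
  z <- vertex_positions(sys)
  nb <- media_before(sys)
  y <- y0; u <- u0
  zc <- z[1]
  y_off <- 0
  ncur <- nb[1]
  nsurf <- length(sys$surfaces)
  for (j in seq_len(nsurf - 1)) {
    s <- sys$surfaces[[j]]
    y <- y + u * (z[j] - zc)
    zc <- z[j]
    if (s$kind == "coordinate_break") {
      y_off <- y_off + s$decenter_y
      next
    }
    if (s$kind == "conic_asphere") {
      pw_mm <- surface_power_from_radius(s$radius, nb[j], s$n_after) / 1000 +
        2 * s$a2 * (s$n_after - nb[j])
      u <- (nb[j] * u - (y - y_off) * pw_mm) / s$n_after
      ncur <- s$n_after
    }
  }
  list(y = y, u = u, z = zc, n = ncur)
}

#' Paraxial image location, height and magnification
#'
#' Closed-form oracle for the exact tracer: finds the paraxial image of
#' the system's object (on-axis point or collimated beam), the image
#' height produced by any element decentration (the prism effect), and
#' the retinal image scale (mm of image height per radian of object-space
#' field angle, evaluated through the stop centre).
#'
#' @param sys an [optical_system()].
#' @return list with `image_z` (axial crossing of the marginal ray, mm;
#'   `Inf` and `afocal = TRUE` if the output beam is collimated),
#'   `image_height` (axis-ray height at the image surface vertex, mm —
#'   nonzero only for decentred systems), and `scale_mm_per_rad`.
#' @export
paraxial_oracle <- function(sys) {
  z <- vertex_positions(sys)
  z_img <- z[length(z)]
  h <- 0.01
  if (!is.finite(sys$object_distance)) {
    marg <- paraxial_trace(sys, h, 0)
  } else {
    zo <- -1000 * sys$object_distance
    u0 <- 1e-3                       # ray leaving the axial object point
    marg <- paraxial_trace(sys, -u0 * zo, u0)
    h <- -u0 * zo
  }
  afocal <- abs(marg$u) < 1e-9 * abs(h)
  image_z <- if (afocal) Inf else marg$z - marg$y / marg$u
  ax <- paraxial_trace(sys, 0, 0)
  image_height <- ax$y + ax$u * (z_img - ax$z)
  # chief ray at small field angle through the stop centre
  th <- 1e-3
  sc <- tryCatch({
    ch <- paraxial_chief(sys, th)
    ch_y_img <- ch$y + ch$u * (z_img - ch$z)
    (ch_y_img - image_height) / th
  }, error = function(e) NA_real_)
  list(image_z = image_z, image_height = image_height, afocal = afocal,
       scale_mm_per_rad = sc)
}

# paraxial chief ray: entering at field angle th (radians) and crossing
# the stop centre; found linearly from two trial rays
paraxial_chief <- function(sys, th) {
  z <- vertex_positions(sys)
  j0 <- sys$stop_index
  stop_y <- function(y0) {
    # height at the stop of a ray entering at (y0, th)
    yy <- y0; uu <- th; zc <- z[1]; y_off <- 0
    nb <- media_before(sys)
    for (j in seq_len(j0)) {
      s <- sys$surfaces[[j]]
      yy <- yy + uu * (z[j] - zc); zc <- z[j]
      if (s$kind == "coordinate_break") { y_off <- y_off + s$decenter_y; next }
      if (s$kind == "conic_asphere") {
        pw <- surface_power_from_radius(s$radius, nb[j], s$n_after) / 1000 +
          2 * s$a2 * (s$n_after - nb[j])
        uu <- (nb[j] * uu - (yy - y_off) * pw) / s$n_after
      }
    }
    yy
  }
  s0 <- stop_y(0); s1 <- stop_y(1)
  y0 <- -s0 / (s1 - s0)
  paraxial_trace(sys, y0, th)
}

#' Paraxial equivalent power of a lens (dioptres)
#'
#' Traces a paraxial ray through the two surfaces of a designed thick
#' lens in its immersion medium and returns the equivalent power, an
#' independent check that a lens built from the effective-power formula
#' reproduces its design power.
#'
#' @param ld a [lens_design()].
#' @return equivalent power in dioptres.
#' @export
paraxial_lens_power <- function(ld) {
  n0 <- ld$n_medium
  t_mm <- 1000 * ld$t_m
  p1 <- surface_power_from_radius(ld$R_anterior, n0, ld$n) / 1000
  p2 <- surface_power_from_radius(ld$R_posterior, ld$n, n0) / 1000
  y <- 1; u <- 0
  u <- (n0 * u - y * p1) / ld$n
  y <- y + u * t_mm
  u <- (ld$n * u - y * p2) / n0
  -1000 * n0 * u
}

#' Paraxial back focal distance of a system from infinity
#'
#' Distance from the last refracting surface vertex to the marginal-ray
#' axial crossing, for a collimated on-axis input.
#'
#' @param sys an [optical_system()].
#' @return back focal distance, mm (`Inf` if afocal).
#' @export
back_focal_distance <- function(sys) {
  sys$object_distance <- Inf
  m <- paraxial_trace(sys, 0.01, 0)
  if (abs(m$u) < 1e-12) return(Inf)
  -m$y / m$u
}
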