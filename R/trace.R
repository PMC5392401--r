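#' Vector refraction (Snell's law)
#'
#' Refracts unit direction vectors at a surface with unit normals `N`
#' (oriented with positive z component, i.e. along the propagation
#' direction), from index `n1` into `n2`. Rays undergoing total internal
#' reflection are returned as `NA` rows.
#'
#' @param D n x 3 matrix of unit directions (or a length-3 vector).
#' @param N n x 3 matrix of unit normals (or a length-3 vector).
#' @param n1,n2 refractive indices before/after.
#' @return n x 3 matrix of refracted unit directions (`NA` rows = TIR).
#' @export
refract <- function(D, N, n1, n2) {
  if (is.null(dim(D))) D <- matrix(D, ncol = 3)
  if (is.null(dim(N))) N <- matrix(N, ncol = 3)
  if (n1 == n2) return(D)
  eta <- n1 / n2
  cosi <- rowSums(D * N)
  sin2t <- eta^2 * (1 - cosi^2)
  cost <- sqrt(pmax(1 - sin2t, 0)) # TIR rows overwritten below
  g <- cost - eta * cosi
  T <- eta * D + cbind(g * N[, 1], g * N[, 2], g * N[, 3])
  T[sin2t > 1, ] <- NA_real_
  T
}

# Intersect rays (local frame, vertex at origin) with a conic/aspheric
# surface. P: n x 3 points, D: n x 3 unit directions. Returns the
# propagation length t, intersection points, and unit normals.
intersect_conic_asphere_rays <- function(s, P, D) {
  n <- nrow(P)
  # step 1: propagate to the vertex tangent plane
  t0 <- -P[, 3] / D[, 3]
  x <- P[, 1] + t0 * D[, 1]
  y <- P[, 2] + t0 * D[, 2]
  z <- rep(0, n)
  dx <- D[, 1]; dy <- D[, 2]; dz <- D[, 3]
  # step 2: closed-form intersection with the conic part
  if (is.finite(s$radius)) {
    cv <- 1 / s$radius
    k1 <- 1 + s$conic_k
    A <- cv * (dx^2 + dy^2) + k1 * cv * dz^2
    B <- 2 * (cv * (x * dx + y * dy) - dz)
    C <- cv * (x^2 + y^2)
    disc <- B^2 - 4 * A * C
    bad <- disc < 0
    sq <- sqrt(pmax(disc, 0))
    q <- -0.5 * (B + sign(B + (B == 0)) * sq)
    t1 <- ifelse(abs(A) > 1e-300, q / A, Inf)
    t2 <- ifelse(abs(q) > 1e-300, C / q, 0)
    tc <- ifelse(abs(t1) < abs(t2), t1, t2)
    tc[bad] <- NA_real_
  } else {
    tc <- rep(0, n)
  }
  # step 3: Newton polish on the full sag (handles a2/a4 terms)
  tt <- tc
  if (s$a2 != 0 || s$a4 != 0 || is.finite(s$radius)) {
    for (it in 1:20) {
      xi <- x + tt * dx; yi <- y + tt * dy; zi <- z + tt * dz
      r <- sqrt(xi^2 + yi^2)
      g <- zi - surface_sag(s, r)
      dgdt <- dz - surface_sag_deriv(s, r) *
        ifelse(r > 1e-12, (xi * dx + yi * dy) / r, 0)
      step <- g / dgdt
      tt <- tt - step
      if (all(is.na(step) | abs(step) < 1e-12)) break
    }
  }
  xi <- x + tt * dx; yi <- y + tt * dy; zi <- z + tt * dz
  r <- sqrt(xi^2 + yi^2)
  # residual check / validity
  res <- abs(zi - surface_sag(s, r))
  ok <- is.finite(tt) & is.finite(res) & res < 1e-8 & r <= s$semi_diameter + 1e-9
  d1 <- surface_sag_deriv(s, r)
  rr <- ifelse(r > 1e-12, r, 1)
  N <- cbind(-d1 * xi / rr, -d1 * yi / rr, rep(1, n))
  N[r <= 1e-12, 1:2] <- 0
  nrm <- sqrt(rowSums(N^2))
  N <- N / nrm
  list(t = t0 + tt, P = cbind(xi, yi, zi), N = N, ok = ok)
}

#' Intersect a single ray with a conic/aspheric surface
#'
#' Exact closed-form conic intersection followed by damped Newton
#' iteration for the polynomial asphericity terms, in the surface's local
#' frame (vertex at the origin).
#'
#' @param origin length-3 ray origin, mm (local frame).
#' @param direction length-3 unit direction.
#' @param s an [surface()] of kind `conic_asphere` (or `image`).
#' @return list with `point` (length-3), `normal` (unit, +z oriented), and
#'   `hit` (`FALSE` if no real intersection inside the semi-diameter).
#' @export
intersect_conic_asphere <- function(origin, direction, s) {
  r <- intersect_conic_asphere_rays(s, matrix(origin, ncol = 3),
                                    matrix(direction, ncol = 3))
  list(point = as.numeric(r$P[1, ]), normal = as.numeric(r$N[1, ]),
       hit = isTRUE(r$ok[1]))
}

#' Apply a coordinate break to a ray
#'
#' Shifts the lateral origin of the local frame by `decenter_y` along +y
#' (entering the decentred frame) or back (restoring). A break/restore
#' pair with equal and opposite shifts is an exact identity on the ray.
#'
#' @param origin length-3 ray origin.
#' @param decenter_y lateral frame shift, mm.
#' @return the ray origin expressed in the shifted frame.
#' @export
apply_coordinate_break <- function(origin, decenter_y) {
  origin - c(0, decenter_y, 0)
}

#' Trace a bundle of rays through a sequential system
#'
#' Marches rays surface by surface: coordinate breaks shift the local
#' frame, the stop clips to its semi-diameter, refracting surfaces apply
#' the exact conic/asphere intersection and vector Snell refraction, and
#' the image surface terminates the trace. Optical path length
#' (sum of n times geometric length) is accumulated per ray.
#'
#' @param sys an [optical_system()].
#' @param P n x 3 matrix of ray origins (global frame, upstream of the
#'   first surface).
#' @param D n x 3 matrix of unit directions.
#' @param last_surface index of the last surface to trace (default: all).
#' @return list with `P` (positions on the last traced surface, global
#'   frame), `D`, `opl` (mm), `alive`, `stop_xy` (n x 2 intersection with
#'   the stop plane, if traced), and `pre_image` (ray state after the last
#'   refracting surface, for reference-sphere OPD evaluation).
#' @export
trace_rays <- function(sys, P, D, last_surface = length(sys$surfaces)) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  if (is.null(dim(D))) D <- matrix(D, ncol = 3)
  n <- nrow(P)
  z <- vertex_positions(sys)
  nb <- media_before(sys)
  opl <- rep(0, n)
  alive <- rep(TRUE, n)
  stop_xy <- NULL
  pre_image <- NULL
  y_off <- 0
  nsurf <- length(sys$surfaces)
  for (j in seq_len(last_surface)) {
    s <- sys$surfaces[[j]]
    if (s$kind == "coordinate_break") {
      y_off <- y_off + s$decenter_y
      next
    }
    off <- c(0, y_off, z[j])
    Pl <- cbind(P[, 1] - off[1], P[, 2] - off[2], P[, 3] - off[3])
    if (s$kind == "stop") {
      t <- -Pl[, 3] / D[, 3]
      Pi <- Pl + t * D
      rr <- sqrt(Pi[, 1]^2 + Pi[, 2]^2)
      # clip tolerance exceeds the pupil aiming residual so that rays
      # aimed exactly at the stop rim survive
      alive <- alive & is.finite(rr) & rr <= s$semi_diameter + 1e-5
      opl <- opl + nb[j] * t
      stop_xy <- Pi[, 1:2, drop = FALSE]
      P <- cbind(Pi[, 1] + off[1], Pi[, 2] + off[2], Pi[, 3] + off[3])
      if (j == nsurf - 1) pre_image <- list(P = P, D = D, opl = opl, n = s$n_after)
      next
    }
    hit <- intersect_conic_asphere_rays(s, Pl, D)
    alive <- alive & hit$ok
    opl <- opl + nb[j] * hit$t
    P <- cbind(hit$P[, 1] + off[1], hit$P[, 2] + off[2], hit$P[, 3] + off[3])
    if (s$kind == "conic_asphere" && nb[j] != s$n_after) {
      D <- refract(D, hit$N, nb[j], s$n_after)
      alive <- alive & is.finite(D[, 3])
    }
    if (j == nsurf - 1) pre_image <- list(P = P, D = D, opl = opl, n = s$n_after)
  }
  list(P = P, D = D, opl = opl, alive = alive, stop_xy = stop_xy,
       pre_image = pre_image)
}

# -- ray generation & aiming --------------------------------------------------

# Starting rays parameterized by their crossing (ax, ay) of the z = 0
# plane, for an object at infinity (field angle in degrees, y meridian)
# or a finite on-axis/off-axis object point.
make_start_rays <- function(sys, ax, ay, field_angle_deg = 0) {
  n <- length(ax)
  if (!is.finite(sys$object_distance)) {
    th <- field_angle_deg * pi / 180
    D <- cbind(rep(0, n), rep(sin(th), n), rep(cos(th), n))
    P <- cbind(ax, ay, rep(0, n)) - 5 * D
  } else {
    zo <- -1000 * sys$object_distance
    h <- -zo * tan(field_angle_deg * pi / 180)
    P <- cbind(rep(0, n), rep(h, n), rep(zo, n))
    V <- cbind(ax - P[, 1], ay - P[, 2], -zo)
    D <- V / sqrt(rowSums(V^2))
  }
  list(P = P, D = D)
}

#' Aim rays at target points on the stop
#'
#' Iteratively adjusts ray starting coordinates so each traced ray crosses
#' the stop surface at its target point, to an aiming residual below
#' `tol` (default 1e-6 mm). The aperture stop, not the lenses, defines the
#' pupil, so aiming holds under lens decentration.
#'
#' @param sys an [optical_system()].
#' @param targets n x 2 matrix of (x, y) stop-plane targets, mm.
#' @param field_angle_deg field angle of the bundle (y meridian), degrees.
#' @param tol aiming residual tolerance, mm.
#' @param max_iter iteration cap; non-convergence is an error naming the
#'   worst ray.
#' @param guess optional n x 2 matrix of starting-coordinate guesses.
#' @return list with `P`, `D` (aimed start rays) and `a` (n x 2 start
#'   coordinates on the z = 0 plane).
#' @export
aim_rays <- function(sys, targets, field_angle_deg = 0, tol = 1e-6,
                     max_iter = 50, guess = NULL) {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 2)
  n <- nrow(targets)
  stop_at <- sys$stop_index
  trace_to_stop <- function(ax, ay) {
    r <- make_start_rays(sys, ax, ay, field_angle_deg)
    tr <- trace_rays(sys, r$P, r$D, last_surface = stop_at)
    tr$stop_xy
  }
  # estimate the (shared, near-linear) start->stop Jacobian from probes
  e <- 0.05
  s0 <- trace_to_stop(0, 0)
  sx <- trace_to_stop(e, 0)
  sy <- trace_to_stop(0, e)
  J <- cbind((sx[1, ] - s0[1, ]) / e, (sy[1, ] - s0[1, ]) / e)
  if (!all(is.finite(J)) || abs(det(J)) < 1e-12)
    stop("pupil ray aiming: singular start->stop Jacobian")
  Jinv <- solve(J)
  a <- guess
  if (is.null(a)) {
    d0 <- targets - matrix(s0, n, 2, byrow = TRUE)
    a <- t(Jinv %*% t(d0))
  }
  for (it in seq_len(max_iter)) {
    s <- trace_to_stop(a[, 1], a[, 2])
    err <- targets - s
    bad <- !is.finite(err[, 1]) | !is.finite(err[, 2])
    err[bad, ] <- 0
    if (max(abs(err)) < tol && !any(bad)) {
      r <- make_start_rays(sys, a[, 1], a[, 2], field_angle_deg)
      return(list(P = r$P, D = r$D, a = a))
    }
    if (any(bad) && it > max_iter / 2)
      stop("ray aiming failed (dead ray) for stop target (",
           targets[which(bad)[1], 1], ", ", targets[which(bad)[1], 2], ")")
    a <- a + t(Jinv %*% t(err))
  }
  stop("ray aiming did not converge for stop target (",
       targets[which.max(abs(rowSums(err^2))), 1], ", ",
       targets[which.max(abs(rowSums(err^2))), 2], ")")
}

#' Sample the stop with an aimed uniform ray grid
#'
#' Lays an `n_grid` x `n_grid` square grid over the stop disc, keeps the
#' inscribed-disc points, and aims one ray at each so the traced bundle
#' fills the 3 mm pupil uniformly.
#'
#' @param sys an [optical_system()].
#' @param n_grid grid points per side.
#' @param field_angle_deg field angle of the bundle, degrees.
#' @param guess optional aiming warm start (from a previous call on a
#'   similar system).
#' @return list with aimed rays (`P`, `D`, `a`), normalized pupil
#'   coordinates `u`, `v`, grid indices `iu`, `iv`, and the stop radius.
#' @export
aim_and_sample_pupil <- function(sys, n_grid = 64, field_angle_deg = 0,
                                 guess = NULL) {
  rp <- sys$surfaces[[sys$stop_index]]$semi_diameter
  g <- seq(-1, 1, length.out = n_grid)
  gg <- expand.grid(iu = seq_len(n_grid), iv = seq_len(n_grid))
  u <- g[gg$iu]; v <- g[gg$iv]
  keep <- u^2 + v^2 <= 1 + 1e-12
  u <- u[keep]; v <- v[keep]
  targets <- cbind(u, v) * rp
  aimed <- aim_rays(sys, targets, field_angle_deg, guess = guess)
  list(P = aimed$P, D = aimed$D, a = aimed$a, u = u, v = v,
       iu = gg$iu[keep], iv = gg$iv[keep], n_grid = n_grid,
       pupil_radius_mm = rp)
}

# -- paraxial helpers needed for the reference sphere -------------------------

# axial position of the exit pupil: paraxial image of the stop through the
# surfaces that follow it
exit_pupil_z <- function(sys) {
  z <- vertex_positions(sys)
  nb <- media_before(sys)
  j0 <- sys$stop_index
  y <- 0; u <- 0.01
  zc <- z[j0]
  nsurf <- length(sys$surfaces)
  ncur <- sys$surfaces[[j0]]$n_after
  if (j0 + 1 <= nsurf - 1) {
    for (j in (j0 + 1):(nsurf - 1)) {
      s <- sys$surfaces[[j]]
      y <- y + u * (z[j] - zc)
      zc <- z[j]
      if (s$kind == "conic_asphere") {
        pw <- surface_power_from_radius(s$radius, nb[j], s$n_after) / 1000 +
          2 * s$a2 * (s$n_after - nb[j])
        u <- (nb[j] * u - y * pw) / s$n_after
        ncur <- s$n_after
      }
    }
  }
  if (abs(u) < 1e-12) return(Inf)
  zc - y / u
}

# -- wavefront ----------------------------------------------------------------

#' Compute the OPD wavefront map over the pupil
#'
#' Traces an aimed uniform pupil grid plus the chief ray through the full
#' system, terminates every ray on the reference sphere centred at the
#' chief ray's retinal intersection and passing through the exit-pupil
#' centre, and reports the optical path difference (chief minus ray) in
#' waves at the design wavelength. Retinal spot data (per-ray retinal
#' intersections, centroid, chief-ray height) ride along for downstream
#' image-displacement measures.
#'
#' @param sys an [optical_system()].
#' @param n_grid pupil grid points per side (default 64).
#' @param max_dead_frac tolerated fraction of vignetted rays before the
#'   map is declared invalid.
#' @param guess optional aiming warm start.
#' @return object of class `wavefront_map`: normalized pupil coordinates
#'   `u`, `v`, grid indices, `opd` (waves), `mask`, spot metadata.
#' @export
compute_wavefront <- function(sys, n_grid = 64, max_dead_frac = 0.05,
                              guess = NULL) {
  sm <- aim_and_sample_pupil(sys, n_grid, guess = guess)
  chief <- aim_rays(sys, c(0, 0))
  P <- rbind(sm$P, chief$P)
  D <- rbind(sm$D, chief$D)
  tr <- trace_rays(sys, P, D)
  n <- length(sm$u)
  ic <- n + 1
  if (!tr$alive[ic]) stop("chief ray vignetted")
  dead_frac <- mean(!tr$alive[seq_len(n)])
  if (dead_frac > max_dead_frac)
    stop(sprintf("%.1f%% of pupil rays vignetted; wavefront map invalid",
                 100 * dead_frac))
  C <- tr$P[ic, ]                       # chief-ray retinal intersection
  zxp <- exit_pupil_z(sys)
  pre <- tr$pre_image
  n_img <- pre$n
  if (is.finite(zxp)) {
    E <- c(0, 0, zxp)
    R <- sqrt(sum((C - E)^2))
    PC <- cbind(pre$P[, 1] - C[1], pre$P[, 2] - C[2], pre$P[, 3] - C[3])
    b <- rowSums(pre$D * PC)
    cc <- rowSums(PC^2) - R^2
    disc <- b^2 - cc
    tref <- -b - sqrt(pmax(disc, 0))
    tref[disc < 0] <- NA_real_
  } else {
    # afocal exit pupil: reference plane through the last vertex, normal
    # along the chief ray
    dchief <- pre$D[ic, ]
    tref <- -(cbind(pre$P[, 1] - C[1], pre$P[, 2] - C[2],
                    pre$P[, 3] - C[3]) %*% dchief)[, 1]
  }
  opl_ref <- pre$opl + n_img * tref
  opd_waves <- (opl_ref[ic] - opl_ref[seq_len(n)]) /
    (sys$wavelength_nm * 1e-6)
  mask <- tr$alive[seq_len(n)] & is.finite(opd_waves)
  opd_waves[!mask] <- NA_real_
  pts <- tr$P[seq_len(n), , drop = FALSE]
  cen <- colMeans(pts[mask, 1:2, drop = FALSE])
  wf <- list(n_grid = n_grid, u = sm$u, v = sm$v, iu = sm$iu, iv = sm$iv,
             opd = opd_waves, mask = mask,
             pupil_radius_mm = sm$pupil_radius_mm,
             wavelength_nm = sys$wavelength_nm,
             spot_points = pts, spot_centroid = cen,
             chief_point = C, dead_frac = dead_frac, aim_a = sm$a)
  class(wf) <- "wavefront_map"
  wf
}

#' @export
print.wavefront_map <- function(x, ...) {
  cat(sprintf("wavefront_map: %d samples (%d x %d grid), RMS %.5f waves @ %.1f nm\n",
              sum(x$mask), x$n_grid, x$n_grid,
              rms_wavefront(x), x$wavelength_nm))
  invisible(x)
}

#' Retinal spot diagram
#'
#' Traces an aimed pupil grid to the retina and reports the ray
#' intersection points, their centroid, RMS spot radius about the
#' centroid, and the chief-ray height.
#'
#' @param sys an [optical_system()].
#' @param n_grid pupil grid points per side.
#' @return list of class `spot_diagram`.
#' @export
spot_diagram <- function(sys, n_grid = 16) {
  sm <- aim_and_sample_pupil(sys, n_grid)
  chief <- aim_rays(sys, c(0, 0))
  tr <- trace_rays(sys, rbind(sm$P, chief$P), rbind(sm$D, chief$D))
  n <- length(sm$u)
  alive <- tr$alive[seq_len(n)]
  pts <- tr$P[seq_len(n), , drop = FALSE][alive, , drop = FALSE]
  cen <- colMeans(pts[, 1:2, drop = FALSE])
  rr <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
  out <- list(points = pts, centroid = cen,
              rms_radius = sqrt(mean(rr^2)),
              chief_height = tr$P[n + 1, 2], n_alive = sum(alive))
  class(out) <- "spot_diagram"
  out
}

# zero out all coordinate-break decentrations (centred twin of a system)
zero_decenter <- function(sys) {
  sys$surfaces <- lapply(sys$surfaces, function(s) {
    if (s$kind == "coordinate_break") s$decenter_y <- 0
    s
  })
  sys
}

# retinal height (y, mm) of the chief ray at a given field angle
chief_ray_height <- function(sys, field_angle_deg) {
  chief <- aim_rays(sys, c(0, 0), field_angle_deg = field_angle_deg)
  tr <- trace_rays(sys, chief$P, chief$D)
  tr$P[1, 2]
}

#' Object-space field angle mapping to a retinal height
#'
#' Finds, by bisection, the field angle whose chief ray lands at the
#' given retinal height in the (centred) system — the visual-field
#' eccentricity corresponding to a retinal displacement.
#'
#' @param sys an [optical_system()] (centred).
#' @param height_mm target retinal height (signed y, mm).
#' @param tol_deg angular tolerance, degrees.
#' @param bracket_deg search half-width, degrees.
#' @return field angle in degrees (signed).
#' @export
field_angle_for_height <- function(sys, height_mm, tol_deg = 1e-3,
                                   bracket_deg = 15) {
  if (abs(height_mm) < 1e-12) return(0)
  f <- function(th) chief_ray_height(sys, th) - height_mm
  r <- stats::uniroot(f, c(-bracket_deg, bracket_deg), tol = tol_deg)
  r$root
}

#' Retinal image decentration
#'
#' Lateral displacement of the retinal spot centroid from the axial image
#' point, in mm, together with its visual-field equivalent in degrees: the
#' object-space field angle whose chief ray — in the centred twin of the
#' system — lands at that retinal height. The chief-ray displacement is
#' reported alongside for comparison.
#'
#' @param sys an [optical_system()] (possibly decentred).
#' @param n_grid pupil grid points per side.
#' @param centered_sys optional precomputed centred twin (defaults to the
#'   system with all coordinate-break decentrations zeroed).
#' @return list with `shift_mm` (centroid, signed), `shift_deg`,
#'   `chief_shift_mm`.
#' @export
image_decentration <- function(sys, n_grid = 64, centered_sys = NULL) {
  sp <- spot_diagram(sys, n_grid = n_grid)
  if (is.null(centered_sys)) centered_sys <- zero_decenter(sys)
  sp0 <- spot_diagram(centered_sys, n_grid = n_grid)
  shift <- sp$centroid[2] - sp0$centroid[2]
  deg <- field_angle_for_height(centered_sys, shift)
  list(shift_mm = unname(shift), shift_deg = unname(deg),
       chief_shift_mm = unname(sp$chief_height - sp0$chief_height))
}
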