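#' Single refracting sphere fixture with known paraxial truth
#'
#' One refracting spherical surface in air, with the image plane at the
#' paraxial focal distance `n2 R / (n2 - 1)`. The closed-form truth lets
#' the exact tracer be validated in the small-aperture limit (and its
#' spherical aberration checked qualitatively at full aperture).
#'
#' @param R surface radius, mm.
#' @param n2 index after the surface.
#' @param semi_diameter aperture semi-diameter, mm.
#' @return list with `system` (an [optical_system()]) and `truth`
#'   (`focal_distance_mm`).
#' @export
make_single_sphere <- function(R, n2, semi_diameter = 3) {
  stopifnot(R != 0, n2 > 1)
  f <- n2 * R / (n2 - 1)
  surfaces <- list(
    surface("stop", semi_diameter = semi_diameter, thickness_after = 0,
            n_after = 1, label = "stop"),
    surface("conic_asphere", radius = R, semi_diameter = 2 * semi_diameter,
            thickness_after = f, n_after = n2, label = "sphere"),
    surface("image", radius = Inf, semi_diameter = 2 * semi_diameter,
            n_after = n2, label = "image")
  )
  list(system = optical_system(surfaces, stop_index = 1),
       truth = list(focal_distance_mm = f))
}

#' Seeded random Galilean telescope fixture
#'
#' Draws a Galilean lens pair in the family of the study's implants —
#' positive power in [40, 80] D, negative in [-80, -40] D, facing-vertex
#' separation in [1, 4] mm, both lenses 1 mm thick, index 1.55 — places
#' it behind the pupil of the aphakic eye, and records the paraxial image
#' distance from the ray-transfer oracle as truth. Draws whose paraxial
#' image falls outside the eye (or behind the retina plus 15 mm) are
#' redrawn, up to 100 attempts.
#'
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param config a [simulation_config()].
#' @return list with `prescription`, `system` (far configuration), and
#'   `truth` (`image_z_mm`, `scale_mm_per_rad`, drawn parameters).
#' @export
make_random_telescope <- function(seed, config = simulation_config()) {
  rng <- local({ set.seed(seed); list(p = runif(1, 40, 80),
                                      n = runif(1, -80, -40),
                                      sep = runif(1, 1, 4),
                                      frac = runif(2, 0.45, 0.65)) })
  for (attempt in 1:100) {
    p <- list(name = sprintf("RT%d", seed),
              placement = "behind_pupil",
              positive_lens = lens_design(rng$p, rng$frac[1] * rng$p),
              negative_lens = lens_design(rng$n, rng$frac[2] * rng$n),
              anterior_lens_axial_position = NA_real_,
              separation_far = rng$sep, separation_near = rng$sep + 0.45,
              placement_offset = 0.5)
    class(p) <- "its_prescription"
    sys <- try(assemble_system(p, config, vergence = "far"), silent = TRUE)
    if (!inherits(sys, "try-error")) {
      orc <- paraxial_oracle(sys)
      z_ret <- config$eye$axial_length
      if (!orc$afocal && orc$image_z > 8 && orc$image_z < z_ret + 15) {
        return(list(prescription = p, system = sys,
                    truth = list(image_z_mm = orc$image_z,
                                 scale_mm_per_rad = orc$scale_mm_per_rad,
                                 P_positive = rng$p, P_negative = rng$n,
                                 separation_mm = rng$sep, seed = seed)))
      }
    }
    rng <- list(p = runif(1, 40, 80), n = runif(1, -80, -40),
                sep = runif(1, 1, 4), frac = runif(2, 0.45, 0.65))
  }
  stop("no focusable telescope drawn in 100 attempts for seed ", seed)
}

#' Small-aperture image distance from the exact tracer
#'
#' Traces a marginal ray at tiny aperture through the exact tracer and
#' returns its axial crossing distance — the quantity the paraxial
#' oracle predicts in closed form.
#'
#' @param sys an [optical_system()].
#' @param h marginal ray height at the stop, mm.
#' @return axial crossing z (mm, absolute).
#' @export
exact_image_z <- function(sys, h = 0.01) {
  aimed <- aim_rays(sys, rbind(c(0, h), c(0, -h)))
  tr <- trace_rays(sys, aimed$P, aimed$D,
                   last_surface = length(sys$surfaces) - 1)
  pre <- tr$pre_image
  # crossing of the two symmetric marginal rays
  # y1 + u1 t = y2 + u2 t  ->  t = (y2 - y1)/(u1 - u2); use y,z components
  u1 <- pre$D[1, 2] / pre$D[1, 3]; u2 <- pre$D[2, 2] / pre$D[2, 3]
  b1 <- pre$P[1, 2] - u1 * pre$P[1, 3]
  b2 <- pre$P[2, 2] - u2 * pre$P[2, 3]
  (b2 - b1) / (u1 - u2)
}
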