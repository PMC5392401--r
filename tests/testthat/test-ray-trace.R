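sphere10 <- surface("conic_asphere", radius = 10, semi_diameter = 5,
                    n_after = 1.5)

test_that("conic intersection is exact on spheres", {
  hit <- intersect_conic_asphere(c(0, 0, -5), c(0, 0, 1), sphere10)
  expect_equal(hit$point, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(hit$normal, c(0, 0, 1), tolerance = 1e-12)
  # ray parallel to the axis at height 3: z = 10 - sqrt(100 - 9)
  hit <- intersect_conic_asphere(c(0, 3, -5), c(0, 0, 1), sphere10)
  expect_equal(hit$point[3], 10 - sqrt(91), tolerance = 1e-12)
  expect_equal(hit$point[3], 0.460608, tolerance = 1e-6)
})

test_that("aspheric intersections satisfy the sag equation to 1e-10 mm", {
  set.seed(42)
  for (i in 1:25) {
    s <- surface("conic_asphere", radius = runif(1, 6, 30) * sample(c(-1, 1), 1),
                 conic_k = runif(1, -2, 1), a2 = runif(1, -5e-3, 5e-3),
                 a4 = runif(1, -5e-4, 5e-4), semi_diameter = 3, n_after = 1.5)
    o <- c(runif(1, -2, 2), runif(1, -2, 2), -8)
    d <- c(runif(1, -0.1, 0.1), runif(1, -0.1, 0.1), 1)
    d <- d / sqrt(sum(d^2))
    hit <- intersect_conic_asphere(o, d, s)
    if (!hit$hit) next
    r <- sqrt(hit$point[1]^2 + hit$point[2]^2)
    expect_lt(abs(hit$point[3] - surface_sag(s, r)), 1e-10)
  }
})

test_that("vector Snell refraction reproduces closed-form angles", {
  N <- c(0, 0, 1)
  # normal incidence: unchanged
  expect_equal(as.numeric(refract(c(0, 0, 1), N, 1, 1.7)), c(0, 0, 1))
  # 45 degrees into n = 1.5: refraction angle asin(sin(45)/1.5) = 28.1255
  d45 <- c(0, sin(pi / 4), cos(pi / 4))
  t <- as.numeric(refract(d45, N, 1, 1.5))
  expect_equal(asin(t[2]) * 180 / pi, 28.1255, tolerance = 1e-4)
  expect_equal(sum(t^2), 1, tolerance = 1e-12)
  # matched media: unchanged
  expect_equal(as.numeric(refract(d45, N, 1.336, 1.336)), d45)
  # total internal reflection: dead ray
  d80 <- c(0, sin(80 * pi / 180), cos(80 * pi / 180))
  expect_true(all(is.na(refract(d80, N, 1.5, 1.0))))
})

test_that("zero-decentration coordinate breaks are exact no-ops", {
  mk <- function(with_breaks) {
    surf <- list(
      surface("stop", semi_diameter = 1.5, thickness_after = 2, n_after = 1),
      surface("conic_asphere", radius = 12, semi_diameter = 4,
              thickness_after = 1, n_after = 1.55),
      surface("conic_asphere", radius = -12, semi_diameter = 4,
              thickness_after = 20, n_after = 1),
      surface("image", n_after = 1)
    )
    if (with_breaks)
      surf <- append(append(surf,
        list(surface("coordinate_break", decenter_y = 0, n_after = 1)), 1),
        list(surface("coordinate_break", decenter_y = 0, n_after = 1)), 4)
    optical_system(surf, stop_index = 1)
  }
  set.seed(3)
  P <- cbind(runif(40, -1, 1), runif(40, -1, 1), -5)
  D <- matrix(rep(c(0, 0, 1), each = 40), ncol = 3)
  a <- trace_rays(mk(FALSE), P, D)
  b <- trace_rays(mk(TRUE), P, D)
  expect_equal(a$P, b$P, tolerance = 1e-14)
  expect_equal(a$opl, b$opl, tolerance = 1e-14)
  expect_identical(a$alive, b$alive)   # energy bookkeeping
  # break then immediate restore leaves a point unchanged
  p <- c(0.3, -0.2, 4)
  expect_equal(apply_coordinate_break(apply_coordinate_break(p, 0.7), -0.7),
               p, tolerance = 1e-12)
})

test_that("the chief ray crosses the stop centre, decentred or not", {
  for (dec in c(0, 0.6)) {
    sys <- assemble_system(build_its1(), simulation_config(), "far",
                           decenter_mm = dec)
    aimed <- aim_rays(sys, c(0, 0))
    tr <- trace_rays(sys, aimed$P, aimed$D)
    expect_lt(max(abs(tr$stop_xy)), 1e-6)
    expect_true(tr$alive)
  }
})

test_that("a 32x32 aimed grid fills the pupil disc without losses", {
  sm <- aim_and_sample_pupil(its1_far(), n_grid = 32)
  tr <- trace_rays(its1_far(), sm$P, sm$D)
  # the inscribed disc holds ~pi/4 of the square lattice (exactly 740
  # points at this grid size, boundary cells included); none vignette
  expect_equal(length(sm$u), 740)
  expect_gte(length(sm$u), floor(0.9 * pi / 4 * 32^2))
  expect_equal(sum(tr$alive), length(sm$u))
  # aimed rays land on their stop targets
  expect_lt(max(abs(tr$stop_xy - cbind(sm$u, sm$v) * 1.5)), 1e-6)
})

test_that("the exact tracer agrees with the paraxial oracle at small aperture", {
  cfg <- simulation_config()
  systems <- list(its1_far(),
                  assemble_system(build_its2(), cfg, "far"),
                  assemble_system(build_its1(), cfg, "near"))
  for (sys in systems) {
    truth <- paraxial_oracle(sys)$image_z
    expect_equal(exact_image_z(sys, h = 0.01), truth,
                 tolerance = 1e-3)
  }
})

test_that("decentration produces the paraxially predicted prism displacement", {
  sys <- assemble_system(build_its1(), simulation_config(), "far",
                         decenter_mm = 0.2)
  pred <- paraxial_oracle(sys)$image_height
  id <- image_decentration(sys, n_grid = 32)
  # chief-ray displacement approaches the paraxial prediction
  expect_equal(id$chief_shift_mm, pred, tolerance = 0.05)
  expect_equal(sign(id$shift_mm), sign(pred))
})

test_that("mirror symmetry: reflecting the decentration negates the shift", {
  cfg <- simulation_config()
  up <- assemble_system(build_its1(), cfg, "far", decenter_mm = 0.4)
  dn <- assemble_system(build_its1(), cfg, "far", decenter_mm = -0.4)
  # tracing the y-mirrored bundle through the y-mirrored system is an
  # exact arithmetic reflection
  sm <- aim_and_sample_pupil(up, n_grid = 16)
  a <- trace_rays(up, sm$P, sm$D)
  Pm <- sm$P; Pm[, 2] <- -Pm[, 2]
  Dm <- sm$D; Dm[, 2] <- -Dm[, 2]
  b <- trace_rays(dn, Pm, Dm)
  expect_equal(b$P[, 2], -a$P[, 2], tolerance = 1e-12)
  expect_equal(b$opl, a$opl, tolerance = 1e-12)
  expect_identical(b$alive, a$alive)
  # the full map pipeline (with its own ray aiming) agrees to the
  # aiming tolerance
  wf_up <- compute_wavefront(up, 32)
  wf_dn <- compute_wavefront(dn, 32)
  expect_equal(rms_wavefront(wf_up), rms_wavefront(wf_dn), tolerance = 1e-8)
  expect_equal(wf_up$spot_centroid[2], -wf_dn$spot_centroid[2],
               tolerance = 1e-8)
})

test_that("a displaced image plane yields pure defocus with the analytic coefficient", {
  fx <- make_single_sphere(20, 1.5, semi_diameter = 0.25)
  sys <- fx$system
  dz <- 0.15
  sys$surfaces[[2]]$thickness_after <- fx$truth$focal_distance_mm + dz
  wf <- compute_wavefront(sys, 32)
  spec <- fit_zernike(wf, 4)
  co <- spec$coefficients
  # analytic defocus: W = n dz u^2/2 * rho^2, c20 = A / (2 sqrt(3))
  u_marg <- 0.25 / fx$truth$focal_distance_mm
  A <- 1.5 * dz * u_marg^2 / 2 / (587.6e-6)
  expect_equal(co[5], A / (2 * sqrt(3)), tolerance = 0.02)
  # nothing but piston + defocus (+ tiny spherical) present
  others <- co[-c(1, 5)]
  expect_lt(max(abs(others)), 1e-4)
  # an undisplaced ideal fixture is aberration-free
  wf0 <- compute_wavefront(ideal_fixture()$system, 32)
  expect_lt(max(abs(wf0$opd), na.rm = TRUE), 1e-3)
})
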