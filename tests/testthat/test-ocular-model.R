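test_that("the aphakic eye has only corneal and aqueous media", {
  eye <- build_aphakic_eye(simulation_config())
  n_after <- vapply(eye$surfaces, function(s) s$n_after, numeric(1))
  expect_setequal(round(n_after, 3), c(1.376, 1.336))
  expect_false(any(abs(n_after - 1.55) < 1e-9))
})

test_that("the stop sits at the pupil plane behind the cornea", {
  eye <- build_aphakic_eye(simulation_config())
  z <- vertex_positions(eye)
  expect_equal(z[eye$stop_index], 0.5 + 3.16)
  # consistent with the through-pupil telescope layout:
  # 1.66 mm to the lens + 1 mm thickness + 0.5 mm to the pupil
  expect_equal(z[eye$stop_index], 0.5 + 1.66 + 1.0 + 0.5)
  expect_equal(eye$surfaces[[eye$stop_index]]$semi_diameter, 1.5)
  expect_true(all(diff(z) >= 0))
})

test_that("removing the crystalline lens leaves the eye strongly hyperopic", {
  eye <- build_aphakic_eye(simulation_config())
  bfd <- back_focal_distance(eye)
  expect_true(is.finite(bfd) && bfd > 0)
  z_last_refracting <- vertex_positions(eye)[2]
  # focus falls well behind the retina
  expect_gt(z_last_refracting + bfd, eye_constants()$axial_length)
})

test_that("eye construction is pure and overridable", {
  cfg <- simulation_config()
  expect_identical(build_aphakic_eye(cfg), build_aphakic_eye(cfg))
  flat <- simulation_config(flat_retina = TRUE)
  expect_identical(build_aphakic_eye(flat)$surfaces[[4]]$radius, Inf)
  long <- simulation_config(eye_overrides = list(axial_length = 25))
  z <- vertex_positions(build_aphakic_eye(long))
  expect_equal(z[4], 25)
  expect_error(simulation_config(eye_overrides = list(bogus = 1)),
               "unknown eye constant")
})

test_that("systems serialize to YAML and back without loss", {
  sys <- assemble_system(build_its1(), simulation_config(), "far",
                         decenter_mm = 0.4)
  f <- withr::local_tempfile(fileext = ".yaml")
  system_to_yaml(sys, f)
  back <- system_from_yaml(f)
  expect_equal(back$surfaces, sys$surfaces, tolerance = 1e-12)
  expect_identical(back$stop_index, sys$stop_index)
  expect_identical(back$object_distance, sys$object_distance)
  # infinite object distance round-trips through the .inf representation
  expect_identical(back$object_distance, Inf)
})
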