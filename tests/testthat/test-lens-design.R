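test_that("effective-power formula reproduces the published surface powers", {
  expect_equal(solve_posterior_power(53, 33, 0.001, 1.55), 20.44,
               tolerance = 0.01 / 20.44)
  expect_equal(solve_posterior_power(-64, -34, 0.001, 1.55), -29.36,
               tolerance = 0.01 / 29.36)
  expect_equal(solve_posterior_power(66, 36, 0.001, 1.55), 30.71,
               tolerance = 0.01 / 30.71)
  expect_equal(solve_posterior_power(-66, -36, 0.001, 1.55), -29.32,
               tolerance = 0.01 / 29.32)
})

test_that("zero thickness reduces the thick-lens formula to additivity", {
  expect_equal(solve_posterior_power(47, 12.5, 0, 1.55), 47 - 12.5)
})

test_that("a degenerate denominator is rejected as unphysical", {
  expect_error(solve_posterior_power(10, 1550, 0.001, 1.55), "degenerate")
})

test_that("surface power <-> radius conversion round-trips", {
  expect_equal(radius_from_surface_power(33, 1.336, 1.55), 6.4848,
               tolerance = 1e-4)
  expect_equal(radius_from_surface_power(20.44, 1.55, 1.336), -10.47,
               tolerance = 1e-3)
  expect_identical(radius_from_surface_power(0, 1.336, 1.55), Inf)
  set.seed(7)
  for (P in runif(20, -80, 80)) {
    R <- radius_from_surface_power(P, 1.336, 1.55)
    expect_equal(surface_power_from_radius(R, 1.336, 1.55), P,
                 tolerance = 1e-9)
  }
})

test_that("every designed lens satisfies the formula and its paraxial power", {
  designs <- list(lens_design(53, 33), lens_design(-64, -34),
                  lens_design(66, 36), lens_design(-66, -36))
  set.seed(11)
  for (D in runif(10, -80, 80)) {
    if (abs(D) < 5) next
    designs <- c(designs, list(lens_design(D, 0.55 * D)))
  }
  for (ld in designs) {
    expect_lt(abs(effective_power_residual(ld$D_total, ld$P_anterior,
                                           ld$P_posterior, ld$t_m, ld$n)),
              1e-9)
    expect_equal(paraxial_lens_power(ld), ld$D_total, tolerance = 0.01 / 53)
  }
})

test_that("telescope axial geometry is self-consistent with the design text", {
  cfg <- simulation_config()
  z <- vertex_positions(its1_far())
  labs <- vapply(its1_far()$surfaces, function(s) s$label, character(1))
  i_pos_post <- which(labs == "positive lens posterior")
  i_neg_ant <- which(labs == "negative lens anterior")
  i_stop <- which(labs == "pupil (stop)")
  # facing-vertex gap 3.1 mm (far); two routes to the negative lens vertex:
  # 1.66 + 1.0 + 3.1 and 2.16 + 2.6 mm behind the posterior cornea
  expect_equal(z[i_neg_ant] - z[i_pos_post], 3.1)
  expect_equal(z[i_neg_ant], 0.5 + 1.66 + 1.0 + 3.1)
  expect_equal(z[i_neg_ant] - z[i_stop], 2.6)
  # near configuration: negative lens translated toward the retina
  near <- assemble_system(build_its1(), cfg, "near")
  zn <- vertex_positions(near)
  expect_equal(zn[i_neg_ant] - zn[i_pos_post], 3.65)
  expect_equal(zn[i_pos_post], z[i_pos_post])  # anterior lens fixed
  # behind-pupil telescope: both lenses behind the stop
  s2 <- assemble_system(build_its2(), cfg, "far")
  z2 <- vertex_positions(s2)
  expect_true(all(z2[5:9] >= z2[3]))
  labs2 <- vapply(s2$surfaces, function(s) s$label, character(1))
  expect_equal(z2[which(labs2 == "negative lens anterior")] -
                 z2[which(labs2 == "positive lens posterior")], 1.5)
})

test_that("focus search recovers the design separations and is monotone in vergence", {
  cfg <- simulation_config()
  p1 <- build_its1()
  sep_far <- focus_separation(p1, cfg, Inf)
  sep_near <- focus_separation(p1, cfg, 0.41)
  sep_mid <- focus_separation(p1, cfg, 1.0)
  expect_equal(sep_far, 3.1, tolerance = 0.15 / 3.1)
  expect_equal(sep_near, 3.65, tolerance = 0.15 / 3.65)
  # separation grows as the target approaches
  expect_true(sep_far < sep_mid && sep_mid < sep_near)
  # deterministic search
  expect_identical(sep_far, focus_separation(p1, cfg, Inf))
})
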