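test_that("Zernike injection-recovery is exact for single modes", {
  wf <- make_injected_zernike(c(0, 0, 0, 0, 0.5))   # j = 4: defocus
  spec <- fit_zernike(wf, 6)
  expect_equal(spec$coefficients[5], 0.5, tolerance = 1e-9)
  expect_lt(max(abs(spec$coefficients[-5])), 1e-9)
  expect_lt(spec$residual_rms, 1e-9)
})

test_that("random order-6 spectra round-trip through the fit", {
  set.seed(99)
  for (rep in 1:5) {
    co <- rep(0, 28)
    co[sample(2:28, 10)] <- runif(10, -0.3, 0.3)
    wf <- make_injected_zernike(co)
    rec <- fit_zernike(wf, 6)$coefficients
    expect_equal(rec, co, tolerance = 1e-9)
  }
})

test_that("piston carries no RMS and RMS is linear in the map", {
  wf <- make_injected_zernike(c(0.8))               # piston only
  expect_lt(rms_wavefront(wf, "piston"), 1e-12)
  wf2 <- make_injected_zernike(c(0, 0, 0, 0.2, 0, 0.1))
  r1 <- rms_wavefront(wf2)
  wf2$opd <- 2 * wf2$opd
  expect_equal(rms_wavefront(wf2), 2 * r1, tolerance = 1e-12)
})

test_that("tilt removal separates image displacement from RMS", {
  # pure tilt (j = 2): zero RMS under the piston+tilt convention,
  # nonzero under piston-only
  wf <- make_injected_zernike(c(0, 0, 0.4))
  expect_lt(rms_wavefront(wf, c("piston", "tilt")), 1e-10)
  # unit-RMS normalization holds up to grid discretization
  expect_equal(rms_wavefront(wf, "piston"), 0.4, tolerance = 5e-3)
})

test_that("Parseval: coefficient power equals map variance", {
  wf <- its1_far_map()
  spec <- fit_zernike(wf, 6)
  co <- spec$coefficients
  rms_fit <- sqrt(sum(co[-c(1, 2, 3)]^2))           # no piston, no tilt
  expect_equal(rms_fit, rms_wavefront(wf, c("piston", "tilt")),
               tolerance = 0.02)
})

test_that("RMS is invariant under a y-mirror of the map", {
  set.seed(5)
  co <- rep(0, 28); co[sample(2:28, 8)] <- runif(8, -0.2, 0.2)
  wf <- make_injected_zernike(co)
  mirrored <- wf
  mirrored$v <- -mirrored$v
  expect_equal(rms_wavefront(mirrored), rms_wavefront(wf), tolerance = 1e-12)
})

test_that("degenerate maps are rejected", {
  wf <- make_injected_zernike(c(0, 0, 0, 0.1), n_grid = 8)
  expect_error(fit_zernike(wf, 6), "too few valid samples")
})
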