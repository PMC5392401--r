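test_that("a diffraction-limited pupil has VSOTF 1 under any CSF", {
  wf <- make_injected_zernike(c(0))
  for (params in list(csf_default_params(),
                      list(a = 120, fc = 5, q = 1.4),
                      list(a = 900, fc = 25, q = 0.8))) {
    expect_equal(vsotf_from_map(wf, csf_params = params), 1,
                 tolerance = 1e-3)
  }
})

test_that("the PSF normalizes and piston leaves it unchanged", {
  wf <- make_injected_zernike(c(0, 0, 0, 0, 0.3, 0.1))
  p <- psf(pupil_function(wf))
  expect_equal(sum(p$I), 1, tolerance = 1e-12)
  shifted <- wf
  shifted$opd <- shifted$opd + 0.37
  expect_equal(vsotf_from_map(shifted), vsotf_from_map(wf), tolerance = 1e-9)
})

test_that("OTF is bounded, unit at dc, and samples beyond the cutoff", {
  wf <- make_injected_zernike(c(0, 0, 0, 0, 0.25))
  o <- otf(psf(pupil_function(wf)))
  expect_equal(Mod(o$O[1, 1]), 1)
  expect_lt(max(Mod(o$O)), 1 + 1e-9)
  # incoherent cutoff of a 3 mm pupil at 587.6 nm: ~89.1 cyc/deg
  cutoff <- (0.003 / 587.6e-9) * (pi / 180)
  expect_equal(cutoff, 89.11, tolerance = 1e-3)
  expect_gt(o$max_sampled_cpd, cutoff)
  beyond <- o$fr > cutoff * 1.05
  expect_lt(max(Mod(o$O[beyond])), 1e-3)
  # defocus-only pupil: even PSF, real OTF
  expect_lt(max(abs(Im(o$O))) / max(Mod(o$O)), 1e-7)
})

test_that("the diffraction-limited MTF matches the analytic autocorrelation", {
  wf <- make_injected_zernike(c(0), n_grid = 256)
  o <- otf(psf(pupil_function(wf, pad_factor = 4)))
  cutoff <- (0.003 / 587.6e-9) * (pi / 180)
  chat <- function(s) ifelse(s >= 1, 0, 2 / pi * (acos(s) - s * sqrt(1 - s^2)))
  idx <- which(o$fx >= 0 & o$fx <= 0.95 * cutoff)
  mtf_num <- Re(o$O[idx, 1])
  mtf_ana <- chat(o$fx[idx] / cutoff)
  expect_lt(max(abs(mtf_num - mtf_ana)), 5e-3)
})

test_that("Strehl for one wave of defocus matches direct quadrature", {
  wf <- make_injected_zernike(c(0, 0, 0, 0, 1), n_grid = 128)
  s_fft <- strehl_from_map(wf, pad_factor = 4)
  # brute-force diffraction integral over the unit disc
  nr <- 400
  rho <- (seq_len(nr) - 0.5) / nr
  w <- sqrt(3) * (2 * rho^2 - 1)          # defocus, coefficient 1 wave
  # angular integral is trivial for a radial phase
  integ <- sum(exp(2i * pi * w) * rho) / sum(rho)
  s_ana <- Mod(integ)^2
  expect_equal(s_fft, s_ana, tolerance = 0.01)
})

test_that("VSOTF decreases monotonically with defocus magnitude", {
  vs <- vapply(seq(0, 0.5, by = 0.1), function(c20)
    vsotf_from_map(make_injected_zernike(c(0, 0, 0, 0, c20))), numeric(1))
  expect_true(all(diff(vs) < 0))
})

test_that("a dc-only OTF leaves a small positive VSOTF", {
  wf <- make_injected_zernike(c(0))
  o_dl <- otf(psf(pupil_function(wf)))
  o_dc <- o_dl
  o_dc$O[] <- 0
  o_dc$O[1, 1] <- 1
  v <- vsotf(o_dc, o_dl)
  expect_gt(v, 0)
  expect_lt(v, 0.05)
})

test_that("grid refinement leaves VSOTF stable", {
  wf <- its1_far_map()
  v4 <- vsotf_from_map(wf, pad_factor = 4)
  v8 <- vsotf_from_map(wf, pad_factor = 8)
  expect_lt(abs(v4 - v8), 1e-3)
  # mismatched grids are rejected
  o1 <- otf(psf(pupil_function(wf, 4)))
  o2 <- otf(psf(pupil_function(wf, 8)))
  expect_error(vsotf(o1, o2), "do not match")
})
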