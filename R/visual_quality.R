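#' Default neural CSF parameters
#'
#' Parameters of the radially symmetric parametric neural contrast
#' sensitivity function used to weight the OTF in the visual Strehl
#' ratio: `CSF_N(f) = a exp(-(f/fc)^q)` with `f` in cycles/degree — a
#' stretched-exponential decline matching the neural (post-optical)
#' contrast sensitivity measured with interference fringes, which falls
#' roughly exponentially from its low-frequency maximum with a
#' characteristic frequency near 10 cycles/degree. The weighting
#' function is configurable; the visual Strehl of a diffraction-limited
#' system is 1 for any parameter choice, and only the shape (not the
#' absolute sensitivity `a`) affects the metric.
#'
#' @return named list `a` (peak sensitivity), `fc` (characteristic
#'   frequency, cycles/degree), `q` (stretch exponent).
#' @export
csf_default_params <- function() {
  list(a = 500, fc = 10.3, q = 1)
}

#' Neural contrast sensitivity function
#'
#' @param f spatial frequency, cycles/degree (vectorized, f >= 0).
#' @param params parameter list, see [csf_default_params()].
#' @return sensitivity (dimensionless, >= 0).
#' @export
csf_n <- function(f, params = csf_default_params()) {
  pmax(params$a * exp(-(f / params$fc)^params$q), 0)
}

#' Peak frequency and sensitivity of a CSF parameter set
#'
#' @param params parameter list, see [csf_default_params()].
#' @return list with `peak_frequency_cpd` and `peak_sensitivity`.
#' @export
csf_peak <- function(params = csf_default_params()) {
  f <- seq(0, 60, by = 0.05)
  s <- csf_n(f, params)
  i <- which.max(s)
  list(peak_frequency_cpd = f[i], peak_sensitivity = s[i])
}

#' Complex pupil function from a wavefront map
#'
#' Uniform-amplitude circular pupil (1 inside the 3 mm disc, 0 outside)
#' with phase 2*pi*OPD, embedded in a zero-padded square grid for
#' frequency resolution. Vignetted samples get zero amplitude.
#'
#' @param map a `wavefront_map` on a regular square grid.
#' @param pad_factor zero-padding factor (>= 2).
#' @return object of class `pupil_function`: complex matrix `A` (P x P),
#'   pupil pitch `dx_mm`, wavelength, grid sizes.
#' @export
pupil_function <- function(map, pad_factor = 4) {
  stopifnot(pad_factor >= 2)
  N <- map$n_grid
  P <- N * pad_factor
  amp <- matrix(0, N, N)
  phs <- matrix(0, N, N)
  idx <- cbind(map$iu, map$iv)
  amp[idx] <- as.numeric(map$mask)
  phs[idx] <- ifelse(map$mask, 2 * pi * map$opd, 0)
  A <- matrix(0 + 0i, P, P)
  A[1:N, 1:N] <- amp * exp(1i * phs)
  out <- list(A = A, n_grid = N, P = P,
              dx_mm = 2 * map$pupil_radius_mm / (N - 1),
              wavelength_nm = map$wavelength_nm)
  class(out) <- "pupil_function"
  out
}

#' Point-spread function
#'
#' Squared modulus of the Fourier transform of the pupil function,
#' normalized to unit sum. The array is in unshifted FFT order: the
#' on-axis image point is element [1, 1].
#'
#' @param pf a [pupil_function()].
#' @return object of class `psf_grid` with intensity matrix `I`.
#' @export
psf <- function(pf) {
  I <- Mod(stats::fft(pf$A))^2
  out <- list(I = I / sum(I), P = pf$P, dx_mm = pf$dx_mm,
              wavelength_nm = pf$wavelength_nm)
  class(out) <- "psf_grid"
  out
}

# FFT frequency index vector (0, 1, ..., P/2, -(P/2-1), ..., -1)
fft_freqs <- function(P) {
  k <- seq_len(P) - 1
  ifelse(k > P / 2, k - P, k)
}

#' Optical transfer function
#'
#' Fourier transform of the PSF, normalized so OTF(0, 0) = 1, with
#' frequency axes in cycles/degree derived from the pupil pitch and
#' wavelength (per-sample pitch `dx/lambda` cycles/radian).
#'
#' @param p a [psf()] grid.
#' @return object of class `otf_grid`: complex matrix `O`, frequency
#'   axes `fx`, `fy` (cycles/degree, FFT order), radial frequency `fr`,
#'   and the incoherent cutoff `cutoff_cpd`.
#' @export
otf <- function(p) {
  O <- stats::fft(p$I)
  O <- O / O[1, 1]
  lam_mm <- p$wavelength_nm * 1e-6
  df_cpd <- (p$dx_mm / lam_mm) * (pi / 180)
  f <- fft_freqs(p$P) * df_cpd
  fr <- sqrt(outer(f^2, f^2, `+`))
  out <- list(O = O, fx = f, fy = f, fr = fr, df_cpd = df_cpd,
              max_sampled_cpd = max(abs(f)))
  class(out) <- "otf_grid"
  out
}

#' Visual Strehl ratio (OTF method)
#'
#' Ratio of the neural-CSF-weighted integral of the real part of the
#' system OTF to the same integral for the diffraction-limited OTF,
#' evaluated by discrete quadrature over the sampled frequency grid.
#' Equals 1 for a diffraction-limited system under any CSF.
#'
#' @param otf_sys [otf()] grid of the system.
#' @param otf_dl [otf()] grid of the diffraction-limited twin (same
#'   frequency grid).
#' @param csf_params neural CSF parameters.
#' @param use_re use the real part of the OTF (default, the established
#'   visual-Strehl convention); `FALSE` uses the modulus.
#' @return VSOTF (dimensionless).
#' @export
vsotf <- function(otf_sys, otf_dl, csf_params = csf_default_params(),
                  use_re = TRUE) {
  if (!identical(dim(otf_sys$O), dim(otf_dl$O)) ||
      !isTRUE(all.equal(otf_sys$fx, otf_dl$fx)))
    stop("system and diffraction-limited OTF grids do not match")
  W <- csf_n(otf_sys$fr, csf_params)
  num <- if (use_re) sum(W * Re(otf_sys$O)) else sum(W * Mod(otf_sys$O))
  den <- sum(W * Re(otf_dl$O))
  num / den
}

#' Visual Strehl ratio straight from a wavefront map
#'
#' Convenience wrapper running the full metric chain: pupil function,
#' PSF, OTF, and the CSF-weighted ratio against the diffraction-limited
#' twin (same pupil mask, zero phase).
#'
#' @param map a `wavefront_map`.
#' @param pad_factor zero-padding factor.
#' @param csf_params neural CSF parameters.
#' @param use_re real-part convention flag, see [vsotf()].
#' @return VSOTF (dimensionless).
#' @export
vsotf_from_map <- function(map, pad_factor = 4,
                           csf_params = csf_default_params(),
                           use_re = TRUE) {
  o_sys <- otf(psf(pupil_function(map, pad_factor)))
  dl <- map
  dl$opd[dl$mask] <- 0
  o_dl <- otf(psf(pupil_function(dl, pad_factor)))
  vsotf(o_sys, o_dl, csf_params, use_re)
}

#' Strehl ratio (on-axis PSF intensity ratio)
#'
#' @param map a `wavefront_map`.
#' @param pad_factor zero-padding factor.
#' @return on-axis intensity of the aberrated PSF divided by that of the
#'   diffraction-limited PSF.
#' @export
strehl_from_map <- function(map, pad_factor = 4) {
  p_sys <- psf(pupil_function(map, pad_factor))
  dl <- map
  dl$opd[dl$mask] <- 0
  p_dl <- psf(pupil_function(dl, pad_factor))
  p_sys$I[1, 1] / p_dl$I[1, 1]
}
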